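#' Simulation configuration for a synthetic LC-MS cohort
#'
#' Parameters of the synthetic untargeted-metabolomics cohort generator.
#' The generator emulates the statistical structure the downstream analysis
#' assumes: log-normal feature intensities with feature-specific location and
#' spread, a subset of class-discriminant features shifted on the log scale,
#' per-sample multiplicative dilution, pooled QC injections with a target
#' coefficient of variation, low-level blank contamination, and
#' intensity-dependent (left-censoring-like) missingness.
#'
#' @param n_per_group Integer vector of length 2: study samples per class.
#' @param n_features Number of features.
#' @param n_discriminant Number of class-discriminant features (0 for a null
#'   cohort).
#' @param effect_size Standardized mean shift of discriminant features in the
#'   second class, in units of the within-group SD on the log scale. Must be
#'   >= 0.
#' @param dilution_range Length-2 numeric `[lo, hi]`, `0 < lo <= hi`:
#'   per-sample multiplicative dilution factors are drawn uniformly on this
#'   interval.
#' @param qc_count Number of pooled QC injections (>= 3).
#' @param blank_count Number of blank injections (>= 3).
#' @param blank_level Blank contamination level for contaminated features, as
#'   a fraction of the median study intensity (0-1).
#' @param blank_contaminated_frac Fraction of features carrying blank
#'   contamination at `blank_level`; the rest sit near zero in blanks.
#' @param missing_rate Probability that a value below the lowest intensity
#'   decile is censored to missing (0-1).
#' @param qc_cv_target Target coefficient of variation of QC replicates.
#' @param seed RNG seed; a single global seed fans out to per-stage child
#'   seeds so each stage is individually reproducible.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_per_group = c(30, 30), n_features = 500,
                       n_discriminant = 10, effect_size = 2,
                       dilution_range = c(0.5, 2), qc_count = 8,
                       blank_count = 4, blank_level = 0.02,
                       blank_contaminated_frac = 0.05,
                       missing_rate = 0.3, qc_cv_target = 0.1, seed = 1) {
  if (length(n_per_group) != 2 || any(n_per_group < 1))
    stop("n_per_group must be two positive integers")
  if (n_features < 1) stop("n_features must be positive")
  if (n_discriminant < 0 || n_discriminant > n_features)
    stop("n_discriminant must be in [0, n_features]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (length(dilution_range) != 2 || dilution_range[1] <= 0 ||
      dilution_range[1] > dilution_range[2])
    stop("dilution_range must be [lo, hi] with 0 < lo <= hi")
  if (qc_count < 3) stop("qc_count must be >= 3")
  if (blank_count < 3) stop("blank_count must be >= 3")
  for (r in c(blank_level, blank_contaminated_frac, missing_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (qc_cv_target <= 0) stop("qc_cv_target must be positive")
  structure(list(
    n_per_group = as.integer(n_per_group), n_features = as.integer(n_features),
    n_discriminant = as.integer(n_discriminant), effect_size = effect_size,
    dilution_range = dilution_range, qc_count = as.integer(qc_count),
    blank_count = as.integer(blank_count), blank_level = blank_level,
    blank_contaminated_frac = blank_contaminated_frac,
    missing_rate = missing_rate, qc_cv_target = qc_cv_target,
    seed = as.integer(seed)), class = "sim_config")
}

# Derive independent child seeds from the global seed, one per stage.
child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a study feature table plus pooled QC and blank injections from the
#' generative model described in [sim_config()], and returns the planted
#' truth (discriminant feature indices, per-sample dilution factors, class
#' labels) alongside it. Output is bit-identical under a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (list: `discriminant_indices`, `dilution_factors` named by study sample,
#'   `class_labels`).
#' @examples
#' sim <- generate_cohort(sim_config(n_per_group = c(10, 10),
#'                                   n_features = 50, seed = 7))
#' sim$table
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_features
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  n <- n1 + n2
  seeds <- child_seeds(config$seed, 7)

  # Feature-level population parameters (log scale).
  pars <- withr::with_seed(seeds[1], list(
    mu = stats::runif(p, log(1e3), log(1e6)),
    sigma = stats::runif(p, 0.2, 0.6),
    disc = if (config$n_discriminant > 0)
      sort(sample.int(p, config$n_discriminant)) else integer(0),
    contam = sample.int(p, max(1, round(config$blank_contaminated_frac * p)))
  ))

  classes <- rep(c("A", "B"), c(n1, n2))
  shift <- matrix(0, n, p)
  if (length(pars$disc))
    shift[classes == "B", pars$disc] <-
      rep(config$effect_size * pars$sigma[pars$disc], each = n2)

  logX <- withr::with_seed(seeds[2],
    matrix(pars$mu, n, p, byrow = TRUE) + shift +
      matrix(stats::rnorm(n * p), n, p) *
        matrix(pars$sigma, n, p, byrow = TRUE))

  dil <- withr::with_seed(seeds[3],
    stats::runif(n, config$dilution_range[1], config$dilution_range[2]))
  study <- exp(logX) * dil

  # QC pool: equal aliquots of every study sample, i.e. the per-feature mean
  # of the (undiluted) study intensities, re-injected with multiplicative
  # noise tuned to the target CV.
  pool <- colMeans(exp(logX))
  s_q <- sqrt(log(1 + config$qc_cv_target^2))
  qc <- withr::with_seed(seeds[4],
    matrix(pool, config$qc_count, p, byrow = TRUE) *
      exp(matrix(stats::rnorm(config$qc_count * p, -s_q^2 / 2, s_q),
                 config$qc_count, p)))

  med_study <- stats::median(study)
  blank_mean <- rep(1e-3 * med_study, p)
  blank_mean[pars$contam] <- config$blank_level * med_study
  blank <- withr::with_seed(seeds[5],
    matrix(blank_mean, config$blank_count, p, byrow = TRUE) *
      exp(matrix(stats::rnorm(config$blank_count * p, 0, 0.3),
                 config$blank_count, p)))

  X <- rbind(study, qc, blank)
  roles <- rep(c("Study", "QC", "Blank"),
               c(n, config$qc_count, config$blank_count))
  rownames(X) <- sprintf("%s%03d", c("S", "QC", "BL")[match(roles,
    c("Study", "QC", "Blank"))], c(seq_len(n), seq_len(config$qc_count),
                                   seq_len(config$blank_count)))
  colnames(X) <- synth_feature_ids(p, seeds[6])

  # Intensity-dependent missingness: values below the lowest study-intensity
  # decile are censored with probability missing_rate.
  thr <- stats::quantile(study, 0.10)
  X <- withr::with_seed(seeds[7], {
    cens <- X < thr & matrix(stats::runif(length(X)), nrow(X)) <
      config$missing_rate
    X[cens] <- NA
    X
  })

  table <- feature_table(X, roles,
                         c(classes, rep(NA_character_,
                                        config$qc_count + config$blank_count)))
  truth <- list(
    discriminant_indices = pars$disc,
    dilution_factors = stats::setNames(dil, rownames(X)[seq_len(n)]),
    class_labels = stats::setNames(classes, rownames(X)[seq_len(n)])
  )
  list(table = table, truth = truth)
}

# Rt_mass style feature names, e.g. "1.23_180.0634".
synth_feature_ids <- function(p, seed) {
  withr::with_seed(seed, {
    rt <- sort(round(stats::runif(p, 0.4, 8.0), 2))
    mz <- round(stats::runif(p, 50, 1200), 4)
    make.unique(sprintf("%.2f_%.4f", rt, mz), sep = "x")
  })
}

#' Generate synthetic cohort metadata
#'
#' Binary risk-factor columns with stated prevalences plus a binary outcome;
#' at most one factor may be associated with the outcome at a given odds
#' ratio while keeping (approximately) its marginal prevalence.
#'
#' @param n Number of subjects.
#' @param prevalences Named numeric vector of factor prevalences in `[0, 1]`.
#' @param outcome_prevalence Outcome prevalence in `[0, 1]`.
#' @param associated_factor Name of the factor tied to the outcome, or `NULL`.
#' @param odds_ratio Odds ratio of the association (1 = none).
#' @param seed RNG seed.
#' @return A data.frame with an `outcome` column (0/1) and one 0/1 column per
#'   factor.
#' @export
generate_metadata <- function(n, prevalences, outcome_prevalence = 0.5,
                              associated_factor = NULL, odds_ratio = 1,
                              seed = 1) {
  if (any(prevalences < 0 | prevalences > 1) ||
      outcome_prevalence < 0 || outcome_prevalence > 1)
    stop("probabilities must lie in [0, 1]")
  if (odds_ratio <= 0) stop("odds_ratio must be positive")
  if (!is.null(associated_factor) &&
      !associated_factor %in% names(prevalences))
    stop("associated_factor not among the prevalence names")
  withr::with_seed(seed, {
    outcome <- stats::rbinom(n, 1, outcome_prevalence)
    meta <- data.frame(outcome = outcome)
    for (f in names(prevalences)) {
      pi <- prevalences[[f]]
      if (!is.null(associated_factor) && f == associated_factor &&
          odds_ratio != 1) {
        # P(factor | outcome) split achieving the odds ratio while keeping
        # the marginal prevalence: solve for p0 on (0, 1).
        rho <- outcome_prevalence
        fobj <- function(p0) {
          p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
          (1 - rho) * p0 + rho * p1 - pi
        }
        p0 <- stats::uniroot(fobj, c(1e-9, 1 - 1e-9))$root
        p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
        meta[[f]] <- stats::rbinom(n, 1, ifelse(outcome == 1, p1, p0))
      } else {
        meta[[f]] <- stats::rbinom(n, 1, pi)
      }
    }
    meta
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
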