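# ---------------------------------------------------------------------------
# Synthetic respondents from a second-order factor model.
#
# A general severity factor g feeds three first-order factors (cognitive,
# somatic, affective) through the published second-order links; each item's
# latent response is its published standardized loading times its factor
# plus unique noise, dichotomized at a single common threshold tau.  tau and
# the clinical severity shift mu are calibrated so the expected total scores
# match the published group means.
# ---------------------------------------------------------------------------

.queds_loadings <- function() {
  c(`1` = 0.32, `2` = 0.46, `3` = 0.59, `4` = 0.37, `5` = 0.59, `6` = 0.37,
    `7` = 0.36, `8` = 0.39, `9` = 0.50, `10` = 0.42, `11` = 0.34, `12` = 0.49,
    `13` = 0.42, `14` = 0.72, `15` = 0.45, `16` = 0.61, `17` = 0.45,
    `18` = 0.62, `19` = 0.32, `20` = 0.62, `21` = 0.37, `22` = 0.39,
    `23` = 0.36, `24` = 0.66, `25` = 0.64, `26` = 0.42, `27` = 0.26,
    `28` = 0.71, `29` = 0.38, `30` = 0.51, `31` = 0.55, `32` = 0.62,
    `33` = 0.26, `34` = 0.70, `35` = 0.54, `36` = 0.46, `37` = 0.65,
    `38` = 0.53, `39` = 0.39, `40` = 0.33, `41` = 0.76)
}

#' Default generator configuration
#'
#' Item loadings are the published standardized first-order loadings; the
#' second-order links are 0.77 (cognitive), 0.70 (somatic) and 0.91
#' (affective).  The threshold `tau`, clinical shift `mu` and retest
#' stability `rho` are left `NA` until [calibrate()] /
#' [calibrate_retest()] set them.
#'
#' @return An object of class `generator_config` with components
#'   `loadings` (named by item id), `second_order`, `factor_of` (item ->
#'   factor name), `tau`, `mu` and `rho`.
#' @export
default_config <- function() {
  factors <- queds_factors()
  factor_of <- character(41)
  for (f in names(factors)) factor_of[factors[[f]]] <- f
  names(factor_of) <- 1:41
  structure(
    list(loadings = .queds_loadings(),
         second_order = c(cognitive = 0.77, somatic = 0.70, affective = 0.91),
         factor_of = factor_of,
         tau = NA_real_, mu = NA_real_, rho = NA_real_),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic-respondent generator config\n")
  cat("  loadings: ", length(x$loadings), " items, range [",
      min(x$loadings), ", ", max(x$loadings), "]\n", sep = "")
  cat("  second-order links:",
      paste(names(x$second_order), x$second_order, sep = "=", collapse = ", "), "\n")
  cat("  tau =", x$tau, "| mu =", x$mu, "| rho =", x$rho, "\n")
  invisible(x)
}

# slope of item i's latent response on the general factor
.g_slope <- function(config) {
  unname(config$loadings * config$second_order[config$factor_of])
}

#' Calibrate the generator to the published group means
#'
#' The common threshold `tau` is set in closed form so that the expected
#' non-clinical total, `k * (1 - pnorm(tau))`, equals the non-clinical
#' target; the clinical severity shift `mu` is then found by bisection so
#' that `sum(1 - pnorm(tau - lambda_i * gamma_k(i) * mu))` equals the
#' clinical target (each latent response is marginally standard normal, so
#' these are the exact expected scores).
#'
#' @param config a `generator_config`.
#' @param target_nonclinical_mean,target_clinical_mean expected total scores
#'   for the two groups; must lie strictly inside (0, number of items).
#' @param tol bisection tolerance on the clinical expected score.
#' @return The calibrated `generator_config`.
#' @export
calibrate <- function(config, target_nonclinical_mean = 6.5,
                      target_clinical_mean = 28.5, tol = 1e-9) {
  k <- length(config$loadings)
  if (target_nonclinical_mean <= 0 || target_nonclinical_mean >= k ||
      target_clinical_mean <= 0 || target_clinical_mean >= k) {
    stop_input("targets must lie strictly inside (0, ", k, ")")
  }
  config$tau <- stats::qnorm(1 - target_nonclinical_mean / k)
  slope <- .g_slope(config)
  expected <- function(mu) sum(1 - stats::pnorm(config$tau - slope * mu))
  lo <- 0; hi <- 1
  while (expected(hi) < target_clinical_mean && hi < 1e6) hi <- hi * 2
  if (expected(lo) > target_clinical_mean || expected(hi) < target_clinical_mean) {
    stop_compute("bisection bracket does not contain the clinical target")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (expected(mid) < target_clinical_mean) lo <- mid else hi <- mid
  }
  config$mu <- (lo + hi) / 2
  config
}

#' Generate a synthetic cohort
#'
#' Per subject: severity g ~ N(0, 1) for the non-clinical group or
#' N(mu, 1) for the clinical group; factor scores f_k = gamma_k g +
#' sqrt(1 - gamma_k^2) eta_k; latent item responses y_i = lambda_i f_k(i) +
#' sqrt(1 - lambda_i^2) eps_i; the 0/1 response is y_i > tau.
#'
#' @param config a calibrated `generator_config`.
#' @param n number of respondents (>= 1).
#' @param group `"nonclinical"` or `"clinical"`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return An object of class `synthetic_cohort` with components
#'   `responses` (n x 41 0/1 matrix, columns I1..I41), `groups`, `scores`,
#'   and the latent matrix in attribute `"latent"` (used by
#'   [generate_retest()]).
#' @export
generate <- function(config, n, group = c("nonclinical", "clinical"), seed = 1L) {
  group <- match.arg(group)
  if (n < 1) stop_input("n must be >= 1")
  if (is.na(config$tau)) stop_input("config must be calibrated first")
  if (group == "clinical" && is.na(config$mu)) {
    stop_input("config must be calibrated first")
  }
  set.seed(seed)
  k <- length(config$loadings)
  gam <- config$second_order
  lam <- config$loadings
  shift <- if (group == "clinical") config$mu else 0
  g <- stats::rnorm(n, shift, 1)
  eta <- matrix(stats::rnorm(n * length(gam)), n, length(gam),
                dimnames = list(NULL, names(gam)))
  fs <- sweep(eta, 2L, sqrt(1 - gam^2), `*`) + outer(g, gam)
  eps <- matrix(stats::rnorm(n * k), n, k)
  y <- sweep(fs[, config$factor_of, drop = FALSE], 2L, lam, `*`) +
    sweep(eps, 2L, sqrt(1 - lam^2), `*`)
  responses <- matrix(as.integer(y > config$tau), n, k,
                      dimnames = list(paste0(substr(group, 1, 1), seq_len(n)),
                                      paste0("I", names(lam))))
  out <- structure(
    list(responses = responses,
         groups = rep(group, n),
         scores = rowSums(responses)),
    class = "synthetic_cohort"
  )
  attr(out, "latent") <- y
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$responses), "respondents x",
      ncol(x$responses), "items (",
      paste(unique(x$groups), collapse = "/"), ")\n")
  cat("  mean score", formatC(mean(x$scores), digits = 2, format = "f"),
      "| sd", formatC(stats::sd(x$scores), digits = 2, format = "f"), "\n")
  invisible(x)
}

#' Generate a retest administration of an existing cohort
#'
#' Time-2 latent responses are rho * y + sqrt(1 - rho^2) * fresh standard
#' normal noise, dichotomized at the same threshold: rho = 1 reproduces the
#' time-1 responses exactly, rho = 0 gives an independent administration.
#'
#' @param cohort a `synthetic_cohort` from [generate()].
#' @param config the `generator_config` used to generate it, with `rho` set
#'   (directly or via [calibrate_retest()]).
#' @param seed integer seed for the fresh noise.
#' @return A `synthetic_cohort` of the same subjects at time 2.
#' @export
generate_retest <- function(cohort, config, seed = 1L) {
  if (is.na(config$rho)) stop_input("config$rho must be set (see calibrate_retest)")
  y <- attr(cohort, "latent")
  if (is.null(y)) stop_input("cohort carries no latent matrix")
  set.seed(seed)
  rho <- config$rho
  y2 <- rho * y + sqrt(1 - rho^2) *
    matrix(stats::rnorm(length(y)), nrow(y), ncol(y))
  responses <- matrix(as.integer(y2 > config$tau), nrow(y), ncol(y),
                      dimnames = dimnames(cohort$responses))
  out <- structure(
    list(responses = responses, groups = cohort$groups,
         scores = rowSums(responses)),
    class = "synthetic_cohort"
  )
  attr(out, "latent") <- y2
  out
}

#' Calibrate the retest stability to a target score correlation
#'
#' Finds rho by bisection so that the correlation between time-1 and time-2
#' total scores of a calibration cohort matches the target.  Common random
#' numbers (one fixed draw of the time-1 cohort and of the fresh noise) make
#' the achieved correlation a deterministic, monotone function of rho, so
#' plain bisection applies; the result is Monte-Carlo accurate at the
#' calibration size `n`.
#'
#' @param config a calibrated `generator_config`.
#' @param target target test-retest score correlation in (0, 1).
#' @param n calibration cohort size.
#' @param seed integer seed for the calibration draw.
#' @param tol bisection tolerance on rho.
#' @return The `generator_config` with `rho` set.
#' @export
calibrate_retest <- function(config, target = 0.74, n = 5000L, seed = 1L,
                             tol = 1e-4) {
  if (target <= 0 || target >= 1) stop_input("target must lie in (0, 1)")
  cohort <- generate(config, n, "nonclinical", seed = seed)
  y <- attr(cohort, "latent")
  set.seed(seed + 1L)
  noise <- matrix(stats::rnorm(length(y)), nrow(y), ncol(y))
  achieved <- function(rho) {
    y2 <- rho * y + sqrt(1 - rho^2) * noise
    stats::cor(cohort$scores, rowSums(y2 > config$tau))
  }
  lo <- 0; hi <- 1
  if (achieved(1) < target) {
    stop_compute("bisection bracket does not contain the retest target")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (achieved(mid) < target) lo <- mid else hi <- mid
  }
  config$rho <- (lo + hi) / 2
  config
}

#' Score-level surrogate for the known-groups analysis
#'
#' Draws integer total scores directly from the published group moments —
#' clinical N(28.5, 6.5), non-clinical N(6.5, 6.0) — rounded and clipped to
#' the score range \[0, 41\].  This surrogate matches both group means and
#' spreads exactly (up to rounding), which the latent generator does not
#' attempt, and is the input for the ROC-based known-groups checks.
#'
#' @param n_clin,n_nonclin group sizes (>= 1).
#' @param seed integer seed.
#' @return List with `scores` (integer vector) and `labels`
#'   (`"clinical"`/`"nonclinical"`, aligned with `scores`).
#' @export
generate_score_surrogate <- function(n_clin = 38L, n_nonclin = 265L, seed = 1L) {
  if (n_clin < 1 || n_nonclin < 1) stop_input("group sizes must be positive")
  set.seed(seed)
  clin <- stats::rnorm(n_clin, 28.5, 6.5)
  nonclin <- stats::rnorm(n_nonclin, 6.5, 6.0)
  scores <- pmin(pmax(round(c(clin, nonclin)), 0L), 41L)
  list(scores = as.integer(scores),
       labels = rep(c("clinical", "nonclinical"), c(n_clin, n_nonclin)))
}

#' Write a generator configuration as JSON
#'
#' @param config a `generator_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  doc <- unclass(config)
  # named atomic vectors serialize as arrays; keep the names via lists
  for (f in c("loadings", "second_order", "factor_of")) {
    doc[[f]] <- as.list(doc[[f]])
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a generator configuration from JSON
#'
#' @param path JSON file written by [write_config()].
#' @return A `generator_config`.
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (f in c("tau", "mu", "rho")) {
    if (!is.null(doc[[f]]) && !is.na(doc[[f]])) cfg[[f]] <- as.numeric(doc[[f]])
  }
  if (!is.null(doc$loadings)) {
    cfg$loadings <- stats::setNames(as.numeric(doc$loadings), names(doc$loadings))
  }
  if (!is.null(doc$second_order)) {
    cfg$second_order <- stats::setNames(as.numeric(doc$second_order),
                                        names(doc$second_order))
  }
  cfg
}
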