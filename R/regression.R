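#' Ordinary least squares of a water-table statistic on log10(MFAC)
#'
#' Fits `response = a + b * log10(mfac)` by OLS and reports the coefficient
#' of determination together with the ANOVA F test of the regression
#' (df 1, n - 2). The response is a signed level in metres relative to
#' ground (negative below ground), so a positive slope means shallower
#' water tables at higher MFAC. r-squared, F and p are invariant to the
#' logarithm base; only the slope rescales.
#'
#' @param mfac Positive MFAC values (km).
#' @param response Water-table statistic per observation (m).
#' @param ids Optional observation identifiers (used in error messages and
#'   residual tables).
#' @return An `mfac_fit` with `intercept`, `slope`, `n`, `r_squared`,
#'   `f_statistic`, `df`, `p_value`, `sigma`, `fitted`, `residuals` and the
#'   underlying `lm` object as `model`.
#' @export
fit_log_linear <- function(mfac, response, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(mfac))
  keep <- !is.na(mfac) & !is.na(response)
  mfac <- mfac[keep]; response <- response[keep]; ids <- ids[keep]
  if (any(mfac <= 0))
    stop("non-positive MFAC for observation(s): ",
         paste(ids[mfac <= 0], collapse = ", "))
  n <- length(mfac)
  if (n < 3) stop(sprintf("need at least 3 observations, have %d", n))
  if (any(!is.finite(response))) stop("response values must be finite")
  lx <- log10(mfac)
  model <- stats::lm(response ~ lx)
  sm <- summary(model)
  fstat <- unname(sm$fstatistic)
  structure(list(
    intercept = unname(stats::coef(model)[1]),
    slope = unname(stats::coef(model)[2]),
    n = n,
    r_squared = sm$r.squared,
    f_statistic = fstat[1],
    df = c(1L, n - 2L),
    p_value = stats::pf(fstat[1], 1, n - 2, lower.tail = FALSE),
    sigma = sm$sigma,
    fitted = unname(stats::fitted(model)),
    residuals = unname(stats::residuals(model)),
    ids = ids, mfac = mfac, response = response,
    model = model), class = "mfac_fit")
}

#' @export
print.mfac_fit <- function(x, ...) {
  cat(sprintf("OLS: response = %.4f %+.4f * log10(MFAC km)\n", x$intercept, x$slope))
  cat(sprintf("n = %d, r2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$n, x$r_squared, x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Predict with confidence and prediction intervals
#'
#' Point predictions on the fitted line with two-sided confidence
#' intervals (for the mean response) and prediction intervals (for a new
#' observation) at the requested level, using the t distribution on n - 2
#' degrees of freedom. Queries outside the fitted log10(MFAC) range are
#' flagged as extrapolation but still returned.
#'
#' @param fit An `mfac_fit`.
#' @param mfac Positive MFAC values (km) at which to predict.
#' @param level Interval level (default 0.95).
#' @return data.frame with `mfac`, `fit`, `ci_lo`, `ci_hi`, `pi_lo`,
#'   `pi_hi`, `extrapolated`.
#' @export
predict_with_intervals <- function(fit, mfac, level = 0.95) {
  stopifnot(inherits(fit, "mfac_fit"))
  if (any(mfac <= 0)) stop("MFAC values must be positive")
  lx <- log10(mfac)
  nd <- data.frame(lx = lx)
  ci <- stats::predict(fit$model, nd, interval = "confidence", level = level)
  pi <- stats::predict(fit$model, nd, interval = "prediction", level = level)
  rng <- range(log10(fit$mfac))
  data.frame(mfac = mfac, fit = ci[, "fit"],
             ci_lo = ci[, "lwr"], ci_hi = ci[, "upr"],
             pi_lo = pi[, "lwr"], pi_hi = pi[, "upr"],
             extrapolated = lx < rng[1] | lx > rng[2])
}

#' Predicted-minus-observed residual table
#'
#' For each well with both an MFAC value and an observed response, the
#' model prediction minus the observation, in metres (positive when the
#' observed water table is deeper than the model suggests). Rows with
#' missing values are omitted and their ids recorded in the `"omitted"`
#' attribute.
#'
#' @param fit An `mfac_fit`.
#' @param mfac MFAC values (km) per well.
#' @param observed Observed response (m) per well.
#' @param ids Well identifiers.
#' @param digits Rounding applied to the display column (default 2 dp).
#' @return data.frame with `id`, `mfac`, `observed`, `predicted`,
#'   `pred_minus_obs`, `pred_minus_obs_2dp`.
#' @export
residuals_predicted_minus_observed <- function(fit, mfac, observed, ids = NULL,
                                               digits = 2) {
  stopifnot(inherits(fit, "mfac_fit"))
  if (is.null(ids)) ids <- as.character(seq_along(mfac))
  keep <- !is.na(mfac) & !is.na(observed)
  omitted <- ids[!keep]
  mfac <- mfac[keep]; observed <- observed[keep]; ids <- ids[keep]
  pred <- fit$intercept + fit$slope * log10(mfac)
  out <- data.frame(id = ids, mfac = mfac, observed = observed,
                    predicted = pred, pred_minus_obs = pred - observed,
                    pred_minus_obs_2dp = round(pred - observed, digits),
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  out
}

#' Wells below an MFAC cut with deep water tables
#'
#' Counts wells with MFAC below `mfac_cut` (and a non-missing water-table
#' record), and among them those whose statistic lies deeper than
#' `depth_cut` below ground. Because tabulated levels are rounded to 2 dp,
#' a printed level exactly equal to the cut cannot be distinguished from a
#' marginally deeper one; the default `ties = "deeper"` therefore counts
#' levels tied with the cut as exceeding it. Use `ties = "shallower"` for a
#' strict comparison.
#'
#' @param mfac MFAC values (km).
#' @param d90 Water-table statistic (m relative to ground, negative below).
#' @param mfac_cut MFAC cut in km (wells strictly below are selected).
#' @param depth_cut Depth below ground in metres (positive, e.g. 0.20).
#' @param ties `"deeper"` (default) or `"shallower"`.
#' @return Named integer vector `c(n_below_cut, n_deeper_than_depth_cut)`.
#' @export
threshold_counts <- function(mfac, d90, mfac_cut, depth_cut,
                             ties = c("deeper", "shallower")) {
  ties <- match.arg(ties)
  keep <- !is.na(mfac) & !is.na(d90)
  mfac <- mfac[keep]; d90 <- d90[keep]
  sel <- mfac < mfac_cut
  deeper <- if (ties == "deeper") d90[sel] <= -depth_cut else d90[sel] < -depth_cut
  c(n_below_cut = sum(sel), n_deeper_than_depth_cut = sum(deeper))
}

#' Fraction of wells predicted within a tolerance
#'
#' @param residual_table Output of [residuals_predicted_minus_observed()],
#'   or a numeric vector of residuals (m).
#' @param tol Tolerance in metres (default 0.10).
#' @return Fraction in `[0, 1]` of wells with `|predicted - observed| <= tol`.
#' @export
coverage_within_tolerance <- function(residual_table, tol = 0.10) {
  res <- if (is.data.frame(residual_table)) residual_table$pred_minus_obs
         else residual_table
  if (length(res) == 0L) stop("empty residual table")
  mean(abs(res) <= tol)
}

#' Predicted D90 at MFAC class boundaries
#'
#' Evaluates the fitted regression line at the class-scheme bin edges and
#' converts to depth below ground in cm, for comparison with the class
#' scheme's predicted D90 bands.
#'
#' @param fit An `mfac_fit` (normally of summer D90 on log10 MFAC).
#' @param edges_km Bin edges in km (default `c(0.5, 1, 2, 5)`).
#' @return data.frame with `mfac_km` and `predicted_d90_cm` (positive cm
#'   below ground).
#' @export
class_boundaries_from_fit <- function(fit, edges_km = c(0.5, 1, 2, 5)) {
  stopifnot(inherits(fit, "mfac_fit"))
  pred_m <- fit$intercept + fit$slope * log10(edges_km)
  data.frame(mfac_km = edges_km, predicted_d90_cm = -pred_m * 100)
}
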