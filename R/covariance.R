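#' Residual covariance specification
#'
#' Describes the within-plant residual covariance used by the generalized
#' non-linear least squares machinery: an optional first-order autoregressive
#' (AR1) correlation across the ordered measurements of one plant, and a
#' variance function giving each day's standard-deviation multiplier.
#'
#' Supported variance models:
#' * `"constant"` — homoscedastic, multiplier 1 everywhere;
#' * `"varExp"` — multiplier `exp(delta * day)`, variance growing (or
#'   shrinking) exponentially with the measurement day;
#' * `"varIdent"` — one free multiplier per harvest day (stratum), the first
#'   stratum anchored at 1 for identifiability; used for destructive designs
#'   where each harvest has its own dispersion.
#'
#' The AR1 coefficient applies per observation-order step within a plant,
#' appropriate for the regularly spaced every-other-day design; the
#' correlation between the i-th and j-th measurement of a plant is
#' `rho^|i-j|`.
#'
#' @param correlation `"independent"` or `"AR1"`.
#' @param rho AR1 coefficient in (-1, 1); required when `correlation="AR1"`.
#' @param variance `"constant"`, `"varExp"` or `"varIdent"`.
#' @param delta exponential-variance coefficient (per day) for `"varExp"`.
#' @param ratios for `"varIdent"`: named numeric vector of per-stratum
#'   standard-deviation ratios, names are the harvest days; the entry for the
#'   first (smallest) day must be 1.
#' @param sigma residual scale (> 0).
#' @return an object of class `cov_spec`.
#' @examples
#' cov_spec("AR1", rho = 0.5, variance = "varExp", delta = 0.2, sigma = 1)
#' @export
cov_spec <- function(correlation = c("independent", "AR1"), rho = NULL,
                     variance = c("constant", "varExp", "varIdent"),
                     delta = NULL, ratios = NULL, sigma = 1) {
  correlation <- match.arg(correlation)
  variance <- match.arg(variance)
  if (correlation == "AR1") {
    if (is.null(rho)) stop("AR1 correlation requires 'rho'", call. = FALSE)
    if (!is.finite(rho) || abs(rho) >= 1)
      stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  } else rho <- 0
  if (variance == "varExp") {
    if (is.null(delta) || !is.finite(delta))
      stop("varExp requires finite 'delta'", call. = FALSE)
  }
  if (variance == "varIdent") {
    if (is.null(ratios) || is.null(names(ratios)))
      stop("varIdent requires 'ratios' named by harvest day", call. = FALSE)
    if (any(ratios <= 0)) stop("variance ratios must be positive", call. = FALSE)
    dd <- as.numeric(names(ratios))
    if (anyNA(dd)) stop("ratio names must be numeric days", call. = FALSE)
    ratios <- ratios[order(dd)]
    if (abs(ratios[[1]] - 1) > 1e-12)
      stop("the first-stratum ratio must be anchored at 1", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be positive", call. = FALSE)
  structure(
    list(correlation = correlation, rho = rho, variance = variance,
         delta = delta, ratios = ratios, sigma = sigma),
    class = "cov_spec"
  )
}

#' @export
print.cov_spec <- function(x, ...) {
  cat("Covariance: ", x$correlation,
      if (x$correlation == "AR1") sprintf(" (rho = %.4g)", x$rho),
      ", variance ", x$variance,
      switch(x$variance,
             varExp = sprintf(" (delta = %.4g)", x$delta),
             varIdent = sprintf(" (%d strata)", length(x$ratios)),
             ""),
      ", sigma = ", format(x$sigma), "\n", sep = "")
  invisible(x)
}

#' Per-day standard-deviation multipliers of a variance function
#'
#' @param spec a [cov_spec()].
#' @param days numeric vector of measurement days.
#' @return numeric vector of multipliers `v(day)` (the residual sd at a day
#'   is `sigma * v(day)`).
#' @export
variance_multipliers <- function(spec, days) {
  stopifnot(inherits(spec, "cov_spec"))
  switch(spec$variance,
    constant = rep(1, length(days)),
    varExp   = exp(spec$delta * days),
    varIdent = {
      idx <- match(as.character(days), names(spec$ratios))
      if (anyNA(idx))
        stop("day(s) without a variance stratum: ",
             paste(unique(days[is.na(idx)]), collapse = ", "), call. = FALSE)
      unname(spec$ratios[idx])
    }
  )
}

#' Within-plant covariance block
#'
#' Builds the covariance matrix of one plant's residual vector: entry (i, j)
#' is `sigma^2 * v(day_i) * v(day_j) * rho^|i-j|`, with `v` the variance
#' multiplier of the spec.  The result is symmetric positive definite for any
#' valid spec.
#'
#' @param spec a [cov_spec()].
#' @param days sorted numeric vector of the plant's measurement days.
#' @return covariance matrix of dimension `length(days)`.
#' @examples
#' plant_covariance(cov_spec("AR1", rho = 0.5), days = c(2, 4, 6))
#' @export
plant_covariance <- function(spec, days) {
  stopifnot(inherits(spec, "cov_spec"))
  if (length(days) < 1L) stop("need at least one day", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("'days' must be strictly increasing", call. = FALSE)
  v <- variance_multipliers(spec, days)
  n <- length(days)
  R <- spec$rho ^ abs(outer(seq_len(n), seq_len(n), "-"))
  spec$sigma^2 * (v %o% v) * R
}

#' Log-likelihood of a grouped growth model
#'
#' Evaluates the Gaussian log-likelihood of a dataset under a mean-function
#' family, a grouping of lines into parameter levels, and a structured
#' within-plant covariance.  Residuals of one plant form a multivariate
#' normal vector with covariance given by [plant_covariance()]; plants are
#' independent.
#'
#' @param data long-format data.frame with columns `plant_id`, `line_id`,
#'   `day`, `value` (a `trait` column, if present, must be constant).
#' @param family mean-function family, see [growth_families()].
#' @param scheme a [grouping_scheme()] mapping lines to parameter levels.
#' @param mean_params named list: one element per scheme level, each a named
#'   numeric vector of that family's parameters.
#' @param spec a [cov_spec()] with all nuisance values set (including sigma).
#' @return the log-likelihood (scalar).  `gnls_neg_loglik()` returns its
#'   negative.
#' @export
gnls_loglik <- function(data, family, scheme, mean_params, spec) {
  -gnls_neg_loglik(data, family, scheme, mean_params, spec)
}

#' @rdname gnls_loglik
#' @export
gnls_neg_loglik <- function(data, family, scheme, mean_params, spec) {
  data <- check_fit_data(data, scheme)
  mu <- model_mean(data, family, scheme, mean_params)
  r <- data$value - mu
  nll <- 0
  for (pid in unique(data$plant_id)) {
    sel <- data$plant_id == pid
    o <- order(data$day[sel])
    Sig <- plant_covariance(spec, data$day[sel][o])
    ri <- r[sel][o]
    L <- tryCatch(chol(Sig), error = function(e)
      stop("covariance block for plant '", pid,
           "' is not positive definite", call. = FALSE))
    z <- backsolve(L, ri, transpose = TRUE)
    nll <- nll + 0.5 * (length(ri) * log(2 * pi) +
                          2 * sum(log(diag(L))) + sum(z^2))
  }
  nll
}

## mean-function values for every row of a dataset under a grouping
model_mean <- function(data, family, scheme, mean_params) {
  lev <- scheme$level_of[as.character(data$line_id)]
  mu <- numeric(nrow(data))
  for (lv in scheme$levels) {
    sel <- lev == lv
    if (!any(sel)) next
    p <- mean_params[[lv]]
    if (is.null(p)) stop("no parameters supplied for level '", lv, "'",
                         call. = FALSE)
    mu[sel] <- growth_value(family, p, data$day[sel])
  }
  mu
}

check_fit_data <- function(data, scheme = NULL) {
  need <- c("plant_id", "line_id", "day", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("data needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if ("trait" %in% names(data) && length(unique(data$trait)) > 1L)
    stop("data contains multiple traits; subset to one first", call. = FALSE)
  if (!is.null(scheme)) {
    unknown <- setdiff(unique(as.character(data$line_id)),
                       names(scheme$level_of))
    if (length(unknown))
      stop("line(s) not covered by the grouping scheme: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  data
}
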