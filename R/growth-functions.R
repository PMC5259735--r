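#' Growth and decay mean functions
#'
#' Closed-form trajectory functions used throughout the package: the
#' expolinear growth curve (exponential phase passing smoothly into a linear
#' phase), a Gompertz sigmoid, and a logistic-style decay curve for reserve
#' depletion.  All three are evaluated in numerically robust forms so that
#' extreme exponents (|argument| up to ~700) never overflow.
#'
#' The expolinear function is
#' \deqn{Y(t) = (Cm/Rm)\,\log[1 + e^{Rm (t - tb)}]}
#' where `Cm` is the maximum absolute growth rate (response units per day,
#' the slope of the late linear phase), `Rm` the maximum relative growth rate
#' (per day, governing the early exponential phase), and `tb` the x-intercept
#' of the extrapolated linear phase (days).
#'
#' The Gompertz function is
#' \deqn{Y(t) = Wf\,e^{-e^{-k (t - TT)}}}
#' with asymptote `Wf`, maximum relative growth rate `k` (per day) attained at
#' time `TT` (days), where the curve passes through `Wf/e`.
#'
#' The decay function is
#' \deqn{Y(t) = Min + (Max - Min)/(1 + e^{rate (t - TT)})}
#' declining from an initial plateau `Max` to a final plateau `Min`, crossing
#' the mid-point `(Max+Min)/2` at `t = TT`.  `rate` defaults to 1 per day,
#' matching the form in which the curve is usually written for reserve decay;
#' it can be freed when steepness must be estimated.
#'
#' @param t numeric vector of times (days); must be finite.
#' @param Cm,Rm,tb expolinear parameters; `Cm > 0`, `Rm > 0`.
#' @param Wf,k,TT Gompertz parameters; `Wf > 0`, `k > 0` (`TT` also used by
#'   the decay curve as the mid-point time).
#' @param Max,Min,rate decay parameters; `Max > Min >= 0`, `rate > 0`.
#' @return numeric vector of trajectory values, same length as `t`.
#' @examples
#' expolinear(6.22, Cm = 149.52, Rm = 0.92, tb = 6.22)  # (Cm/Rm) * log(2)
#' gompertz(5.51, Wf = 26.99, k = 0.26, TT = 5.51)      # Wf / e
#' decay_curve(6.012, Max = 0.436, Min = 0.058, TT = 6.012)  # mid-point
#' @name growth_functions
NULL

## log(1 + e^u) without overflow: max(u,0) + log1p(e^{-|u|})
log1pexp <- function(u) {
  pmax(u, 0) + log1p(exp(-abs(u)))
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  t
}

#' @rdname growth_functions
#' @export
expolinear <- function(t, Cm, Rm, tb) {
  check_time(t)
  stopifnot(Cm > 0, Rm > 0)
  (Cm / Rm) * log1pexp(Rm * (t - tb))
}

#' @rdname growth_functions
#' @export
gompertz <- function(t, Wf, k, TT) {
  check_time(t)
  stopifnot(Wf > 0, k > 0)
  Wf * exp(-exp(-k * (t - TT)))
}

#' @rdname growth_functions
#' @export
decay_curve <- function(t, Max, Min, TT, rate = 1) {
  check_time(t)
  stopifnot(Max > Min, Min >= 0, rate > 0)
  Min + (Max - Min) * stats::plogis(-rate * (t - TT))
}

#' Families of mean functions
#'
#' The three trajectory families are addressed by name throughout the
#' fitting, selection and simulation layers.  `growth_families()` lists them;
#' `family_params()` gives the parameter names of a family (the decay family
#' has an optional fourth parameter, `rate`, fixed at 1 unless freed).
#'
#' @param family one of `"expolinear"`, `"gompertz"`, `"decay"`.
#' @param free_rate logical; if `TRUE` the decay family includes `rate` as an
#'   estimated parameter.
#' @return `growth_families()`: character vector; `family_params()`:
#'   character vector of parameter names.
#' @export
growth_families <- function() c("expolinear", "gompertz", "decay")

#' @rdname growth_families
#' @export
family_params <- function(family, free_rate = FALSE) {
  switch(match.arg(family, growth_families()),
    expolinear = c("Cm", "Rm", "tb"),
    gompertz   = c("Wf", "k", "TT"),
    decay      = if (free_rate) c("Max", "Min", "TT", "rate")
                 else c("Max", "Min", "TT")
  )
}

#' Evaluate a mean function by family name
#'
#' @param family family name, see [growth_families()].
#' @param p named numeric vector or list of parameters for that family (decay
#'   may omit `rate`, which then defaults to 1).
#' @param t numeric vector of times (days).
#' @return numeric vector of mean values.
#' @export
growth_value <- function(family, p, t) {
  family <- match.arg(family, growth_families())
  p <- as.list(p)
  switch(family,
    expolinear = expolinear(t, p$Cm, p$Rm, p$tb),
    gompertz   = gompertz(t, p$Wf, p$k, p$TT),
    decay      = decay_curve(t, p$Max, p$Min, p$TT,
                             rate = if (is.null(p$rate)) 1 else p$rate)
  )
}

#' Analytic parameter gradients of the mean functions
#'
#' Partial derivatives of the trajectory value with respect to each family
#' parameter, used for the generalized least-squares information matrix and
#' available to derivative-based optimisation.
#'
#' @inheritParams growth_value
#' @param free_rate logical; include the derivative with respect to the decay
#'   `rate` parameter.
#' @return numeric matrix, `length(t)` rows and one column per parameter
#'   (named as in [family_params()]).
#' @export
growth_gradient <- function(family, p, t, free_rate = FALSE) {
  family <- match.arg(family, growth_families())
  check_time(t)
  p <- as.list(p)
  if (family == "expolinear") {
    u <- p$Rm * (t - p$tb)
    s <- log1pexp(u)
    sig <- stats::plogis(u)
    cbind(
      Cm = s / p$Rm,
      Rm = (p$Cm / p$Rm) * (sig * (t - p$tb) - s / p$Rm),
      tb = -p$Cm * sig
    )
  } else if (family == "gompertz") {
    g <- exp(-p$k * (t - p$TT))
    y <- p$Wf * exp(-g)
    cbind(
      Wf = exp(-g),
      k  = y * g * (t - p$TT),
      TT = -y * g * p$k
    )
  } else {
    rate <- if (is.null(p$rate)) 1 else p$rate
    q <- stats::plogis(-rate * (t - p$TT))  # declining fraction
    dq <- q * (1 - q)
    out <- cbind(
      Max = q,
      Min = 1 - q,
      TT  = (p$Max - p$Min) * rate * dq
    )
    if (free_rate)
      out <- cbind(out, rate = -(p$Max - p$Min) * (t - p$TT) * dq)
    out
  }
}
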