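#' Small-sample Akaike information criterion
#'
#' \deqn{AICc = -2\log L + 2k + \frac{2k(k+1)}{n-k-1}}
#' The correction term requires `n > k + 1`; it vanishes as `n` grows, so
#' AICc approaches plain AIC in the large-sample limit.
#'
#' @param logL maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return the AICc value.
#' @examples
#' aicc(-469.8, 9, 110)  # 959.4
#' @export
aicc <- function(logL, k, n) {
  stopifnot(is.finite(logL), k >= 1, n >= 1)
  if (n <= k + 1)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Normalized relative likelihoods of a candidate set,
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}}, computed from the
#' AICc differences to the best model.
#'
#' @param deltas numeric vector of AICc differences (all `>= 0`, at least
#'   one exactly 0).
#' @return numeric weights summing to 1.
#' @examples
#' akaike_weights(c(0, 1.8, 38.8, 42.6, 53.5))
#' @export
akaike_weights <- function(deltas) {
  if (!length(deltas)) stop("empty delta set", call. = FALSE)
  if (any(deltas < 0)) stop("deltas must be non-negative", call. = FALSE)
  if (min(deltas) > 1e-8)
    stop("at least one delta must be zero (the best model)", call. = FALSE)
  w <- exp(-deltas / 2)
  w / sum(w)
}

#' Evidence ratio against the best model
#'
#' `exp(delta/2)`: how many times more likely the best model is than the
#' model `delta` AICc units behind it (equivalently the ratio of their
#' Akaike weights).
#'
#' @param delta non-negative AICc difference.
#' @return the evidence ratio (`>= 1`).
#' @examples
#' evidence_ratio(1.8)  # about 2.46
#' @export
evidence_ratio <- function(delta) {
  if (any(delta < 0)) stop("delta must be non-negative", call. = FALSE)
  exp(delta / 2)
}

#' Support category of an AICc difference
#'
#' Banding of model support by the AICc difference to the best model:
#' below 2 "strong", 2 up to 4 "moderate", 4 through 10 "substantial-to-weak",
#' above 10 "discard".
#'
#' @param delta non-negative AICc difference (vectorized).
#' @return character vector of categories.
#' @export
support_category <- function(delta) {
  if (any(delta < 0)) stop("delta must be non-negative", call. = FALSE)
  out <- character(length(delta))
  out[delta < 2] <- "strong"
  out[delta >= 2 & delta < 4] <- "moderate"
  out[delta >= 4 & delta <= 10] <- "substantial-to-weak"
  out[delta > 10] <- "discard"
  out
}

#' Multi-model AICc comparison table
#'
#' Ranks a set of fits of the same data (identical trait and observation
#' count) by AICc and attaches differences, Akaike weights, evidence ratios
#' and support categories.  Accepts `growth_fit` objects or plain lists with
#' elements `logLik`, `df`, `n_obs` and a scheme/label.
#'
#' @param fits list of fits (e.g. the five grouping hypotheses).
#' @param labels optional character labels; defaults to the fits' scheme
#'   names.
#' @return a `data.frame` of class `selection_table`, sorted by ascending
#'   AICc, with columns `scheme`, `df`, `logL`, `AICc`, `dAICc`, `wAICc`,
#'   `ER`, `support`.
#' @export
selection_table <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1L)
  get1 <- function(f, what) {
    switch(what,
      logL = if (inherits(f, "growth_fit")) f$logLik else f$logLik,
      df   = f$df,
      n    = f$n_obs,
      name = if (is.list(f$scheme) && !is.null(f$scheme$name)) f$scheme$name
             else if (!is.null(f$scheme)) as.character(f$scheme)
             else NA_character_)
  }
  n_set <- vapply(fits, get1, numeric(1), what = "n")
  if (length(unique(n_set)) != 1L)
    stop("fits were made on different sample sizes: ",
         paste(unique(n_set), collapse = ", "), call. = FALSE)
  if (is.null(labels))
    labels <- vapply(fits, get1, character(1), what = "name")
  tab <- data.frame(
    scheme = labels,
    df = vapply(fits, get1, numeric(1), what = "df"),
    logL = vapply(fits, get1, numeric(1), what = "logL"),
    stringsAsFactors = FALSE
  )
  tab$AICc <- mapply(aicc, tab$logL, tab$df, n_set)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  tab$wAICc <- akaike_weights(tab$dAICc)
  tab$ER <- evidence_ratio(tab$dAICc)
  tab$support <- support_category(tab$dAICc)
  rownames(tab) <- NULL
  class(tab) <- c("selection_table", "data.frame")
  attr(tab, "n") <- unique(n_set)
  tab
}

#' @export
print.selection_table <- function(x, digits = 4, ...) {
  cat("Model selection by AICc (n = ", attr(x, "n"), ")\n", sep = "")
  y <- as.data.frame(x)
  y$wAICc <- signif(y$wAICc, 3)
  y$ER <- signif(y$ER, 4)
  print(format(y, digits = digits), row.names = FALSE)
  invisible(x)
}
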