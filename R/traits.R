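#' End-point trait comparison with Tukey HSD letters
#'
#' Fits a fixed-effects model with line as the only factor (pooled residual
#' variance, so every mean gets the same standard error at equal replication),
#' runs all pairwise Tukey Honestly-Significant-Difference comparisons at the
#' given level, and summarizes them as a compact letter display: lines
#' sharing a letter are not significantly different.  Letters are assigned
#' from the largest mean downwards ('a' first) by the insert-and-absorb
#' algorithm, so two lines share a letter exactly when their Tukey-adjusted
#' p-value is at or above `alpha`.
#'
#' @param values data.frame with columns `line` (or `line_id`) and `value`,
#'   one row per plant.
#' @param alpha significance level for the letter display (default 0.05).
#' @param pooled_variance logical; `FALSE` switches the per-line SEs to the
#'   line's own sample variance (the Tukey test itself remains the classical
#'   pooled-variance HSD).
#' @return a data.frame of class `endpoint_summary` with columns `line`,
#'   `n`, `mean`, `se`, `letter`, sorted by descending mean, with the overall
#'   F-test p-value in attribute `"p_value"` and the pairwise Tukey results
#'   in attribute `"tukey"`.
#' @examples
#' d <- data.frame(line = rep(c("A", "B"), each = 10),
#'                 value = c(rnorm(10, 10, .1), rnorm(10, 1, .1)))
#' endpoint_compare(d)
#' @export
endpoint_compare <- function(values, alpha = 0.05, pooled_variance = TRUE) {
  if ("line_id" %in% names(values) && !"line" %in% names(values))
    names(values)[names(values) == "line_id"] <- "line"
  stopifnot(is.data.frame(values), all(c("line", "value") %in% names(values)))
  values$line <- factor(values$line)
  tabn <- table(values$line)
  if (nlevels(values$line) < 2L)
    stop("need at least two lines to compare", call. = FALSE)
  if (any(tabn < 2L))
    stop("line(s) with fewer than 2 replicates: ",
         paste(names(tabn)[tabn < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(value ~ line, data = values)
  p_overall <- stats::anova(fit)[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$line
  means <- tapply(values$value, values$line, mean)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  se <- if (pooled_variance) sqrt(mse / tabn)
        else sqrt(tapply(values$value, values$line, stats::var) / tabn)

  lines_desc <- names(sort(means, decreasing = TRUE))
  ## adjusted p for an unordered pair, robust to "A-B" vs "B-A" labelling
  pair_p <- function(a, b) {
    hit <- rownames(tk) %in% c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))
    tk[hit, "p adj"][1L]
  }
  letters_of <- cld_insert_absorb(lines_desc, pair_p, alpha)

  out <- data.frame(
    line = lines_desc,
    n = as.integer(tabn[lines_desc]),
    mean = as.numeric(means[lines_desc]),
    se = as.numeric(se[lines_desc]),
    letter = letters_of[lines_desc],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "p_value") <- p_overall
  attr(out, "tukey") <- tk
  class(out) <- c("endpoint_summary", "data.frame")
  out
}

## insert-and-absorb compact letter display.  `groups` are ordered by
## descending mean; `pair_p(a, b)` returns the adjusted p-value.
cld_insert_absorb <- function(groups, pair_p, alpha) {
  cols <- list(groups)                  # start: one letter covering all
  for (i in seq_along(groups)) for (j in seq_len(i - 1L)) {
    a <- groups[j]; b <- groups[i]
    if (pair_p(a, b) >= alpha) next     # non-significant pair may share
    k <- 1L
    while (k <= length(cols)) {
      if (all(c(a, b) %in% cols[[k]])) {
        without_a <- setdiff(cols[[k]], a)
        without_b <- setdiff(cols[[k]], b)
        cols[[k]] <- without_a
        cols <- append(cols, list(without_b), after = k)
        k <- k + 1L
      }
      k <- k + 1L
    }
    ## absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (k in seq_along(cols)) for (m in seq_along(cols))
      if (k != m && keep[m] && all(cols[[k]] %in% cols[[m]]) &&
          !(all(cols[[m]] %in% cols[[k]]) && k < m))
        keep[k] <- FALSE
    cols <- cols[keep]
  }
  ## order columns by the rank of their best (largest-mean) member
  first_rank <- vapply(cols, function(cc) min(match(cc, groups)), numeric(1))
  cols <- cols[order(first_rank)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols))
    out[cols[[k]]] <- paste0(out[cols[[k]]], letters[k])
  out
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat("End-point comparison (Tukey HSD), overall p-value ",
      format.pval(attr(x, "p_value"), digits = 3), "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Seed circularity
#'
#' The dimensionless shape descriptor `4 * pi * Area / Perimeter^2`: 1 for a
#' perfect circle, approaching 0 for elongated outlines.
#'
#' @param area seed area (cm^2), positive.
#' @param perimeter seed perimeter (cm), positive.
#' @return circularity value(s).
#' @examples
#' circularity(pi, 2 * pi)     # circle of radius 1 -> 1
#' circularity(1.20, 4.90)
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive", call. = FALSE)
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  4 * pi * area / perimeter^2
}

#' Root or shoot allocation per gram of seed
#'
#' Expresses an asymptotic organ size (e.g. the Gompertz `Wf` of primary or
#' basal root length) relative to the seed weight fuelling it.
#'
#' @param asymptote asymptotic organ size (cm, cm^2 or g).
#' @param seed_weight seed weight (g), positive.
#' @return allocation in organ units per gram.
#' @examples
#' allocation_per_gram(19.64, 0.10)  # 196.4 cm of primary root per gram
#' @export
allocation_per_gram <- function(asymptote, seed_weight) {
  if (any(seed_weight <= 0)) stop("seed weight must be positive", call. = FALSE)
  if (any(asymptote < 0)) stop("asymptote must be non-negative", call. = FALSE)
  asymptote / seed_weight
}

#' Reserve remobilization efficiency
#'
#' Final seedling dry weight per unit of initial cotyledon dry weight: the
#' asymptote of the seedling dry-weight curve divided by the initial plateau
#' of the cotyledon decay curve.
#'
#' @param seedling_Wf asymptotic seedling dry weight (g), positive.
#' @param cotyledon_Max initial cotyledon dry weight (g), positive.
#' @return dimensionless efficiency.
#' @examples
#' remobilization_efficiency(0.19, 0.121)  # about 1.57
#' @export
remobilization_efficiency <- function(seedling_Wf, cotyledon_Max) {
  if (any(cotyledon_Max <= 0))
    stop("cotyledon weight must be positive", call. = FALSE)
  if (any(seedling_Wf <= 0))
    stop("seedling weight must be positive", call. = FALSE)
  seedling_Wf / cotyledon_Max
}

#' Round half up to a number of decimals
#'
#' Round-half-up at the printed precision (0.5 always rounds away from zero),
#' the convention used when comparing derived ratios to printed values.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
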