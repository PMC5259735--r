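#' Line pedigree for a reciprocal-hybrid design
#'
#' The design the package targets crosses two selfed parents with contrasting
#' maternal seed-size classes and includes both reciprocal F1 hybrids, whose
#' nuclear genotype is identical but whose maternal parent (and hence seed
#' size class) differs.  `bean_lines()` returns the default pedigree for the
#' common-bean landrace G19833 (large-seeded) x wild accession G23419
#' (small-seeded) design; any pedigree with the same structure (two selfed
#' parents + the two reciprocals) is accepted by [grouping_scheme()].
#'
#' @param line_id,maternal,paternal character vectors defining each line by
#'   its maternal and paternal parent (selfed parents have
#'   `maternal == paternal`).
#' @param parent_class named character vector mapping each parent line id to
#'   its seed-size class (`"large"` or `"small"`).
#' @return a data.frame with columns `line_id`, `maternal`, `paternal`,
#'   `seed_class` (the class of the maternal parent).
#' @examples
#' bean_lines()
#' @export
bean_lines <- function() {
  line_pedigree(
    line_id  = c("G19833", "G19833xG23419", "G23419xG19833", "G23419"),
    maternal = c("G19833", "G19833",        "G23419",        "G23419"),
    paternal = c("G19833", "G23419",        "G19833",        "G23419"),
    parent_class = c(G19833 = "large", G23419 = "small")
  )
}

#' @rdname bean_lines
#' @export
line_pedigree <- function(line_id, maternal, paternal, parent_class) {
  stopifnot(length(line_id) == length(maternal),
            length(line_id) == length(paternal))
  if (anyDuplicated(line_id)) stop("duplicated line_id", call. = FALSE)
  if (!all(sort(unique(parent_class)) %in% c("large", "small")) ||
      !all(c("large", "small") %in% parent_class))
    stop("parent_class must assign both 'large' and 'small'", call. = FALSE)
  missing_parents <- setdiff(unique(c(maternal, paternal)), names(parent_class))
  if (length(missing_parents))
    stop("no seed-size class for parent(s): ",
         paste(missing_parents, collapse = ", "), call. = FALSE)
  data.frame(
    line_id = line_id, maternal = maternal, paternal = paternal,
    seed_class = unname(parent_class[maternal]),
    stringsAsFactors = FALSE
  )
}

validate_pedigree <- function(lines) {
  need <- c("line_id", "maternal", "paternal", "seed_class")
  if (!is.data.frame(lines) || !all(need %in% names(lines)))
    stop("'lines' must be a pedigree data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(lines) != 4L)
    stop("the design requires exactly four lines ",
         "(two selfed parents and two reciprocal F1s), got ", nrow(lines),
         call. = FALSE)
  selfed <- lines$maternal == lines$paternal
  if (sum(selfed) != 2L)
    stop("expected exactly two selfed parental lines", call. = FALSE)
  parents <- lines$line_id[selfed]
  f1 <- lines[!selfed, , drop = FALSE]
  ok_f1 <- setequal(f1$maternal, parents) && setequal(f1$paternal, parents) &&
    all(f1$maternal != f1$paternal)
  if (!ok_f1)
    stop("the two non-selfed lines must be reciprocal F1s of the parents",
         call. = FALSE)
  if (length(unique(lines$seed_class[selfed])) != 2L)
    stop("the two parents must have contrasting seed-size classes",
         call. = FALSE)
  lines
}

#' Genetic grouping hypotheses
#'
#' Each of the five grouping hypotheses partitions the four lines into
#' parameter levels: every line in a level shares one set of mean-curve
#' parameters.
#'
#' * `GEN4` — every genotype its own level (4 levels), distinguishing the
#'   reciprocal F1s from each other;
#' * `GEN3` — one level per nuclear genotype (3): each parent, and the two
#'   reciprocal F1s pooled;
#' * `MAPHE` — maternal seed-size phenotype (2): large vs small class;
#' * `MAHY` — parents pooled, each reciprocal F1 its own level (3);
#' * `UNI` — no differences among genotypes (1 level).
#'
#' @param name scheme name, one of `"GEN4"`, `"GEN3"`, `"MAPHE"`, `"MAHY"`,
#'   `"UNI"`.
#' @param lines pedigree data.frame as returned by [bean_lines()].
#' @return an object of class `grouping_scheme`: a list with elements `name`,
#'   `level_of` (named character vector line_id -> level label), `levels`
#'   (level labels in a stable order), and `lines`.
#' @examples
#' sch <- grouping_scheme("MAPHE")
#' sch$level_of
#' n_levels(sch)
#' @export
grouping_scheme <- function(name = c("GEN4", "GEN3", "MAPHE", "MAHY", "UNI"),
                            lines = bean_lines()) {
  name <- match.arg(name)
  lines <- validate_pedigree(lines)
  selfed <- lines$maternal == lines$paternal
  level_of <- switch(name,
    GEN4  = stats::setNames(lines$line_id, lines$line_id),
    GEN3  = stats::setNames(ifelse(selfed, lines$line_id, "F1"),
                            lines$line_id),
    MAPHE = stats::setNames(lines$seed_class, lines$line_id),
    MAHY  = stats::setNames(ifelse(selfed, "parental", lines$line_id),
                            lines$line_id),
    UNI   = stats::setNames(rep("all", nrow(lines)), lines$line_id)
  )
  structure(
    list(name = name, level_of = level_of,
         levels = unique(unname(level_of)), lines = lines),
    class = "grouping_scheme"
  )
}

#' @rdname grouping_scheme
#' @export
n_levels <- function(scheme) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  length(scheme$levels)
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat("Grouping scheme", x$name, "with", n_levels(x), "level(s):\n")
  for (lv in x$levels)
    cat("  ", lv, ": ",
        paste(names(x$level_of)[x$level_of == lv], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Total parameter count of a fitted grouping model
#'
#' Degrees of freedom bookkeeping: each parameter level estimates one full
#' set of mean-curve parameters, plus the nuisance (variance/correlation)
#' terms of the chosen covariance structure, which are shared across levels.
#' For the usual three-parameter families with an AR1 + exponential-variance
#' structure the nuisance count is 3 (sigma, rho, delta); a per-harvest
#' variance model with H harvests and no AR1 contributes 1 + (H - 1).
#'
#' @param scheme a [grouping_scheme()].
#' @param family mean-function family (determines parameters per level).
#' @param n_variance_terms number of estimated nuisance terms (including the
#'   residual scale sigma).
#' @param free_rate logical, passed to [family_params()].
#' @return integer total number of estimated parameters.
#' @examples
#' param_count(grouping_scheme("MAPHE"), "expolinear", 3)  # 9
#' param_count(grouping_scheme("GEN4"), "expolinear", 3)   # 15
#' @export
param_count <- function(scheme, family = "expolinear", n_variance_terms,
                        free_rate = FALSE) {
  stopifnot(inherits(scheme, "grouping_scheme"),
            is.numeric(n_variance_terms), n_variance_terms >= 0)
  n_levels(scheme) * length(family_params(family, free_rate)) +
    as.integer(n_variance_terms)
}

#' Partition refinement between grouping schemes
#'
#' `is_refinement(fine, coarse)` is `TRUE` when every level of `fine` lies
#' wholly inside one level of `coarse`, i.e. the coarse scheme can be obtained
#' by merging levels of the fine one.  GEN4 refines every scheme; UNI is a
#' coarsening of all.
#'
#' @param fine,coarse [grouping_scheme()] objects over the same lines.
#' @return logical.
#' @export
is_refinement <- function(fine, coarse) {
  stopifnot(inherits(fine, "grouping_scheme"),
            inherits(coarse, "grouping_scheme"))
  ids <- names(fine$level_of)
  if (!setequal(ids, names(coarse$level_of)))
    stop("schemes are over different line sets", call. = FALSE)
  ## each fine level must map into a single coarse level
  all(tapply(coarse$level_of[ids], fine$level_of[ids],
             function(z) length(unique(z)) == 1L))
}
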