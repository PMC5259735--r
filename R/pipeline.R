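#' Read and validate a long-format trait dataset
#'
#' Datasets are comma-separated UTF-8 text with a mandatory header and
#' columns `plant_id`, `line_id`, `day`, `trait`, `value`.  Validation
#' rejects duplicate `(plant_id, day, trait)` records, non-finite values,
#' negative days, and lines absent from the pedigree, reporting the
#' offending rows by line number.
#'
#' @param path file to read.
#' @param lines pedigree data.frame the `line_id` values must come from;
#'   `NULL` skips the pedigree check.
#' @return validated data.frame.
#' @export
read_dataset <- function(path, lines = bean_lines()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(d, lines)
}

#' @rdname read_dataset
#' @param data in-memory dataset to validate or write.
#' @export
validate_dataset <- function(data, lines = bean_lines()) {
  need <- c("plant_id", "line_id", "day", "trait", "value")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("dataset lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data$day <- as.numeric(data$day)
  data$value <- as.numeric(data$value)
  bad_rows <- function(sel) paste(which(sel), collapse = ", ")
  if (anyNA(data$day) || any(data$day < 0))
    stop("invalid day at row(s): ",
         bad_rows(is.na(data$day) | data$day < 0), call. = FALSE)
  if (anyNA(data$value) || any(!is.finite(data$value)))
    stop("non-finite value at row(s): ",
         bad_rows(!is.finite(data$value)), call. = FALSE)
  key <- paste(data$plant_id, data$day, data$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (plant_id, day, trait) at row(s): ",
         bad_rows(duplicated(key)), call. = FALSE)
  if (!is.null(lines)) {
    unknown <- setdiff(unique(data$line_id), lines$line_id)
    if (length(unknown))
      stop("line_id not in pedigree: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  data
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects the choices [run_full_analysis()] needs: the pedigree, the
#' trait-to-family mapping, per-trait covariance structures (AR1 +
#' exponential variance for repeated-measurement traits; independent
#' residuals with per-harvest variance strata for destructive cotyledon
#' decay; independent residuals with exponential variance for destructive
#' seedling dry weight), the schemes to compare, and the per-class seed
#' weights used for derived allocation statistics.
#'
#' @param lines pedigree data.frame.
#' @param families named trait -> family map, default [trait_family_map()].
#' @param covariance named list per trait:
#'   `list(correlation =, variance =)`; traits not listed use
#'   AR1 + varExp.
#' @param schemes scheme names to compare, coarsest first.
#' @param seed_weights named per-class seed weights (g) for allocation
#'   statistics.
#' @param control a [growth_control()].
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(lines = bean_lines(),
                            families = trait_family_map(),
                            covariance = NULL,
                            schemes = c("UNI", "MAPHE", "MAHY", "GEN3",
                                        "GEN4"),
                            seed_weights = c(large = 0.55, small = 0.10),
                            control = growth_control()) {
  default_cov <- list(
    CDW = list(correlation = "independent", variance = "varIdent"),
    SDLDW = list(correlation = "independent", variance = "varExp")
  )
  covariance <- utils::modifyList(default_cov,
                                  if (is.null(covariance)) list()
                                  else covariance)
  structure(list(lines = lines, families = families,
                 covariance = covariance, schemes = schemes,
                 seed_weights = seed_weights, control = control),
            class = "analysis_config")
}

cov_for_trait <- function(config, trait) {
  cv <- config$covariance[[trait]]
  if (is.null(cv)) cv <- list(correlation = "AR1", variance = "varExp")
  cv
}

#' Run the full multi-trait, multi-hypothesis analysis
#'
#' For every trait present in the data, fits the mean-function family under
#' each grouping hypothesis with the configured covariance structure,
#' warm-starting each finer scheme from every already-fitted coarser scheme
#' (which enforces the likelihood-nesting order), and assembles an AICc
#' selection table, the best model's estimate table, and the derived
#' allocation statistics that the fitted asymptotes and seed weights allow.
#'
#' @param data validated long-format dataset (possibly several traits).
#' @param config an [analysis_config()].
#' @param endpoint_data optional data.frame (`line`, `value` or
#'   `line`, `trait`, `value`) of end-point measurements to compare with
#'   Tukey HSD.
#' @return list of class `analysis_report`: per-trait `selection`
#'   (selection_table), `best` (scheme name), `estimates` (best-model
#'   estimate table), `fits`; plus `allocation`, `endpoints` and `meta`.
#' @export
run_full_analysis <- function(data, config = analysis_config(),
                              endpoint_data = NULL) {
  data <- validate_dataset(data, config$lines)
  traits <- unique(data$trait)
  if (!length(traits)) stop("dataset contains no trait records", call. = FALSE)
  schemes <- lapply(config$schemes, grouping_scheme, lines = config$lines)
  names(schemes) <- config$schemes
  ## fit coarse before fine so warm starts are available
  ord <- order(vapply(schemes, n_levels, numeric(1)))
  schemes <- schemes[ord]

  per_trait <- list()
  for (tr in traits) {
    fam <- if (tr %in% names(config$families)) config$families[[tr]] else NULL
    if (is.null(fam))
      stop("no family configured for trait '", tr, "'", call. = FALSE)
    cv <- cov_for_trait(config, tr)
    d <- data[data$trait == tr, , drop = FALSE]
    fits <- list()
    failed <- character(0)
    for (nm in names(schemes)) {
      sch <- schemes[[nm]]
      ## candidate warm starts from every coarser fitted scheme
      warm <- NULL
      for (prev in fits)
        if (is_refinement(sch, prev$scheme) &&
            (is.null(warm) || prev$logLik > warm$logLik)) warm <- prev
      start <- if (!is.null(warm)) expand_start(warm, sch) else NULL
      f <- tryCatch(
        fit_growth(d, fam, sch, correlation = cv$correlation,
                   variance = cv$variance, start = start, trait = tr,
                   control = config$control),
        error = function(e) e)
      if (inherits(f, "error")) { failed <- c(failed, nm); next }
      fits[[nm]] <- f
    }
    if (!length(fits))
      stop("all scheme fits failed for trait '", tr, "'", call. = FALSE)
    sel <- selection_table(fits)
    best <- fits[[sel$scheme[1L]]]
    per_trait[[tr]] <- list(
      selection = sel, best = sel$scheme[1L],
      estimates = estimates_table(best), fits = fits,
      converged = vapply(fits, function(f) f$converged, logical(1)),
      failed = failed)
  }

  report <- list(
    traits = per_trait,
    allocation = derive_allocation(per_trait, config$seed_weights),
    endpoints = if (!is.null(endpoint_data))
      run_endpoints(endpoint_data) else NULL,
    meta = list(schemes = names(schemes),
                seed = config$control$seed,
                rel_tol = config$control$rel_tol,
                package_version = as.character(utils::packageVersion("growsel")))
  )
  class(report) <- "analysis_report"
  report
}

run_endpoints <- function(endpoint_data) {
  if (!"trait" %in% names(endpoint_data)) endpoint_data$trait <- "endpoint"
  lapply(split(endpoint_data, endpoint_data$trait), endpoint_compare)
}

## derived allocation statistics available from fitted best models
derive_allocation <- function(per_trait, seed_weights) {
  get_level_par <- function(trait, par) {
    pt <- per_trait[[trait]]
    if (is.null(pt)) return(NULL)
    est <- pt$estimates
    est <- est[est$parameter == par, c("level", "estimate")]
    if (!nrow(est)) NULL else stats::setNames(est$estimate, est$level)
  }
  out <- list()
  for (tr in intersect(c("PRL", "AvBRL", "TRL", "LAREA"), names(per_trait))) {
    wf <- get_level_par(tr, "Wf")
    if (is.null(wf)) next
    common <- intersect(names(wf), names(seed_weights))
    if (length(common))
      out[[paste0(tr, "_per_gram")]] <-
        allocation_per_gram(wf[common], seed_weights[common])
  }
  sdl <- get_level_par("SDLDW", "Wf")
  cot <- get_level_par("CDW", "Max")
  if (!is.null(sdl) && !is.null(cot)) {
    common <- intersect(names(sdl), names(cot))
    if (length(common))
      out$remobilization_efficiency <-
        remobilization_efficiency(sdl[common], cot[common])
  }
  if (length(out)) out else NULL
}

#' @export
print.analysis_report <- function(x, ...) {
  for (tr in names(x$traits)) {
    cat("==", tr, "(best:", x$traits[[tr]]$best, ")==\n")
    print(x$traits[[tr]]$selection)
  }
  if (!is.null(x$allocation)) {
    cat("\nDerived allocation statistics:\n")
    utils::str(x$allocation, give.attr = FALSE)
  }
  invisible(x)
}

#' Render an analysis report to files
#'
#' Writes the per-trait selection tables (columns `scheme`, `df`, `logL`,
#' `AICc`, `dAICc`, `wAICc`, `ER`, `support`) and best-model estimate tables
#' (columns `parameter`, `level`, `estimate`, `se`, `ll95`, `ul95`), in the
#' requested format: `"csv"` one delimited file per table, `"json"` a single
#' machine-readable `report.json`, `"md"` a human-readable markdown summary.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if absent).
#' @param format `"csv"`, `"json"` or `"md"`.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, dir, format = c("csv", "json", "md")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(0)
  if (format == "csv") {
    for (tr in names(report$traits)) {
      p1 <- file.path(dir, paste0("selection_", tr, ".csv"))
      utils::write.csv(as.data.frame(report$traits[[tr]]$selection), p1,
                       row.names = FALSE, quote = FALSE)
      p2 <- file.path(dir, paste0("estimates_", tr, ".csv"))
      utils::write.csv(report$traits[[tr]]$estimates, p2,
                       row.names = FALSE, quote = FALSE)
      paths <- c(paths, p1, p2)
    }
    if (!is.null(report$allocation)) {
      p <- file.path(dir, "allocation.csv")
      al <- do.call(rbind, lapply(names(report$allocation), function(nm)
        data.frame(statistic = nm, level = names(report$allocation[[nm]]),
                   value = as.numeric(report$allocation[[nm]]))))
      utils::write.csv(al, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  } else if (format == "json") {
    p <- file.path(dir, "report.json")
    slim <- list(
      traits = lapply(report$traits, function(pt)
        list(selection = as.data.frame(pt$selection), best = pt$best,
             estimates = pt$estimates, converged = as.list(pt$converged))),
      allocation = report$allocation,
      meta = report$meta)
    jsonlite::write_json(slim, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- p
  } else {
    p <- file.path(dir, "report.md")
    con <- file(p, "w"); on.exit(close(con))
    for (tr in names(report$traits)) {
      pt <- report$traits[[tr]]
      cat("## ", tr, " (best model: ", pt$best, ")\n\n", sep = "", file = con)
      cat(knit_table(as.data.frame(pt$selection)), "\n", file = con)
      cat("\nBest-model estimates:\n\n", file = con)
      cat(knit_table(pt$estimates), "\n\n", file = con)
    }
    paths <- p
  }
  invisible(paths)
}

## minimal markdown table writer
knit_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 4, format = "g")
                     else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  rule <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(cells, 1L, function(r) paste("|", paste(r, collapse = " | "),
                                             "|"))
  paste(c(header, rule, body), collapse = "\n")
}
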