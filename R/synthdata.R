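#' Default parameter library
#'
#' Reference values used as simulation truth and reporting defaults: per
#' seed-size class growth-curve estimates (with their standard errors) for
#' the seven dynamic traits, seed-descriptor means and standard errors for
#' the four lines (30-seed samples), and the nominal per-class seed weights.
#' Root and shoot traits are measured non-destructively every other day up
#' to day 12; dry-weight traits come from destructive harvests (one plant
#' per observation).
#'
#' @return a list with elements `lines` (pedigree), `seed_traits`
#'   (data.frame `line`, `trait`, `mean`, `se`, `n`), `growth` (per-trait
#'   list: `family`, `destructive`, `params`/`se` per seed-size class) and
#'   `seed_weight` (named per-class weights, g).
#' @examples
#' default_parameter_library()$growth$TRL$params$large
#' @export
default_parameter_library <- function() {
  g <- list(
    TRL = list(
      family = "expolinear", destructive = FALSE, unit = "cm",
      params = list(large = c(Cm = 149.52, Rm = 0.92, tb = 6.22),
                    small = c(Cm = 84.86, Rm = 0.65, tb = 6.14)),
      se = list(large = c(Cm = 6.89, Rm = 0.11, tb = 0.18),
                small = c(Cm = 8.60, Rm = 0.11, tb = 0.48))),
    FORK = list(
      family = "expolinear", destructive = FALSE, unit = "count",
      params = list(large = c(Cm = 317.59, Rm = 1.25, tb = 6.72),
                    small = c(Cm = 131.78, Rm = 0.74, tb = 6.37)),
      se = list(large = c(Cm = 23.00, Rm = 0.18, tb = 0.20),
                small = c(Cm = 27.62, Rm = 0.17, tb = 0.79))),
    PRL = list(
      family = "gompertz", destructive = FALSE, unit = "cm",
      params = list(large = c(Wf = 26.99, k = 0.26, TT = 5.51),
                    small = c(Wf = 19.64, k = 0.29, TT = 3.18)),
      se = list(large = c(Wf = 1.29, k = 0.02, TT = 0.24),
                small = c(Wf = 1.00, k = 0.03, TT = 0.28))),
    AvBRL = list(
      family = "gompertz", destructive = FALSE, unit = "cm",
      params = list(large = c(Wf = 12.93, k = 0.33, TT = 5.84),
                    small = c(Wf = 6.09, k = 0.37, TT = 4.90)),
      se = list(large = c(Wf = 0.81, k = 0.02, TT = 0.17),
                small = c(Wf = 0.67, k = 0.05, TT = 0.28))),
    LAREA = list(
      family = "gompertz", destructive = FALSE, unit = "cm2",
      params = list(large = c(Wf = 46.90, k = 0.64, TT = 8.33),
                    small = c(Wf = 28.39, k = 0.62, TT = 8.06)),
      se = list(large = c(Wf = 2.49, k = 0.08, TT = 0.14),
                small = c(Wf = 2.51, k = 0.14, TT = 0.24))),
    CDW = list(
      family = "decay", destructive = TRUE, unit = "g",
      params = list(large = c(Max = 0.436, Min = 0.058, TT = 6.012),
                    small = c(Max = 0.121, Min = 0.011, TT = 2.727)),
      se = list(large = c(Max = 0.015, Min = 0.004, TT = 0.192),
                small = c(Max = 0.057, Min = 0.004, TT = 0.951))),
    SDLDW = list(
      family = "gompertz", destructive = TRUE, unit = "g",
      params = list(large = c(Wf = 0.55, k = 0.26, TT = 7.28),
                    small = c(Wf = 0.19, k = 0.24, TT = 7.35)),
      se = list(large = c(Wf = 0.04, k = 0.02, TT = 0.33),
                small = c(Wf = 0.04, k = 0.06, TT = 1.16)))
  )
  lines <- bean_lines()
  traits <- c("weight", "length", "width", "height", "area", "perimeter",
              "circularity", "aspect_ratio")
  means <- rbind(
    G19833          = c(0.55, 7.71, 5.88, 15.6, 1.20, 4.90, 0.64, 1.89),
    G19833xG23419   = c(0.52, 7.63, 5.87, 15.2, 1.19, 4.86, 0.61, 1.90),
    G23419xG19833   = c(0.101, 5.37, 2.94, 7.8, 0.39, 2.54, 0.77, 1.48),
    G23419          = c(0.10, 5.28, 2.98, 7.7, 0.40, 2.56, 0.76, 1.48)
  )
  ses <- c(0.01, 0.08, 0.06, 0.15, 0.02, 0.09, 0.02, 0.02)
  seed_traits <- data.frame(
    line = rep(rownames(means), each = length(traits)),
    trait = rep(traits, times = nrow(means)),
    mean = as.vector(t(means)),
    se = rep(ses, times = nrow(means)),
    n = 30L,
    stringsAsFactors = FALSE
  )
  list(lines = lines, seed_traits = seed_traits, growth = g,
       seed_weight = c(large = 0.55, small = 0.10))
}

#' Default trait-to-family mapping
#'
#' Total root length and branch counts follow the expolinear curve; primary
#' and basal root length, leaf area and seedling dry weight follow the
#' Gompertz curve; cotyledon dry weight follows the decay curve.
#'
#' @return named character vector trait -> family.
#' @export
trait_family_map <- function() {
  c(TRL = "expolinear", FORK = "expolinear", PRL = "gompertz",
    AvBRL = "gompertz", LAREA = "gompertz", SDLDW = "gompertz",
    CDW = "decay")
}

#' Simulation configuration
#'
#' Assembles the truth and design of a synthetic dataset.  Defaults emulate
#' the study design the package targets: four lines (two parents, two
#' reciprocal F1s) whose trait trajectories differ by maternal seed-size
#' class (MAPHE truth) with the library estimates as true parameters;
#' non-destructive traits are measured on the same plants every other day
#' from day 2 to 12 with AR1-correlated residuals (`rho = 0.5`) whose
#' standard deviation grows exponentially with the day (`delta = 0.2` per
#' day); destructive traits harvest independent plants every other day (from
#' day 0 for cotyledon reserves) with per-harvest variance strata.
#'
#' The noise scale is set through `cv`: the residual standard deviation at
#' the final measurement day equals `cv` times the mean trajectory value at
#' that day (averaged over truth levels).  Pass `sigma` to fix that final-day
#' standard deviation absolutely instead.
#'
#' @param trait trait name; when it is one of the library traits the family,
#'   destructive flag and truth parameters default from
#'   [default_parameter_library()].
#' @param family mean-function family (required for non-library traits).
#' @param truth_scheme grouping scheme (or name) whose levels index
#'   `truth_params`; default MAPHE.
#' @param truth_params named list of per-level true parameter vectors;
#'   default from the library (library truths are per seed-size class, so
#'   non-MAPHE truth schemes need explicit parameters).
#' @param lines pedigree data.frame, default [bean_lines()].
#' @param plants_per_line plants per line (non-destructive) or per line and
#'   harvest (destructive); default 14.
#' @param days measurement days; default `seq(2, 12, 2)`, or `seq(0, 12, 2)`
#'   for destructive decay traits.
#' @param destructive logical; one observation per plant.
#' @param rho AR1 coefficient for within-plant residuals (non-destructive
#'   designs); 0 gives independent residuals.
#' @param variance `"varExp"`, `"varIdent"` or `"constant"`; defaults to
#'   varExp for repeated measurements and varIdent for destructive designs.
#' @param delta exponential variance coefficient (per day).
#' @param ratios named per-harvest sd ratios for varIdent (first day 1);
#'   default all 1.
#' @param cv final-day residual coefficient of variation (default 0.10).
#' @param sigma absolute final-day residual sd; overrides `cv`.
#' @param truncate_negative logical; clamp negative simulated values at zero
#'   (off by default because truncation biases the Gaussian error model the
#'   fitting layer assumes; the number clamped is recorded when on).
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(trait = "TRL", family = NULL, truth_scheme = "MAPHE",
                       truth_params = NULL, lines = bean_lines(),
                       plants_per_line = 14L, days = NULL,
                       destructive = NULL, rho = 0.5, variance = NULL,
                       delta = 0.2, ratios = NULL, cv = 0.10, sigma = NULL,
                       truncate_negative = FALSE, seed = 1L) {
  lib <- default_parameter_library()
  in_lib <- trait %in% names(lib$growth)
  if (is.null(family))
    family <- if (in_lib) lib$growth[[trait]]$family
              else stop("unknown trait '", trait, "': supply 'family'",
                        call. = FALSE)
  family <- match.arg(family, growth_families())
  if (is.null(destructive))
    destructive <- if (in_lib) lib$growth[[trait]]$destructive else FALSE
  if (is.character(truth_scheme))
    truth_scheme <- grouping_scheme(truth_scheme, lines)
  if (is.null(truth_params)) {
    if (!in_lib || truth_scheme$name != "MAPHE")
      stop("default truth parameters exist only for library traits under ",
           "the MAPHE scheme; supply 'truth_params'", call. = FALSE)
    truth_params <- lib$growth[[trait]]$params
  }
  missing_lv <- setdiff(truth_scheme$levels, names(truth_params))
  if (length(missing_lv))
    stop("truth_params lacks level(s): ", paste(missing_lv, collapse = ", "),
         call. = FALSE)
  if (is.null(days))
    days <- if (destructive && family == "decay") seq(0, 12, by = 2)
            else seq(2, 12, by = 2)
  days <- sort(unique(as.numeric(days)))
  if (any(days < 0)) stop("days must be non-negative", call. = FALSE)
  if (is.null(variance)) variance <- if (destructive) "varIdent" else "varExp"
  variance <- match.arg(variance, c("varExp", "varIdent", "constant"))
  if (variance == "varIdent" && is.null(ratios))
    ratios <- stats::setNames(rep(1, length(days)), as.character(days))
  if (!destructive && (!is.finite(rho) || abs(rho) >= 1))
    stop("rho must lie in (-1, 1)", call. = FALSE)
  structure(list(
    trait = trait, family = family, truth_scheme = truth_scheme,
    truth_params = truth_params, lines = validate_pedigree(lines),
    plants_per_line = as.integer(plants_per_line), days = days,
    destructive = isTRUE(destructive), rho = if (destructive) 0 else rho,
    variance = variance, delta = delta, ratios = ratios, cv = cv,
    sigma = sigma, truncate_negative = isTRUE(truncate_negative),
    seed = as.integer(seed)
  ), class = "sim_config")
}

## residual sd at each day implied by a config (anchored at the final day)
config_noise_sd <- function(config) {
  final_means <- vapply(config$truth_params[config$truth_scheme$levels],
                        function(p) growth_value(config$family, p,
                                                 max(config$days)),
                        numeric(1))
  sd_final <- if (!is.null(config$sigma)) config$sigma
              else config$cv * mean(final_means)
  v <- switch(config$variance,
    constant = rep(1, length(config$days)),
    varExp   = exp(config$delta * (config$days - max(config$days))),
    varIdent = {
      r <- config$ratios[as.character(config$days)]
      r / r[[length(r)]]
    })
  stats::setNames(sd_final * as.numeric(v), as.character(config$days))
}

#' Simulate longitudinal trait trajectories
#'
#' Draws one AR1-correlated, heteroskedastic Gaussian residual series per
#' plant around the true mean trajectory of its line's parameter level and
#' returns a long-format dataset.  Reproducible given `config$seed`.
#'
#' @param config a [sim_config()] with `destructive = FALSE`.
#' @return data.frame with columns `plant_id`, `line_id`, `day`, `trait`,
#'   `value`.  When `truncate_negative` is on, the number of clamped values
#'   is in attribute `"n_truncated"`.
#' @examples
#' head(simulate_trajectories(sim_config("TRL", plants_per_line = 2)))
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$destructive)
    stop("config is destructive; use simulate_destructive()", call. = FALSE)
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)
  sd_day <- config_noise_sd(config)
  nd <- length(config$days)
  rows <- list()
  for (li in config$lines$line_id) {
    lv <- config$truth_scheme$level_of[[li]]
    mu <- growth_value(config$family, config$truth_params[[lv]], config$days)
    for (p in seq_len(config$plants_per_line)) {
      z <- stats::rnorm(nd)
      e <- numeric(nd)
      e[1] <- z[1]
      if (nd > 1) for (j in 2:nd)
        e[j] <- config$rho * e[j - 1] + sqrt(1 - config$rho^2) * z[j]
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = sprintf("%s_p%02d", li, p), line_id = li,
        day = config$days, trait = config$trait,
        value = mu + sd_day * e, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  finish_sim(out, config)
}

#' Simulate destructive harvest data
#'
#' Each harvest day measures an independent set of plants (one observation
#' per plant), with per-harvest residual standard deviations following the
#' configured variance strata.
#'
#' @param config a [sim_config()] with `destructive = TRUE`;
#'   `plants_per_line` plants are harvested per line and day.
#' @return long-format data.frame as in [simulate_trajectories()].
#' @export
simulate_destructive <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$destructive)
    stop("config is not destructive; use simulate_trajectories()",
         call. = FALSE)
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)
  sd_day <- config_noise_sd(config)
  rows <- list()
  for (li in config$lines$line_id) {
    lv <- config$truth_scheme$level_of[[li]]
    for (d in config$days) {
      mu <- growth_value(config$family, config$truth_params[[lv]], d)
      n <- config$plants_per_line
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = sprintf("%s_d%02g_p%02d", li, d, seq_len(n)),
        line_id = li, day = d, trait = config$trait,
        value = mu + stats::rnorm(n, 0, sd_day[[as.character(d)]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  finish_sim(out, config)
}

finish_sim <- function(out, config) {
  if (config$truncate_negative) {
    n_trunc <- sum(out$value < 0)
    out$value[out$value < 0] <- 0
    attr(out, "n_truncated") <- n_trunc
    if (n_trunc > 0)
      message(n_trunc, " negative simulated value(s) truncated at 0")
  }
  out
}

#' Simulate end-point seed descriptors
#'
#' Independent normal draws per line and trait with the library means and a
#' per-seed standard deviation of `se * sqrt(n_ref)` (the library standard
#' errors come from samples of 30 seeds).
#'
#' @param lines line ids to simulate (default: all four library lines).
#' @param n seeds per line (>= 2), default 30.
#' @param traits which descriptors to draw (default `"weight"`).
#' @param seed integer RNG seed.
#' @return data.frame with columns `line`, `trait`, `value`.
#' @examples
#' simulate_seed_traits(n = 5, seed = 1)
#' @export
simulate_seed_traits <- function(lines = NULL, n = 30L, traits = "weight",
                                 seed = 1L) {
  lib <- default_parameter_library()
  st <- lib$seed_traits
  if (is.null(lines)) lines <- unique(st$line)
  unknown <- setdiff(lines, st$line)
  if (length(unknown))
    stop("unknown line(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  unknown_t <- setdiff(traits, st$trait)
  if (length(unknown_t))
    stop("unknown trait(s): ", paste(unknown_t, collapse = ", "),
         call. = FALSE)
  if (n < 2L) stop("need n >= 2 seeds per line", call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  rows <- list()
  for (li in lines) for (tr in traits) {
    row <- st[st$line == li & st$trait == tr, ]
    rows[[length(rows) + 1L]] <- data.frame(
      line = li, trait = tr,
      value = stats::rnorm(n, row$mean, row$se * sqrt(row$n)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
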