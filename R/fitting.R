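#' Control settings for the GNLS optimizer
#'
#' @param maxit maximum iterations per optimizer run.
#' @param rel_tol relative convergence tolerance on the objective.
#' @param n_starts maximum number of (jittered) starting points tried before
#'   declaring non-convergence.
#' @param seed integer seed used to draw jittered restarts (restarting is
#'   deterministic given the seed).
#' @param profile_sigma logical; profile the residual scale sigma out of the
#'   likelihood analytically (default) instead of optimizing it jointly.
#' @return a list of class `growth_control`.
#' @export
growth_control <- function(maxit = 500L, rel_tol = 1e-10, n_starts = 5L,
                           seed = 1L, profile_sigma = TRUE) {
  structure(list(maxit = as.integer(maxit), rel_tol = rel_tol,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 profile_sigma = isTRUE(profile_sigma)),
            class = "growth_control")
}

## ---- internal: fast likelihood machinery ---------------------------------
## Plants sharing the same ordered day vector share one covariance block;
## observations are grouped so each block is Cholesky-factorized once per
## likelihood evaluation.
build_lik_structure <- function(data) {
  o <- order(data$plant_id, data$day)
  data <- data[o, , drop = FALSE]
  sig <- tapply(data$day, data$plant_id, function(d) paste(d, collapse = ","))
  plant_sig <- unname(sig[as.character(data$plant_id)])
  groups <- lapply(split(seq_len(nrow(data)), plant_sig), function(idx) {
    ## rows are plant-major and day-ordered; every plant in the group shares
    ## the same day vector, so idx reshapes to one column per plant
    nd <- length(idx) / length(unique(data$plant_id[idx]))
    im <- matrix(idx, nrow = nd)
    list(idx = im, days = data$day[im[, 1L]])
  })
  list(data = data, groups = groups, n = nrow(data),
       max_per_plant = max(tabulate(factor(data$plant_id))))
}

## negative log-likelihood given mean vector mu and unit-sigma cov spec;
## returns list(nll, sigma2_hat) when profiling, else nll at given sigma
nll_from_structure <- function(str, mu, spec_unit, sigma = NULL) {
  r <- str$data$value - mu
  quad <- 0; logdet <- 0
  for (g in str$groups) {
    V <- plant_covariance(spec_unit, g$days)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(NULL)
    R <- matrix(r[g$idx], nrow = nrow(g$idx))
    Z <- backsolve(L, R, transpose = TRUE)
    quad <- quad + sum(Z * Z)
    logdet <- logdet + ncol(g$idx) * 2 * sum(log(diag(L)))
  }
  n <- str$n
  if (is.null(sigma)) {
    sigma2 <- quad / n
    list(nll = 0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n),
         sigma2 = sigma2)
  } else {
    list(nll = 0.5 * (n * log(2 * pi) + n * log(sigma^2) + logdet +
                        quad / sigma^2),
         sigma2 = sigma^2)
  }
}

## ---- internal: parameter transforms --------------------------------------
## positive parameters are optimized on the log scale, rho through atanh;
## decay uses (log(Max - Min), log Min, TT[, log rate]) so Max > Min >= 0
## holds throughout the search.
theta_names <- function(family, levels, free_rate) {
  pn <- family_params(family, free_rate)
  as.vector(outer(pn, levels, paste, sep = "."))
}

encode_mean <- function(family, mean_params, levels, free_rate) {
  unlist(lapply(levels, function(lv) {
    p <- mean_params[[lv]]
    switch(family,
      expolinear = c(log(p[["Cm"]]), log(p[["Rm"]]), p[["tb"]]),
      gompertz   = c(log(p[["Wf"]]), log(p[["k"]]), p[["TT"]]),
      decay      = {
        base <- c(log(p[["Max"]] - p[["Min"]]), log(max(p[["Min"]], 1e-8)),
                  p[["TT"]])
        if (free_rate) c(base, log(p[["rate"]])) else base
      })
  }))
}

decode_mean <- function(family, th, levels, free_rate) {
  np <- length(family_params(family, free_rate))
  out <- stats::setNames(vector("list", length(levels)), levels)
  for (i in seq_along(levels)) {
    v <- th[(i - 1L) * np + seq_len(np)]
    out[[levels[i]]] <- switch(family,
      expolinear = c(Cm = exp(v[1]), Rm = exp(v[2]), tb = v[3]),
      gompertz   = c(Wf = exp(v[1]), k = exp(v[2]), TT = v[3]),
      decay      = {
        p <- c(Max = exp(v[2]) + exp(v[1]), Min = exp(v[2]), TT = v[3])
        if (free_rate) c(p, rate = exp(v[4])) else p
      })
  }
  out
}

## nuisance vector layout (transformed): atanh(rho) | delta | log ratios[-1]
encode_nuisance <- function(correlation, variance, rho, delta, ratios,
                            sigma = NULL) {
  out <- numeric(0)
  if (correlation == "AR1") out <- c(out, z_rho = atanh(rho))
  if (variance == "varExp") out <- c(out, delta = delta)
  if (variance == "varIdent" && length(ratios) > 1L) {
    lr <- log(ratios[-1L])
    names(lr) <- paste0("lr_", names(ratios)[-1L])
    out <- c(out, lr)
  }
  if (!is.null(sigma)) out <- c(out, log_sigma = log(sigma))
  out
}

decode_nuisance <- function(eta, correlation, variance, strata_days,
                            with_sigma = FALSE) {
  eta <- unname(eta)
  i <- 0L
  rho <- NULL; delta <- NULL; ratios <- NULL; sigma <- NULL
  if (correlation == "AR1") { i <- i + 1L; rho <- tanh(eta[i]) }
  if (variance == "varExp") { i <- i + 1L; delta <- eta[i] }
  if (variance == "varIdent") {
    h <- length(strata_days)
    rr <- if (h > 1L) exp(eta[i + seq_len(h - 1L)]) else numeric(0)
    i <- i + max(h - 1L, 0L)
    ratios <- stats::setNames(c(1, rr), as.character(strata_days))
  }
  if (with_sigma) { i <- i + 1L; sigma <- exp(eta[i]) }
  list(rho = rho, delta = delta, ratios = ratios, sigma = sigma)
}

#' Self-starting initial values for the growth families
#'
#' Derives per-level starting parameters from the per-day level means:
#' expolinear takes the late linear slope (`Cm`), its x-intercept (`tb`) and
#' the early log-linear slope (`Rm`); Gompertz takes 1.05x the maximum
#' response (`Wf`), the day whose mean is closest to `Wf/e` (`TT`) and a
#' log-log regression slope (`k`); decay takes the first/last harvest means
#' (`Max`/`Min`) and the interpolated mid-point crossing (`TT`).
#'
#' @param family mean-function family.
#' @param data long-format data with columns `line_id`, `day`, `value`.
#' @param scheme a [grouping_scheme()].
#' @param free_rate logical; include a starting decay `rate` (1).
#' @return named list of per-level starting parameter vectors.
#' @export
initial_values <- function(family, data, scheme, free_rate = FALSE) {
  family <- match.arg(family, growth_families())
  data <- check_fit_data(data, scheme)
  lev <- scheme$level_of[as.character(data$line_id)]
  out <- stats::setNames(vector("list", n_levels(scheme)), scheme$levels)
  for (lv in scheme$levels) {
    d <- data[lev == lv, , drop = FALSE]
    if (nrow(d) < 3L)
      stop("fewer than 3 observations for level '", lv, "'", call. = FALSE)
    ybar <- tapply(d$value, d$day, mean)
    days <- as.numeric(names(ybar))
    o <- order(days); days <- days[o]; ybar <- as.numeric(ybar[o])
    nd <- length(days)
    out[[lv]] <- switch(family,
      expolinear = {
        if (nd < 2L) stop("need >= 2 distinct days", call. = FALSE)
        Cm0 <- (ybar[nd] - ybar[nd - 1L]) / (days[nd] - days[nd - 1L])
        Cm0 <- max(Cm0, 0.05 * max(abs(ybar)) / diff(range(days)), 1e-6)
        tb0 <- days[nd] - ybar[nd] / Cm0
        early <- seq_len(max(2L, floor(nd / 2)))
        pos <- early[ybar[early] > 0]
        Rm0 <- if (length(pos) >= 2L)
          stats::coef(stats::lm(log(ybar[pos]) ~ days[pos]))[[2]] else 0.5
        Rm0 <- min(max(Rm0, 0.05), 5)
        c(Cm = Cm0, Rm = Rm0, tb = tb0)
      },
      gompertz = {
        Wf0 <- 1.05 * max(ybar)
        if (Wf0 <= 0) Wf0 <- 1e-6
        TT0 <- days[which.min(abs(ybar - Wf0 / exp(1)))]
        frac <- pmin(pmax(ybar / Wf0, 1e-6), 0.99)
        zz <- log(-log(frac))
        k0 <- -stats::coef(stats::lm(zz ~ days))[[2]]
        k0 <- min(max(k0, 0.02), 5)
        c(Wf = Wf0, k = k0, TT = TT0)
      },
      decay = {
        Max0 <- ybar[1L]; Min0 <- ybar[nd]
        if (Max0 <= Min0) { Max0 <- max(ybar); Min0 <- min(ybar) }
        if (Max0 <= Min0) Max0 <- Min0 + 1e-6
        Min0 <- max(Min0, 1e-8)
        mid <- (Max0 + Min0) / 2
        below <- which(ybar <= mid)
        TT0 <- if (length(below) && below[1L] > 1L) {
          i <- below[1L]
          days[i - 1L] + (days[i] - days[i - 1L]) *
            (ybar[i - 1L] - mid) / (ybar[i - 1L] - ybar[i])
        } else stats::median(days)
        p <- c(Max = unname(Max0), Min = unname(Min0), TT = unname(TT0))
        if (free_rate) c(p, rate = 1) else p
      })
  }
  out
}

#' Fit a grouped growth model by maximum likelihood
#'
#' Generalized non-linear least squares: the chosen mean-function family gets
#' one parameter set per level of the grouping scheme, residuals within a
#' plant follow the structured covariance of [cov_spec()] (optional AR1
#' correlation, variance function), and all parameters are estimated jointly
#' by full maximum likelihood.  The residual scale sigma is profiled out
#' analytically by default.  Optimization is quasi-Newton (`nlminb`) on
#' transformed parameters (log for positive parameters, atanh for the AR1
#' coefficient); if a run fails to converge, up to `control$n_starts` seeded
#' jittered restarts are tried, and the convergence flag reports the outcome
#' honestly.
#'
#' @param data long-format data.frame with columns `plant_id`, `line_id`,
#'   `day`, `value` (single trait).
#' @param family mean-function family, see [growth_families()].
#' @param scheme a [grouping_scheme()] (or scheme name, resolved against the
#'   default pedigree).
#' @param correlation,variance covariance structure choices, see [cov_spec()].
#'   An AR1 structure requires at least one plant with repeated measurements.
#' @param start optional named list of per-level starting mean parameters
#'   (e.g. a warm start expanded from a coarser fit, see [expand_start()]).
#' @param free_rate logical; estimate the decay steepness `rate` instead of
#'   fixing it at 1 per day.
#' @param trait optional trait label stored in the result.
#' @param control a [growth_control()] list.
#' @return an object of class `growth_fit` with the per-level estimates,
#'   nuisance estimates (sigma, rho, delta or stratum ratios), maximized
#'   log-likelihood, parameter count, standard errors and asymptotic 95%
#'   confidence bounds, and a `converged` flag.
#' @examples
#' sim <- simulate_trajectories(sim_config("TRL", plants_per_line = 4,
#'                                         seed = 1))
#' fit <- fit_growth(sim, "expolinear", grouping_scheme("MAPHE"))
#' coef(fit)
#' @export
fit_growth <- function(data, family, scheme,
                       correlation = c("AR1", "independent"),
                       variance = c("varExp", "varIdent", "constant"),
                       start = NULL, free_rate = FALSE, trait = NULL,
                       control = growth_control()) {
  family <- match.arg(family, growth_families())
  if (is.character(scheme)) scheme <- grouping_scheme(scheme)
  correlation <- match.arg(correlation)
  variance <- match.arg(variance)
  data <- check_fit_data(data, scheme)
  if (is.null(trait) && "trait" %in% names(data))
    trait <- as.character(data$trait[1L])

  days_all <- sort(unique(data$day))
  if (length(days_all) < 2L)
    stop("data contains a single measurement day; the trajectory is not ",
         "identifiable", call. = FALSE)
  str <- build_lik_structure(data)
  if (correlation == "AR1" && str$max_per_plant < 2L)
    stop("AR1 correlation requires at least one plant with repeated ",
         "measurements; use correlation = \"independent\"", call. = FALSE)
  strata_days <- if (variance == "varIdent") days_all else NULL

  levels <- scheme$levels
  np <- length(family_params(family, free_rate))
  n_mean <- np * length(levels)

  make_spec <- function(nu, sigma = 1) {
    cov_spec(correlation,
             rho = if (correlation == "AR1") nu$rho else NULL,
             variance = variance, delta = nu$delta, ratios = nu$ratios,
             sigma = sigma)
  }

  profile <- control$profile_sigma
  objective <- function(theta) {
    mp <- tryCatch(decode_mean(family, theta[seq_len(n_mean)], levels,
                               free_rate),
                   error = function(e) NULL)
    if (is.null(mp)) return(1e10)
    eta <- theta[-seq_len(n_mean)]
    nu <- decode_nuisance(eta, correlation, variance, strata_days,
                          with_sigma = !profile)
    if (correlation == "AR1" && abs(nu$rho) >= 1 - 1e-10) return(1e10)
    spec <- tryCatch(make_spec(nu), error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    mu <- tryCatch(model_mean(str$data, family, scheme, mp),
                   error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu))) return(1e10)
    res <- nll_from_structure(str, mu, spec,
                              sigma = if (profile) NULL else nu$sigma)
    if (is.null(res) || !is.finite(res$nll)) return(1e10)
    res$nll
  }

  ## starting points: user-supplied, self-start, then seeded jitters
  starts <- list()
  if (!is.null(start)) starts <- c(starts, list(start))
  self <- tryCatch(initial_values(family, data, scheme, free_rate),
                   error = function(e) NULL)
  if (!is.null(self)) starts <- c(starts, list(self))
  if (!length(starts))
    stop("no usable starting values", call. = FALSE)
  nu0 <- list(rho = if (correlation == "AR1") 0.2 else NULL,
              delta = if (variance == "varExp") 0.05 else NULL,
              ratios = if (variance == "varIdent")
                stats::setNames(rep(1, length(strata_days)),
                                as.character(strata_days)) else NULL)
  eta0 <- encode_nuisance(correlation, variance, nu0$rho, nu0$delta,
                          nu0$ratios, sigma = if (profile) NULL else 1)

  run_one <- function(theta0) {
    stats::nlminb(theta0, objective,
                  control = list(iter.max = control$maxit,
                                 eval.max = 4L * control$maxit,
                                 rel.tol = control$rel_tol))
  }
  jitter_theta <- function(theta0) {
    theta0 + stats::rnorm(length(theta0), 0, 0.15)
  }

  best <- NULL; tried <- 0L
  rng <- local_rng(control$seed)
  on.exit(rng(), add = TRUE)
  base_thetas <- lapply(starts, function(s) {
    th <- c(encode_mean(family, s, levels, free_rate), eta0)
    if (!profile) {
      ## start sigma at its profiled value for these mean parameters
      mu0 <- tryCatch(model_mean(str$data, family, scheme, s),
                      error = function(e) NULL)
      if (!is.null(mu0)) {
        nu <- decode_nuisance(eta0, correlation, variance, strata_days,
                              with_sigma = FALSE)
        spec0 <- tryCatch(make_spec(nu), error = function(e) NULL)
        prof <- if (!is.null(spec0))
          nll_from_structure(str, mu0, spec0) else NULL
        if (!is.null(prof) && is.finite(prof$sigma2) && prof$sigma2 > 0)
          th[["log_sigma"]] <- 0.5 * log(prof$sigma2)
      }
    }
    th
  })
  queue <- base_thetas
  while (tried < control$n_starts) {
    if (!length(queue))
      queue <- lapply(base_thetas[1L], jitter_theta)
    th0 <- queue[[1L]]; queue <- queue[-1L]
    tried <- tried + 1L
    ans <- tryCatch(run_one(th0), error = function(e) NULL)
    if (is.null(ans) || !is.finite(ans$objective)) next
    if (is.null(best) || ans$objective < best$objective - 1e-12) best <- ans
    if (best$convergence == 0 && best$objective < 1e9) break
  }
  if (is.null(best))
    stop("optimization failed from every starting point", call. = FALSE)
  ## polish: refit once from the optimum; accept only improvements.  The
  ## honest convergence criterion is that refitting from the returned
  ## estimates does not improve the objective beyond tolerance (nlminb's
  ## own code is unreliable for extremely well- or ill-scaled problems).
  polish <- tryCatch(run_one(best$par), error = function(e) NULL)
  improvement <- if (is.null(polish) || !is.finite(polish$objective)) Inf
                 else best$objective - polish$objective
  if (is.finite(improvement) && improvement >= 0) best <- polish
  converged <- best$objective < 1e9 &&
    (best$convergence == 0 ||
       (is.finite(improvement) &&
          abs(improvement) < max(1e-6, 1e-8 * abs(best$objective))))

  ## decode the optimum
  theta <- best$par
  mean_params <- decode_mean(family, theta[seq_len(n_mean)], levels,
                             free_rate)
  nu <- decode_nuisance(theta[-seq_len(n_mean)], correlation, variance,
                        strata_days, with_sigma = !profile)
  mu <- model_mean(str$data, family, scheme, mean_params)
  unit_spec <- make_spec(nu)
  final <- nll_from_structure(str, mu, unit_spec,
                              sigma = if (profile) NULL else nu$sigma)
  sigma_hat <- sqrt(final$sigma2)
  logLik <- -final$nll

  n_nuis <- 1L +                                   # sigma
    (correlation == "AR1") +
    (variance == "varExp") +
    (if (variance == "varIdent") length(strata_days) - 1L else 0L)
  df <- n_mean + n_nuis

  fit <- structure(list(
    trait = trait, family = family, scheme = scheme,
    correlation = correlation, variance = variance, free_rate = free_rate,
    mean_params = mean_params,
    sigma = sigma_hat, rho = nu$rho, delta = nu$delta, ratios = nu$ratios,
    logLik = logLik, df = df, n_obs = str$n,
    n_plants = length(unique(str$data$plant_id)),
    converged = converged, n_starts_used = tried,
    control = control, data = str$data
  ), class = "growth_fit")
  fit <- add_inference(fit, str)
  fit
}

## seeded local RNG: returns a restore function
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

## ---- inference: SEs, vcov, asymptotic CIs --------------------------------
## Mean-parameter covariance from the weighted Jacobian cross-product
## (J' Sigma^{-1} J)^{-1}; variance and mean parameters are asymptotically
## orthogonal in the Gaussian model, so nuisance SEs come from a numeric
## Hessian over the nuisance block alone.
add_inference <- function(fit, str) {
  scheme <- fit$scheme; levels <- scheme$levels
  pn <- family_params(fit$family, fit$free_rate)
  np <- length(pn)
  lev_row <- scheme$level_of[as.character(str$data$line_id)]
  n <- str$n
  J <- matrix(0, n, np * length(levels))
  colnames(J) <- theta_names(fit$family, levels, fit$free_rate)
  for (i in seq_along(levels)) {
    sel <- lev_row == levels[i]
    if (!any(sel)) next
    G <- growth_gradient(fit$family, fit$mean_params[[levels[i]]],
                         str$data$day[sel], fit$free_rate)
    J[sel, (i - 1L) * np + seq_len(np)] <- G
  }
  spec <- cov_spec(fit$correlation, rho = fit$rho, variance = fit$variance,
                   delta = fit$delta, ratios = fit$ratios, sigma = fit$sigma)
  A <- matrix(0, ncol(J), ncol(J))
  for (g in str$groups) {
    V <- plant_covariance(spec, g$days)
    L <- chol(V)
    for (j in seq_len(ncol(g$idx))) {
      Ji <- J[g$idx[, j], , drop = FALSE]
      Z <- backsolve(L, Ji, transpose = TRUE)
      A <- A + crossprod(Z)
    }
  }
  vcov_mean <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(vcov_mean)) {
    ev <- eigen(A, symmetric = TRUE)
    bad <- colnames(J)[which.min(abs(ev$values))]
    stop("singular information matrix; parameter '", bad,
         "' is not identifiable from these data", call. = FALSE)
  }
  dimnames(vcov_mean) <- list(colnames(J), colnames(J))
  est <- unlist(lapply(levels, function(lv)
    stats::setNames(fit$mean_params[[lv]][pn], paste(pn, lv, sep = "."))))
  se <- sqrt(pmax(diag(vcov_mean), 0))[names(est)]
  fit$coefficients <- est
  fit$vcov_mean <- vcov_mean
  fit$se <- se
  fit$nuisance_se <- nuisance_se(fit, str)
  z <- stats::qnorm(0.975)
  fit$ci <- cbind(ll95 = est - z * se, ul95 = est + z * se)
  rownames(fit$ci) <- names(est)
  fit
}

nuisance_se <- function(fit, str) {
  eta <- c(sigma = fit$sigma,
           if (fit$correlation == "AR1") c(rho = fit$rho),
           if (fit$variance == "varExp") c(delta = fit$delta),
           if (fit$variance == "varIdent" && length(fit$ratios) > 1L)
             stats::setNames(fit$ratios[-1L],
                             paste0("ratio_", names(fit$ratios)[-1L])))
  mu <- model_mean(str$data, fit$family, fit$scheme, fit$mean_params)
  strata <- if (fit$variance == "varIdent")
    as.numeric(names(fit$ratios)) else NULL
  f <- function(e) {
    i <- 1L
    sig <- e[i]
    rho <- if (fit$correlation == "AR1") { i <- i + 1L; e[i] } else NULL
    del <- if (fit$variance == "varExp") { i <- i + 1L; e[i] } else NULL
    rat <- if (fit$variance == "varIdent")
      stats::setNames(c(1, e[-seq_len(i)]), as.character(strata)) else NULL
    if (sig <= 0 || (!is.null(rho) && abs(rho) >= 1) ||
        (!is.null(rat) && any(rat <= 0))) return(1e10)
    ## nll_from_structure's sigma argument expects a unit-sigma spec
    spec1 <- tryCatch(
      cov_spec(fit$correlation, rho = rho, variance = fit$variance,
               delta = del, ratios = rat, sigma = 1),
      error = function(e) NULL)
    if (is.null(spec1)) return(1e10)
    res <- nll_from_structure(str, mu, spec1, sigma = sig)
    if (is.null(res)) 1e10 else res$nll
  }
  H <- tryCatch(stats::optimHess(eta, f), error = function(e) NULL)
  if (is.null(H)) return(stats::setNames(rep(NA_real_, length(eta)),
                                         names(eta)))
  V <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(V)) return(stats::setNames(rep(NA_real_, length(eta)),
                                         names(eta)))
  stats::setNames(sqrt(pmax(diag(V), 0)), names(eta))
}

#' Warm-start expansion from a coarser fit
#'
#' Maps the level estimates of a fitted coarser grouping onto the levels of a
#' finer scheme (each fine level inherits the parameters of the coarse level
#' containing it), giving a starting point that guarantees the finer model
#' starts at least at the coarser model's likelihood.
#'
#' @param fit a `growth_fit` under a coarser scheme.
#' @param fine a [grouping_scheme()] refined from the fit's scheme.
#' @return named list of per-level starting parameters for `fine`.
#' @export
expand_start <- function(fit, fine) {
  stopifnot(inherits(fit, "growth_fit"), inherits(fine, "grouping_scheme"))
  if (!is_refinement(fine, fit$scheme))
    stop("'fine' does not refine the fitted scheme", call. = FALSE)
  out <- stats::setNames(vector("list", n_levels(fine)), fine$levels)
  for (lv in fine$levels) {
    line <- names(fine$level_of)[fine$level_of == lv][1L]
    out[[lv]] <- fit$mean_params[[fit$scheme$level_of[[line]]]]
  }
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Generalized non-linear least squares fit",
      if (!is.null(x$trait)) paste0(" (", x$trait, ")"), "\n", sep = "")
  cat("  family:", x$family, "  scheme:", x$scheme$name,
      " levels:", paste(x$scheme$levels, collapse = "/"), "\n")
  cat("  covariance:", x$correlation, "+", x$variance, "\n")
  cat(sprintf("  logLik = %.3f on %d parameters (n = %d obs, %d plants)%s\n",
              x$logLik, x$df, x$n_obs, x$n_plants,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- estimates_table(x)
  tab[c("estimate", "se", "ll95", "ul95")] <-
    lapply(tab[c("estimate", "se", "ll95", "ul95")], round, digits = 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
vcov.growth_fit <- function(object, ...) object$vcov_mean

#' @export
confint.growth_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Tidy per-parameter estimate table of a fit
#'
#' @param fit a `growth_fit`.
#' @return data.frame with columns `parameter`, `level`, `estimate`, `se`,
#'   `ll95`, `ul95` (the layout used for reporting best-model estimates).
#' @export
estimates_table <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  pn <- family_params(fit$family, fit$free_rate)
  rows <- expand.grid(parameter = pn, level = fit$scheme$levels,
                      stringsAsFactors = FALSE)
  key <- paste(rows$parameter, rows$level, sep = ".")
  data.frame(rows,
             estimate = unname(fit$coefficients[key]),
             se = unname(fit$se[key]),
             ll95 = unname(fit$ci[key, "ll95"]),
             ul95 = unname(fit$ci[key, "ul95"]),
             stringsAsFactors = FALSE)
}
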