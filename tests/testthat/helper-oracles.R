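# Independent oracles used across tests.

# central finite-difference gradient of f at x (componentwise)
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

# dense multivariate-normal negative log-likelihood: builds the full
# block-diagonal covariance over all observations and evaluates the density
# with generic solve()/determinant(), independent of the package's
# per-block Cholesky path.
dense_mvn_nll <- function(data, family, scheme, mean_params, spec) {
  data <- data[order(data$plant_id, data$day), ]
  mu <- numeric(nrow(data))
  lev <- scheme$level_of[as.character(data$line_id)]
  for (lv in unique(lev)) {
    sel <- lev == lv
    mu[sel] <- growth_value(family, mean_params[[lv]], data$day[sel])
  }
  n <- nrow(data)
  Sigma <- matrix(0, n, n)
  for (pid in unique(data$plant_id)) {
    idx <- which(data$plant_id == pid)
    Sigma[idx, idx] <- plant_covariance(spec, data$day[idx])
  }
  r <- data$value - mu
  0.5 * (n * log(2 * pi) +
           as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
           drop(r %*% solve(Sigma, r)))
}

# small random-but-seeded dataset helper for likelihood tests
tiny_dataset <- function(n_plants = 3, days = c(2, 4, 6, 8), seed = 42) {
  set.seed(seed)
  lines <- bean_lines()$line_id
  do.call(rbind, lapply(seq_len(n_plants), function(i) {
    data.frame(plant_id = paste0("p", i),
               line_id = lines[(i - 1) %% 4 + 1],
               day = days, trait = "TRL",
               value = abs(rnorm(length(days), 50, 20)))
  }))
}
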