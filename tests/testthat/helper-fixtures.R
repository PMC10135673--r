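# Shared fixtures and independent scalar oracles.

# Two-taxon, two-feature affinity table used across allocation tests.
tiny_affinity <- function() {
  scores <- rbind(
    Baetidae  = c(deposit_feeder = 1L, scraper = 3L, gill = 5L, tegument = 0L),
    Ancylidae = c(deposit_feeder = 0L, scraper = 5L, gill = 2L, tegument = 2L))
  trait_affinity(scores, feature = c("feeding", "feeding", "respiration",
                                     "respiration"))
}

# Independent scalar diversity oracle: plain formula evaluation, written
# separately from the vectorized/vegan path in the package.
diversity_oracle <- function(abund) {
  abund <- abund[abund > 0]
  p <- abund / sum(abund)
  S <- length(abund)
  H <- -sum(p * log(p))
  list(H = H, D1 = 1 - sum(p^2), D2 = 1 / sum(p^2), S = S,
       J = if (S > 1) H / log(S) else NA_real_)
}

# Broken-line Gaussian data with known parameters.
gen_broken_gauss <- function(n, alpha, beta1, beta2, psi, sigma,
                             xmin = 0, xmax = 10) {
  x <- sort(runif(n, xmin, xmax))
  y <- piecewise_predict(alpha, beta1, beta2, psi, x) + rnorm(n, 0, sigma)
  list(x = x, y = y)
}

# Broken-line negative-binomial counts with known parameters.
gen_broken_nb <- function(n, alpha, beta1, beta2, psi, k,
                          xmin = 0, xmax = 10) {
  x <- sort(runif(n, xmin, xmax))
  mu <- exp(piecewise_predict(alpha, beta1, beta2, psi, x))
  list(x = x, y = rnbinom(n, size = k, mu = mu))
}

# Exhaustive profile-likelihood grid search over candidate breakpoints:
# the brute-force oracle the iterative fitter is checked against.
profile_grid_psi <- function(y, x, family, ngrid) {
  grid <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = ngrid)
  ll <- vapply(grid, function(p) {
    U <- pmax(x - p, 0)
    f <- tryCatch(
      if (family == "gaussian") lm(y ~ x + U)
      else suppressWarnings(MASS::glm.nb(y ~ x + U)),
      error = function(e) NULL)
    if (is.null(f) || anyNA(coef(f))) -Inf else as.numeric(logLik(f))
  }, 0)
  list(best = grid[which.max(ll)], step = diff(grid[1:2]))
}

# Best converged multi-start segmented fit by log-likelihood (global
# optimum candidate for comparison against the grid oracle).
best_segfit <- function(y, x, family) {
  starts <- unique(quantile(x, seq(0.1, 0.9, 0.1), names = FALSE))
  fits <- lapply(starts, function(s)
    tryCatch(suppressWarnings(segfit(y, x, family, psi_start = s)),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && isTRUE(f$converged), fits)
  if (!length(fits)) return(NULL)
  fits[[which.max(vapply(fits, function(f) f$logLik, 0))]]
}
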