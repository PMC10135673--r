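# Response-curve fitting and backward elimination.

test_that("predictor centering subtracts the mean and is invertible", {
  expect_equal(center_predictor(c(1, 2, 3)), list(x = c(-1, 0, 1), center = 2))
  expect_equal(center_predictor(rep(4.2, 5))$x, rep(0, 5))
  set.seed(1)
  x <- rnorm(50, 10, 3)
  ctr <- center_predictor(x)
  expect_lt(abs(mean(ctr$x)), 1e-12)
  expect_equal(ctr$x + ctr$center, x)
  expect_error(center_predictor(numeric(0)), "empty")
  expect_error(center_predictor(c(1, NA)), "missing")
})

test_that("intercept-only maximum likelihood recovers the sample mean", {
  set.seed(2)
  y <- rnbinom(100, size = 3, mu = 8)
  x <- runif(100)
  f <- trait_response(y, x, "negbin", form = "intercept")
  expect_equal(exp(coef(f)[["intercept"]]), mean(y), tolerance = 1e-6)
  yg <- rnorm(60, 5)
  fg <- trait_response(yg, runif(60), "gaussian", form = "intercept")
  expect_equal(coef(fg)[["intercept"]], mean(yg), tolerance = 1e-10)
})

test_that("exactly collinear Gaussian data give an exact fit", {
  x <- seq(0, 10, length.out = 30)
  y <- 2 + 3 * x
  f <- trait_response(y, x, "gaussian", form = "linear")
  expect_equal(coef(f)[["linear"]], 3, tolerance = 1e-10)
  expect_lt(max(abs(residuals(f))), 1e-9)
  d <- residual_diagnostics(f)
  expect_equal(nrow(d), 30)
})

test_that("negative-binomial fits recover simulated coefficients within 3 SE", {
  set.seed(3)
  hits <- 0; reps <- 60
  for (r in 1:reps) {
    x <- runif(300, -2, 2)
    y <- rnbinom(300, size = 2, mu = exp(1 + 0.8 * x))
    f <- trait_response(y, x, "negbin", form = "linear", center = FALSE)
    hits <- hits + (abs(coef(f)[["linear"]] - 0.8) <= 3 * f$se[["linear"]])
  }
  expect_gte(hits / reps, 0.94)   # nominal 3-SE coverage is 99.7%
})

test_that("Gaussian quadratic fits recover simulated coefficients within 3 SE", {
  set.seed(4)
  hits <- 0; reps <- 60
  for (r in 1:reps) {
    x <- runif(120, -2, 2)
    y <- 1 + 0.5 * x - 0.7 * x^2 + rnorm(120, 0, 0.8)
    f <- trait_response(y, x, "gaussian", form = "quadratic", center = FALSE)
    hits <- hits + (abs(coef(f)[["quadratic"]] + 0.7) <= 3 * f$se[["quadratic"]])
  }
  expect_gte(hits / reps, 0.94)
})

test_that("large dispersion reduces the model to Poisson", {
  set.seed(5)
  x <- runif(400, -1, 1)
  y <- rpois(400, exp(1 + 0.5 * x))
  f <- trait_response(y, x, "negbin", form = "linear", center = FALSE)
  fp <- glm(y ~ x, family = poisson)
  expect_lt(max(abs(coef(f)[1:2] - coef(fp))), 1e-3)
  expect_gt(f$theta, 100)   # effectively equidispersed
  # NB log-likelihood approaches the Poisson one at huge k
  llp <- as.numeric(logLik(fp))
  mu <- fitted(fp)
  llnb <- sum(dnbinom(y, size = 1e6, mu = mu, log = TRUE))
  expect_lt(abs(llnb - llp) / length(y), 1e-4)
})

test_that("log-likelihood is monotone in nested polynomial forms", {
  set.seed(6)
  for (fam in c("gaussian", "negbin")) {
    for (r in 1:5) {
      x <- runif(80, 0, 4)
      y <- if (fam == "negbin") rnbinom(80, 2, mu = exp(0.5 + 0.3 * x))
           else rnorm(80, 1 + x)
      lls <- sapply(c("intercept", "linear", "quadratic"), function(fo)
        trait_response(y, x, fam, form = fo)$logLik)
      expect_true(all(diff(lls) >= -1e-6))
    }
  }
})

test_that("fitted curves on the original scale ignore centering", {
  set.seed(7)
  x <- runif(100, 5, 25)
  y <- rnbinom(100, 2, mu = exp(2 - 0.05 * x))
  grid <- seq(min(x), max(x), length.out = 33)
  f1 <- trait_response(y, x, "negbin", form = "linear", center = TRUE)
  f2 <- trait_response(y, x, "negbin", form = "linear", center = FALSE)
  expect_equal(as.numeric(predict(f1, grid)), as.numeric(predict(f2, grid)),
               tolerance = 1e-8)
})

test_that("backward elimination keeps real terms and drops absent ones", {
  set.seed(8)
  x <- runif(150, -2, 2)
  # strong quadratic signal
  yq <- rnbinom(150, 2, mu = exp(1.5 + 0.2 * x - 0.9 * x^2))
  fq <- trait_response(yq, x, "negbin")
  expect_identical(fq$form, "quadratic")
  expect_true(all(c("intercept", "linear", "quadratic") %in% names(coef(fq))))
  expect_identical(fq$trace$decision[1], "retained")
  # strong linear signal
  yl <- rnorm(150, 1 + 2 * x, 0.5)
  fl <- trait_response(yl, x, "gaussian")
  expect_identical(fl$form, "linear")
  expect_identical(nrow(fl$trace), 2L)
  expect_gte(fl$trace$p[1], 0.05)
  expect_lt(fl$trace$p[2], 0.05)
  # trace is reproducible
  fl2 <- trait_response(yl, x, "gaussian")
  expect_identical(fl$trace, fl2$trace)
})

test_that("response curves evaluate the inverse-link formula on the grid", {
  set.seed(9)
  x <- runif(80, 0, 30)
  y <- rnbinom(80, 2, mu = exp(2 + 0.03 * x))
  f <- trait_response(y, x, "negbin", form = "quadratic")
  grid <- runif(10, min(x), max(x))
  cf <- coef(f)
  manual <- exp(cf[["intercept"]] + cf[["linear"]] * (grid - f$center) +
                  cf[["quadratic"]] * (grid - f$center)^2)
  expect_equal(as.numeric(predict(f, grid)), manual, tolerance = 1e-12)
  expect_true(all(predict(f, grid) > 0))
  # intercept-only curve is flat at the sample mean
  f0 <- trait_response(y, x, "negbin", form = "intercept")
  expect_equal(suppressWarnings(as.numeric(predict(f0, c(0, 15, 30)))),
               rep(mean(y), 3), tolerance = 1e-6)
  expect_warning(predict(f, max(x) + 10), "outside")
})

test_that("deviance residuals are centred for well-specified count models", {
  set.seed(10)
  x <- runif(500, -1, 1)
  y <- rnbinom(500, size = 5, mu = exp(2.5 + 0.3 * x))
  f <- trait_response(y, x, "negbin", form = "linear")
  d <- residual_diagnostics(f)
  expect_identical(nrow(d), 500L)
  expect_lt(abs(attr(d, "summary")[["mean"]]), 0.2)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(500L, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
})

test_that("degenerate inputs are rejected with advice", {
  expect_error(trait_response(rep(0L, 20), runif(20), "negbin"), "sparse")
  expect_error(trait_response(c(1.5, 2, 3, 1, 2), runif(5), "negbin"), "integer")
  expect_error(trait_response(1:10, runif(9), "negbin"), "lengths")
})
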