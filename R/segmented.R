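# Segmented (broken-line) regression and tipping-point detection.
#
# The response (on the linear-predictor scale) follows two straight lines
# joined at an unknown breakpoint psi:
#
#   y = alpha + beta1 * x                              for x <  psi
#   y = (alpha - beta2 * psi) + (beta1 + beta2) * x    for x >  psi
#
# beta2 is the difference in slopes; the two branches agree at x = psi, so
# the fitted curve is continuous.  Estimation follows the iterative
# linearization of broken-line models: at a working psi the model is fitted
# with the hinge term (x - psi)+ and the indicator correction term
# -1(x > psi); the ratio of their coefficients proposes the psi update.
# Here the proposal is additionally subjected to a backtracking line
# search on the profile log-likelihood, which makes every accepted step
# increase the profile likelihood and the iteration converge to a local
# profile optimum even where the raw linearization oscillates.
#
# Because beta2 exists only under the alternative, breakpoint existence is
# tested by maximizing a pointwise statistic over K interior candidate
# psi values with a Davies-bound adjusted p-value: a Wald statistic for
# the hinge coefficient in Gaussian models (Davies test) and a GLM score
# statistic for adding the hinge to the null negative-binomial fit
# (score test).

#' Piecewise-linear (broken-line) predictor
#'
#' Evaluates the two-segment linear predictor with breakpoint `psi`:
#' `alpha + beta1*x` left of `psi` and
#' `(alpha - beta2*psi) + (beta1 + beta2)*x` right of it. The segments
#' agree at `x = psi`.
#'
#' @param alpha left-segment intercept.
#' @param beta1 left-segment slope.
#' @param beta2 difference in slopes (right minus left).
#' @param psi breakpoint, in predictor units.
#' @param x predictor values.
#' @return numeric vector on the linear-predictor scale.
#' @export
piecewise_predict <- function(alpha, beta1, beta2, psi, x) {
  alpha + beta1 * x + beta2 * pmax(x - psi, 0)
}

# Fast weighted-least-squares / IRLS engines used inside the iteration
# loops (the final reported model is refitted through the standard
# formula interfaces once).

# Gaussian ML fit by QR; returns NULL when rank deficient.
gauss_ls <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  if (f$rank < ncol(X)) return(NULL)
  cf <- numeric(ncol(X)); cf[f$pivot] <- f$coefficients
  n <- length(y)
  rss <- sum(f$residuals^2)
  if (rss <= 0) return(list(ll = Inf, coef = cf, theta = NA_real_))
  list(ll = -n / 2 * (log(2 * pi) + log(rss / n) + 1), coef = cf,
       theta = NA_real_)
}

# Negative-binomial ML by alternating IRLS (glm.fit at fixed theta) and
# theta ML updates, warm-startable; theta clamped to [1e-3, 1e6].
nb_irls <- function(X, y, warm = NULL) {
  th <- if (!is.null(warm$theta) && is.finite(warm$theta)) warm$theta else {
    m <- mean(y) + 0.1; v <- stats::var(y)
    if (is.finite(v) && v > m * 1.01) m^2 / (v - m) else 100
  }
  th <- min(max(th, 1e-3), 1e6)
  start <- if (!is.null(warm$coef) && length(warm$coef) == ncol(X)) warm$coef
  ll_old <- -Inf; mu <- NULL; cf <- NULL
  for (i in 1:30) {
    fit <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, family = MASS::negative.binomial(th), start = start)),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    mu <- fit$fitted.values
    cf <- fit$coefficients
    th_new <- tryCatch(suppressWarnings(
      as.numeric(MASS::theta.ml(y, mu, limit = 30))), error = function(e) NA_real_)
    if (!is.finite(th_new)) th_new <- 1e6
    th <- min(max(th_new, 1e-3), 1e6)
    ll <- sum(stats::dnbinom(y, size = th, mu = mu, log = TRUE))
    start <- cf
    if (abs(ll - ll_old) < 1e-8 * (abs(ll) + 1)) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(ll = ll_old, coef = cf, theta = th)
}

# Profile log-likelihood at fixed psi: fit y ~ x + (x - psi)+.
# Returns NULL if the fit fails or is degenerate.
profile_fit <- function(y, x, psi, family, warm = NULL) {
  X <- cbind(1, x, pmax(x - psi, 0))
  if (family == "gaussian") gauss_ls(X, y) else nb_irls(X, y, warm)
}

#' Fit a segmented regression from one starting value
#'
#' Iteratively estimates the breakpoint `psi` together with the segment
#' parameters, for Gaussian responses or negative-binomial counts (log
#' link; the broken line then describes the log mean, and the dispersion
#' is re-estimated at every iteration).  See the file header for the
#' algorithm; convergence is declared when the accepted `psi` step falls
#' below `tol * range(x)`.
#'
#' @param y response vector (counts for `family = "negbin"`).
#' @param x predictor on its original scale.
#' @param family `"gaussian"` or `"negbin"`.
#' @param psi_start starting breakpoint, strictly inside `range(x)`.
#' @param tol relative convergence tolerance on `psi` (default 1e-6).
#' @param maxit maximum iterations (default 50).
#' @param min_segment fewer observations than this on either side of the
#'   estimate triggers a warning flag (never suppression; default 5).
#' @return object of class `"segfit"`: `alpha`, `beta1`, `beta2`, `psi`,
#'   `se_psi` (delta method), slopes on both sides, log-likelihood,
#'   dispersion `theta` (negbin), convergence flag, iteration count and
#'   warnings. Methods: `print`, `coef`, `predict`, `residuals`, `plot`.
#' @export
segfit <- function(y, x, family = c("gaussian", "negbin"), psi_start,
                   tol = 1e-6, maxit = 50, min_segment = 5) {
  family <- match.arg(family)
  if (length(y) != length(x)) abort("`y` and `x` lengths differ")
  if (length(y) < 10) abort("segmented fitting needs at least 10 observations")
  if (psi_start <= min(x) || psi_start >= max(x))
    abort("`psi_start` must lie strictly inside the range of x")
  if (family == "negbin" && !is_count_vector(y))
    abort("negative-binomial responses must be non-negative integer counts")
  if (min(sum(x < psi_start), sum(x > psi_start)) < 10)
    warning("fewer than 10 observations on one side of `psi_start`", call. = FALSE)

  rng <- diff(range(x))
  xs <- sort(x)
  lo <- xs[2]; hi <- xs[length(xs) - 1]   # keep >= 1 point beyond psi
  psi <- psi_start
  converged <- FALSE
  failure <- NULL
  # one pass of damped linearization from the current iterate
  iterate <- function(psi, cur) {
    converged <- FALSE
    for (it in seq_len(maxit)) {
      Xw <- cbind(1, x, pmax(x - psi, 0), -(x > psi))
      fw <- if (family == "gaussian") gauss_ls(Xw, y) else nb_irls(Xw, y, cur)
      step <- if (is.null(fw) || anyNA(fw$coef)) NA_real_
              else fw$coef[4] / fw$coef[3]
      if (!is.finite(step) || step == 0) { converged <- TRUE; break }
      accepted <- FALSE
      for (h in 0:40) {                    # backtracking on the profile ll
        cand <- psi + step / 2^h
        if (cand <= lo || cand >= hi) next
        pr <- profile_fit(y, x, cand, family, warm = cur)
        if (!is.null(pr) && pr$ll >= cur$ll - 1e-10) {
          if (abs(cand - psi) < tol * rng) converged <- TRUE
          psi <- cand; cur <- pr; accepted <- TRUE
          break
        }
      }
      if (!accepted) { converged <- TRUE; break }  # local profile optimum
      if (converged) break
    }
    list(psi = psi, cur = cur, converged = converged, it = it)
  }

  cur <- profile_fit(y, x, psi, family)
  if (is.null(cur)) {
    failure <- "initial fit failed"
    it <- NA_integer_
  } else {
    res <- iterate(psi, cur)
    # local polish: the profile log-likelihood is kinked at the data
    # points and the linearization can stall one basin short of the
    # nearest optimum; probe the midpoints of neighbouring data gaps and
    # re-iterate from any that improves the profile.
    for (round in 1:3) {
      if (!res$converged) break
      j <- findInterval(res$psi, xs)
      idx <- max(2, j - 4):min(length(xs) - 1, j + 4)
      mids <- (xs[idx] + xs[idx + 1]) / 2
      mids <- mids[mids > lo & mids < hi]
      better <- NULL
      for (mm in mids) {
        pr <- profile_fit(y, x, mm, family, warm = res$cur)
        if (!is.null(pr) && pr$ll > res$cur$ll + 1e-10 &&
            (is.null(better) || pr$ll > better$cur$ll))
          better <- list(psi = mm, cur = pr)
      }
      if (is.null(better)) break
      res <- iterate(better$psi, better$cur)
    }
    psi <- res$psi; cur <- res$cur; converged <- res$converged; it <- res$it
    if (!converged && identical(it, maxit)) failure <- "iteration cap reached"
  }

  if (!is.null(failure) && is.null(cur)) {
    return(structure(list(family = family, psi = psi_start, converged = FALSE,
                          warnings = failure, n = length(y)),
                     class = "segfit"))
  }

  # final reported model: one refit through the standard interfaces
  Uf <- pmax(x - psi, 0)
  dff <- data.frame(y = y, x = x, U = Uf)
  fit <- tryCatch(
    if (family == "gaussian") stats::lm(y ~ x + U, data = dff)
    else suppressWarnings(MASS::glm.nb(y ~ x + U, data = dff)),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    return(structure(list(family = family, psi = psi, converged = FALSE,
                          warnings = "final refit failed", n = length(y)),
                     class = "segfit"))
  }
  cf <- stats::coef(fit)
  # SE of psi by the delta method on gamma/beta from the working model
  U <- pmax(x - psi, 0); V <- -(x > psi)
  dfw <- data.frame(y = y, x = x, U = U, V = V)
  fw <- tryCatch(
    if (family == "gaussian") stats::lm(y ~ x + U + V, data = dfw)
    else suppressWarnings(MASS::glm.nb(y ~ x + U + V, data = dfw)),
    error = function(e) NULL)
  se_psi <- if (!is.null(fw) && !anyNA(stats::coef(fw)[c("U", "V")]) &&
                all(c("U", "V") %in% colnames(suppressWarnings(stats::vcov(fw)))))
    sqrt(suppressWarnings(stats::vcov(fw))["V", "V"]) / abs(stats::coef(fw)[["U"]])
  else NA_real_

  warnings <- character()
  n_left <- sum(x < psi); n_right <- sum(x > psi)
  if (min(n_left, n_right) < min_segment)
    warnings <- c(warnings, sprintf(
      "only %d observation(s) on one side of the breakpoint", min(n_left, n_right)))
  if (!is.null(failure)) warnings <- c(warnings, failure)

  structure(list(
    family = family, psi = unname(psi), se_psi = unname(se_psi),
    alpha = unname(cf[[1]]), beta1 = unname(cf[["x"]]), beta2 = unname(cf[["U"]]),
    slope_left = unname(cf[["x"]]), slope_right = unname(cf[["x"]] + cf[["U"]]),
    theta = if (family == "negbin") theta_of(fit) else NA_real_,
    logLik = as.numeric(stats::logLik(fit)), converged = converged,
    iterations = if (is.null(failure)) it else NA,
    n = length(y), n_left = n_left, n_right = n_right,
    psi_start = psi_start, warnings = warnings,
    fitted = as.numeric(stats::fitted(fit)),
    deviance_residuals = as.numeric(stats::residuals(fit, type = "deviance")),
    y = y, x = x, model = fit
  ), class = "segfit")
}

#' @export
coef.segfit <- function(object, ...) {
  c(alpha = object$alpha, beta1 = object$beta1, beta2 = object$beta2,
    psi = object$psi)
}

#' @export
predict.segfit <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$x
  eta <- piecewise_predict(object$alpha, object$beta1, object$beta2,
                           object$psi, newdata)
  if (object$family == "negbin" && type == "response") exp(eta) else eta
}

#' @export
residuals.segfit <- function(object, ...) object$deviance_residuals

#' @export
logLik.segfit <- function(object, ...) {
  structure(object$logLik, df = 4 + (object$family == "negbin"), class = "logLik")
}

#' @export
print.segfit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.null(x$alpha)) {
    cat("Segmented fit: FAILED (", x$warnings, ")\n"); return(invisible(x))
  }
  cat(sprintf("Segmented %s fit (n = %d)\n",
              if (x$family == "negbin") "negative-binomial" else "Gaussian", x$n))
  cat(sprintf("  breakpoint psi: %.4g (SE %.3g)\n", x$psi, x$se_psi))
  cat(sprintf("  slopes: %.4g (left) -> %.4g (right); difference %.4g\n",
              x$slope_left, x$slope_right, x$beta2))
  if (!x$converged) cat("  [NOT CONVERGED]\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
plot.segfit <- function(x, npoints = 200, ...) {
  grid <- seq(min(x$x), max(x$x), length.out = npoints)
  graphics::plot(x$x, x$y, xlab = "predictor", ylab = "response", ...)
  graphics::lines(grid, predict(x, grid), lwd = 2)
  graphics::abline(v = x$psi, lty = 2)
  invisible(x)
}

# Interior candidate breakpoints: K equally spaced interior quantiles.
candidate_psi <- function(x, K) {
  unique(stats::quantile(x, probs = seq_len(K) / (K + 1), names = FALSE))
}

# Davies-bound adjusted two-sided p-value for the max of |signed stats|
# evaluated over ordered candidates.
davies_p <- function(stats_signed) {
  M <- max(abs(stats_signed))
  V <- sum(abs(diff(stats_signed)))
  min(1, 2 * (stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)))
}

#' Davies test for breakpoint existence (Gaussian response)
#'
#' Tests the null of no breakpoint (`beta2 = 0`, a straight line) against
#' a broken-line alternative.  Because the breakpoint vanishes under the
#' null, the hinge-coefficient Wald statistic is evaluated at `K` interior
#' candidate values of `psi` (equally spaced quantiles of `x`) and the
#' maximum is referred to the Davies upper bound for its two-sided
#' p-value.
#'
#' @param y Gaussian response.
#' @param x predictor.
#' @param K number of interior candidate breakpoints (default 10).
#' @return list with `best` (candidate with the extreme statistic),
#'   `statistic` (max |statistic|), `p_value`, `candidates`, `stats`,
#'   and `test = "davies"`.
#' @export
davies_test <- function(y, x, K = 10) {
  if (length(y) < 10) abort("Davies test needs at least 10 observations")
  if (stats::sd(y) == 0)
    return(list(best = stats::median(x), statistic = 0, p_value = 1,
                candidates = candidate_psi(x, K), stats = NULL, test = "davies"))
  cand <- candidate_psi(x, K)
  st <- vapply(cand, function(p) {
    h <- pmax(x - p, 0)
    sm <- tryCatch(summary(stats::lm(y ~ x + h))$coefficients,
                   error = function(e) NULL)
    if (is.null(sm) || nrow(sm) < 3) 0 else sm[3, 3]
  }, 0)
  list(best = cand[which.max(abs(st))], statistic = max(abs(st)),
       p_value = davies_p(st), candidates = cand, stats = st, test = "davies")
}

#' Score test for breakpoint existence (negative-binomial response)
#'
#' Tests `beta2 = 0` for count responses: the straight-line
#' negative-binomial model is fitted once, and the GLM score statistic for
#' adding the hinge term `(x - psi)+` is evaluated at `K` interior
#' candidate `psi` values, holding the dispersion at the null estimate.
#' The maximized statistic is referred to the same Davies-bound adjusted
#' two-sided p-value as [davies_test()].
#'
#' @inheritParams davies_test
#' @return list as in [davies_test()] with `test = "score"`.
#' @export
score_test <- function(y, x, K = 10) {
  if (!is_count_vector(y)) abort("score test expects non-negative integer counts")
  if (length(y) < 10) abort("score test needs at least 10 observations")
  f0 <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ x)), error = function(e) NULL)
  if (is.null(f0)) abort("null negative-binomial fit failed")
  mu <- stats::fitted(f0)
  k <- theta_of(f0)
  Vi <- mu + mu^2 / k
  W <- mu^2 / Vi
  X <- cbind(1, x)
  XtWX_inv <- solve(crossprod(X, W * X))
  cand <- candidate_psi(x, K)
  st <- vapply(cand, function(p) {
    h <- pmax(x - p, 0)
    U <- sum((y - mu) / Vi * mu * h)
    xwh <- crossprod(X, W * h)
    vh <- sum(W * h^2) - as.numeric(crossprod(xwh, XtWX_inv %*% xwh))
    if (vh <= 0) 0 else U / sqrt(vh)
  }, 0)
  list(best = cand[which.max(abs(st))], statistic = max(abs(st)),
       p_value = davies_p(st), candidates = cand, stats = st, test = "score")
}

#' Detect a tipping point along an environmental gradient
#'
#' The full detection procedure: run the breakpoint-existence test
#' ([davies_test()] for Gaussian responses, [score_test()] for counts),
#' fit the segmented model from a grid of starting values (interior
#' deciles of `x` between its 5th and 95th percentiles), and among the
#' converged fits select the breakpoint estimate closest to the test's
#' best candidate.  Equidistant candidates are broken by higher
#' log-likelihood, then by smaller `psi`.  The estimate is reported
#' whatever the test verdict; `significant` records whether the existence
#' test rejected at `alpha`.
#'
#' @inheritParams segfit
#' @param K candidate breakpoints for the existence test (default 10).
#' @param starts starting values for the segmented fits; default interior
#'   deciles of `x` within its 5th-95th percentile band.
#' @param alpha significance level for the existence test (default 0.05).
#' @param response,predictor optional labels carried into output tables.
#' @return object of class `"tipping_point"`: the selected `"segfit"`
#'   (`$fit`), `psi`, `se_psi`, test name/statistic/p-value, `significant`
#'   flag, `estimable` flag and the multi-start `trace` (one row per
#'   start: estimate, convergence, log-likelihood, distance to the test's
#'   best candidate).
#' @export
tipping_point <- function(y, x, family = c("gaussian", "negbin"),
                          K = 10, starts = NULL, alpha = 0.05,
                          tol = 1e-6, maxit = 50, min_segment = 5,
                          response = deparse1(substitute(y)),
                          predictor = deparse1(substitute(x))) {
  family <- match.arg(family)
  force(response); force(predictor)
  test <- if (family == "gaussian") davies_test(y, x, K) else score_test(y, x, K)
  if (is.null(starts)) {
    qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    starts <- stats::quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE)
    starts <- unique(starts[starts > qs[1] & starts < qs[2]])
  }
  fits <- lapply(starts, function(s)
    tryCatch(suppressWarnings(
      segfit(y, x, family, psi_start = s, tol = tol, maxit = maxit,
             min_segment = min_segment)),
      error = function(e) NULL))
  keep <- !vapply(fits, is.null, TRUE)
  fits <- fits[keep]; starts_used <- starts[keep]
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  trace <- data.frame(
    start = starts_used,
    psi = vapply(fits, function(f) f$psi %||% NA_real_, 0),
    converged = conv,
    logLik = vapply(fits, function(f) f$logLik %||% NA_real_, 0),
    stringsAsFactors = FALSE)
  trace$dist <- abs(trace$psi - test$best)

  out <- list(response = response, predictor = predictor, family = family,
              test = test$test, statistic = test$statistic,
              p_value = test$p_value, best_candidate = test$best,
              significant = test$p_value < alpha, alpha = alpha,
              trace = trace, estimable = any(conv))
  if (!any(conv)) {
    out$fit <- NULL; out$psi <- NA_real_; out$se_psi <- NA_real_
    out$warnings <- "no estimable tipping point (no start converged)"
  } else {
    cand <- which(conv)
    d <- trace$dist[cand]
    sel <- cand[d - min(d) < 1e-10]
    if (length(sel) > 1) {                      # tie on distance
      ll <- trace$logLik[sel]
      sel <- sel[ll - max(ll) > -1e-10]
      if (length(sel) > 1) sel <- sel[which.min(trace$psi[sel])]
    }
    sel <- sel[1]
    out$fit <- fits[[sel]]
    out$psi <- out$fit$psi
    out$se_psi <- out$fit$se_psi
    out$warnings <- out$fit$warnings
  }
  structure(out, class = "tipping_point")
}

#' @export
print.tipping_point <- function(x, ...) {
  cat(sprintf("Tipping point: %s ~ %s (%s)\n", x$response, x$predictor,
              if (x$family == "negbin") "negative-binomial" else "Gaussian"))
  cat(sprintf("  %s test: statistic %.3f, p = %.4g (%s at %g%%)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant",
              100 * x$alpha))
  if (x$estimable)
    cat(sprintf("  psi = %.4g (SE %.3g); slopes %.4g -> %.4g\n",
                x$psi, x$se_psi, x$fit$slope_left, x$fit$slope_right))
  else cat("  no estimable tipping point\n")
  for (w in x$warnings) if (nzchar(w)) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
plot.tipping_point <- function(x, ...) {
  if (!x$estimable) abort("no estimable tipping point to plot")
  plot(x$fit, ...)
  invisible(x)
}
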