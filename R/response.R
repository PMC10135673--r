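# Trait / diversity-metric response curves along environmental gradients.
#
# Per-trait counts are modelled with a negative-binomial GLM (log link,
# variance mu + mu^2/k with dispersion k); per-metric diversity values
# with a Gaussian linear model.  Predictors are mean-centered before
# fitting to tame collinearity between linear and quadratic terms.
# Backward elimination decides the polynomial form: the quadratic term is
# tested first (likelihood-ratio chi^2, 1 df, alpha = 0.05); if dropped,
# the linear term is tested the same way; failing both leaves an
# intercept-only model.  Lower-order terms are always retained under a
# retained higher-order term.

#' Center a predictor at its mean
#'
#' @param x numeric vector without missing values.
#' @return list with `x` (centered values, mean zero) and `center` (the
#'   subtracted mean, used to map fits back to the original scale).
#' @export
center_predictor <- function(x) {
  if (length(x) == 0) abort("cannot center an empty predictor")
  if (anyNA(x)) abort("predictor has missing values; filter incomplete sites first")
  m <- mean(x)
  list(x = x - m, center = m)
}

# Single maximum-likelihood fit of a given polynomial form.
# x is on the centered scale.  Returns NULL on hard failure.
fit_form <- function(y, x, family, form) {
  df <- data.frame(y = y, x = x)
  fml <- switch(form,
                quadratic = y ~ x + I(x^2),
                linear    = y ~ x,
                intercept = y ~ 1)
  if (family == "negbin") {
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = df)),
                    error = function(e) NULL)
  } else {
    fit <- tryCatch(stats::lm(fml, data = df), error = function(e) NULL)
  }
  fit
}

theta_of <- function(fit) if (!is.null(fit$theta)) unname(fit$theta) else NA_real_

#' Fit a trait or diversity-metric response curve
#'
#' Fits the abundance of one trait (negative-binomial, log link) or one
#' diversity metric (Gaussian, identity link) against a single
#' environmental predictor.  With `form = "auto"` the polynomial form is
#' chosen by backward elimination at level `alpha`; fixed forms fit
#' exactly the requested model.
#'
#' @param y response: non-negative integer counts (negbin) or real values
#'   (gaussian).
#' @param x predictor on its original scale (m/s, NTU, m a.s.l., ...).
#' @param family `"negbin"` for trait counts, `"gaussian"` for diversity
#'   metrics.
#' @param form `"auto"` (backward elimination), `"quadratic"`, `"linear"`
#'   or `"intercept"`.
#' @param alpha significance level for term tests (default 0.05).
#' @param center mean-center the predictor before fitting (default TRUE).
#' @param response,predictor optional labels carried into output tables.
#' @return object of class `"trait_response"`: coefficients on the
#'   centered scale, dispersion `theta` (negbin), `center`, log-likelihood,
#'   the selection `trace` (one row per tested term), convergence flag and
#'   deviance residuals. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `simulate`, `plot`.
#' @export
trait_response <- function(y, x, family = c("negbin", "gaussian"),
                           form = c("auto", "quadratic", "linear", "intercept"),
                           alpha = 0.05, center = TRUE,
                           response = deparse1(substitute(y)),
                           predictor = deparse1(substitute(x))) {
  family <- match.arg(family)
  form <- match.arg(form)
  force(response); force(predictor)
  if (length(y) != length(x)) abort("`y` and `x` lengths differ")
  if (anyNA(y) || anyNA(x)) abort("missing values; filter incomplete sites first")
  if (family == "negbin") {
    if (!is_count_vector(y)) abort("negative-binomial responses must be non-negative integer counts")
    if (all(y == 0))
      abort("response is zero at every site; exclude sparse traits before model fitting")
  }
  if (length(y) < 5) abort("too few observations to fit a response curve")

  ctr <- if (center) center_predictor(x) else list(x = x, center = 0)
  xc <- ctr$x

  trace <- data.frame(step = integer(), term = character(), p = numeric(),
                      decision = character(), stringsAsFactors = FALSE)
  lrt_p <- function(fit1, fit0) {
    lr <- max(0, 2 * (as.numeric(stats::logLik(fit1)) - as.numeric(stats::logLik(fit0))))
    stats::pchisq(lr, df = 1, lower.tail = FALSE)
  }

  if (form == "auto") {
    fq <- fit_form(y, xc, family, "quadratic")
    fl <- fit_form(y, xc, family, "linear")
    f0 <- fit_form(y, xc, family, "intercept")
    if (is.null(fl) || is.null(f0))
      abort("model fitting failed for response '%s'", response)
    if (!is.null(fq)) {
      pq <- lrt_p(fq, fl)
      keep_q <- pq < alpha
      trace <- rbind(trace, data.frame(step = 1L, term = "quadratic", p = pq,
                                       decision = if (keep_q) "retained" else "dropped"))
    } else {
      keep_q <- FALSE
      trace <- rbind(trace, data.frame(step = 1L, term = "quadratic", p = NA_real_,
                                       decision = "fit failed; dropped"))
    }
    if (keep_q) {
      final <- fq; form <- "quadratic"
    } else {
      pl <- lrt_p(fl, f0)
      keep_l <- pl < alpha
      trace <- rbind(trace, data.frame(step = 2L, term = "linear", p = pl,
                                       decision = if (keep_l) "retained" else "dropped"))
      if (keep_l) { final <- fl; form <- "linear" }
      else { final <- f0; form <- "intercept" }
    }
  } else {
    final <- fit_form(y, xc, family, form)
    if (is.null(final)) abort("model fitting failed for response '%s'", response)
  }

  cf <- stats::coef(final)
  names(cf) <- c("intercept", "linear", "quadratic")[seq_along(cf)]
  converged <- if (family == "negbin") isTRUE(final$converged) else TRUE
  theta <- if (family == "negbin") theta_of(final) else NA_real_
  theta_boundary <- isTRUE(family == "negbin" && (theta < 1e-3 || theta > 1e6))

  coefs <- suppressWarnings(summary(final))$coefficients
  pvals <- stats::setNames(coefs[, ncol(coefs)], names(cf))
  ses <- stats::setNames(coefs[, 2], names(cf))

  structure(list(
    response = response, predictor = predictor, family = family, form = form,
    coefficients = cf, theta = theta, theta_boundary = theta_boundary,
    center = ctr$center, logLik = as.numeric(stats::logLik(final)),
    p_values = pvals, se = ses, trace = trace, converged = converged,
    fitted = as.numeric(stats::fitted(final)),
    deviance_residuals = as.numeric(stats::residuals(final, type = "deviance")),
    y = y, x = x, n = length(y), alpha = alpha, model = final
  ), class = "trait_response")
}

#' @export
coef.trait_response <- function(object, ...) object$coefficients

#' @export
logLik.trait_response <- function(object, ...) {
  # one auxiliary parameter in either family (theta or sigma)
  structure(object$logLik, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' Predicted mean response along a predictor grid
#'
#' Evaluates the fitted response curve on the original predictor scale:
#' the stored centering constant is applied, the polynomial linear
#' predictor evaluated, and the inverse link applied (`exp` for
#' negative-binomial fits, identity for Gaussian).  Grid points outside
#' the observed predictor range (plus `extrapolation` times the range on
#' either side) are flagged in the `"extrapolated"` attribute.
#'
#' @param object a `"trait_response"` fit.
#' @param newdata numeric vector of predictor values on the original
#'   scale; defaults to an even 100-point grid over the observed range.
#' @param extrapolation fraction of the observed range tolerated outside
#'   it before a point is flagged (default 0, i.e. flag anything outside
#'   the data range).
#' @param ... unused.
#' @return numeric vector of predicted means (strictly positive for
#'   negative-binomial fits) with attribute `"extrapolated"`.
#' @export
predict.trait_response <- function(object, newdata = NULL, extrapolation = 0, ...) {
  if (is.null(newdata))
    newdata <- seq(min(object$x), max(object$x), length.out = 100)
  xc <- newdata - object$center
  cf <- object$coefficients
  eta <- rep(cf[["intercept"]], length(xc)) +
    (if ("linear" %in% names(cf)) cf[["linear"]] * xc else 0) +
    (if ("quadratic" %in% names(cf)) cf[["quadratic"]] * xc^2 else 0)
  mu <- if (object$family == "negbin") exp(eta) else eta
  band <- extrapolation * diff(range(object$x))
  extra <- newdata < min(object$x) - band | newdata > max(object$x) + band
  if (any(extra))
    warning(sum(extra), " grid point(s) outside the observed predictor range",
            call. = FALSE)
  attr(mu, "extrapolated") <- extra
  mu
}

#' @export
residuals.trait_response <- function(object, type = "deviance", ...) {
  if (type != "deviance") return(stats::residuals(object$model, type = type, ...))
  object$deviance_residuals
}

#' Deviance-residual diagnostics for a response fit
#'
#' Residual-versus-fitted pairs used to assess homogeneity of the model,
#' plus summary statistics.  No automatic pass/fail is applied.
#'
#' @param fit a `"trait_response"` (or `"segfit"`) object.
#' @return data.frame with columns `fitted` and `deviance_resid`;
#'   attribute `"summary"` holds the residual mean and SD.
#' @export
residual_diagnostics <- function(fit) {
  d <- data.frame(fitted = fit$fitted, deviance_resid = fit$deviance_residuals)
  attr(d, "summary") <- c(mean = mean(d$deviance_resid), sd = stats::sd(d$deviance_resid))
  d
}

#' @export
simulate.trait_response <- function(object, nsim = 1, seed = NULL, ...) {
  sim1 <- function() {
    mu <- predict(object, newdata = object$x)
    if (object$family == "negbin")
      stats::rnbinom(object$n, size = object$theta, mu = mu)
    else
      stats::rnorm(object$n, mu, stats::sd(object$y - mu))
  }
  run <- function() as.data.frame(replicate(nsim, sim1()))
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.trait_response <- function(x, ...) {
  cat(sprintf("%s response curve: %s ~ %s (%s)\n",
              if (x$family == "negbin") "Negative-binomial" else "Gaussian",
              x$response, x$predictor, x$form))
  cat("Coefficients (centered predictor scale):\n")
  print(round(x$coefficients, 4))
  if (x$family == "negbin")
    cat(sprintf("Dispersion k: %.3f%s\n", x$theta,
                if (x$theta_boundary) " (at bound)" else ""))
  cat(sprintf("logLik: %.2f   n: %d%s\n", x$logLik, x$n,
              if (!x$converged) "   [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
summary.trait_response <- function(object, ...) {
  print(object)
  cat("\nBackward-elimination trace:\n")
  if (nrow(object$trace)) print(object$trace, row.names = FALSE)
  else cat("  (form was fixed, no selection performed)\n")
  rd <- attr(residual_diagnostics(object), "summary")
  cat(sprintf("\nDeviance residuals: mean %.3f, sd %.3f\n", rd[["mean"]], rd[["sd"]]))
  invisible(object)
}

#' @export
plot.trait_response <- function(x, npoints = 100, ...) {
  grid <- seq(min(x$x), max(x$x), length.out = npoints)
  mu <- predict(x, grid)
  graphics::plot(x$x, x$y, xlab = x$predictor, ylab = x$response,
                 main = sprintf("%s ~ %s (%s %s)", x$response, x$predictor,
                                x$family, x$form), ...)
  graphics::lines(grid, mu, lwd = 2)
  invisible(x)
}
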