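#' Stimulus-response curve container
#'
#' One response-vs-stimulus-parameter curve: % active ROIs or relative band
#' power (dB) against stimulus duration (s), pulse frequency (Hz) or
#' intensity (mA).
#'
#' @param x stimulus parameter values, strictly increasing
#' @param y responses
#' @param kind one of "duration", "frequency", "intensity"
#' @param y_sem optional per-point SEM
#' @param n_per_point optional per-point replicate count
#' @return a data.frame of class `response_curve`
#' @export
response_curve <- function(x, y, kind = c("duration", "frequency", "intensity"),
                           y_sem = NULL, n_per_point = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  if (any(diff(x) <= 0)) stopf("x must be strictly increasing")
  out <- data.frame(x = x, y = y)
  if (!is.null(y_sem)) out$y_sem <- y_sem
  if (!is.null(n_per_point)) out$n_per_point <- n_per_point
  structure(out, class = c("response_curve", "data.frame"), kind = kind)
}

#' Evaluate the general stimulus-response sigmoid
#'
#' `R(x) = r_max / (1 + exp(-r_slope (x - r_50))) + r_min`, with `r_min = 0`
#' for calcium population responses and a free floor for band-power curves.
#'
#' @param fit a `sigmoid_fit` or a list/vector with elements `r_max`, `r_50`,
#'   `r_slope` and optionally `r_min`
#' @param x stimulus parameter values
#' @return response values
#' @export
evaluate_sigmoid <- function(fit, x) {
  p <- if (inherits(fit, "sigmoid_fit")) as.list(stats::coef(fit)) else as.list(fit)
  r_min <- p$r_min %||% 0
  stopifnot(is.finite(p$r_max), is.finite(p$r_50), is.finite(p$r_slope))
  p$r_max / (1 + exp(-p$r_slope * (x - p$r_50))) + r_min
}

sigmoid_rhs <- function(par, x, with_offset) {
  r_min <- if (with_offset) par[4] else 0
  L <- 1 / (1 + exp(-par[3] * (x - par[2])))
  list(f = par[1] * L + r_min, L = L)
}

sigmoid_jacobian <- function(par, x, with_offset) {
  L <- 1 / (1 + exp(-par[3] * (x - par[2])))
  J <- cbind(L,
             -par[1] * par[3] * L * (1 - L),
             par[1] * (x - par[2]) * L * (1 - L))
  if (with_offset) J <- cbind(J, 1)
  J
}

default_init <- function(x, y, with_offset) {
  rng <- max(y) - min(y)
  r_min <- if (with_offset) min(y) else 0
  r_max <- if (with_offset) rng else max(y)
  if (r_max <= 0) r_max <- max(abs(y), 1e-6)
  mid <- (max(y) + min(y)) / 2
  r_50 <- x[which.min(abs(y - mid))]
  sec <- diff(y) / diff(x)
  r_slope <- if (rng > 0 && any(sec > 0)) 4 * max(sec) / rng else 1 / diff(range(x))
  c(r_max, r_50, r_slope, if (with_offset) r_min)
}

#' Fit the stimulus-response sigmoid by nonlinear least squares
#'
#' Levenberg-Marquardt minimization of the (optionally 1/SEM^2-weighted)
#' residual sum of squares of `R(x) = r_max/(1+exp(-r_slope (x - r_50))) +
#' r_min`, with `r_min` pinned to 0 unless `with_offset = TRUE`. `r_max` and
#' `r_slope` are constrained non-negative (responses are non-negative and
#' non-decreasing in the stimulus); a fit ending on the `r_slope = 0` bound
#' or failing to converge is returned with `converged = FALSE` rather than
#' raising. Initial values follow a secant-slope heuristic unless `init` is
#' given.
#'
#' @param x stimulus values, or a [response_curve()]
#' @param y responses (ignored when `x` is a curve)
#' @param with_offset free the `r_min` floor (band-power curves)
#' @param init optional named or positional start `c(r_max, r_50, r_slope[, r_min])`
#' @param weights optional least-squares weights (e.g. 1/SEM^2)
#' @return an object of class `sigmoid_fit` with methods `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `predict`, `fitted`, `residuals`, `plot` and
#'   `simulate`
#' @examples
#' x <- c(1, 5, 10, 20, 60)
#' y <- evaluate_sigmoid(c(r_max = 82.8, r_50 = 7.5, r_slope = 0.4), x)
#' fit <- fit_sigmoid(x, y)
#' coef(fit)
#' @export
fit_sigmoid <- function(x, y = NULL, with_offset = FALSE, init = NULL,
                        weights = NULL) {
  kind <- "duration"
  if (inherits(x, "response_curve")) {
    kind <- attr(x, "kind")
    if (is.null(weights) && !is.null(x$y_sem) && all(x$y_sem > 0)) {
      weights <- 1 / x$y_sem^2
    }
    y <- x$y; x <- x$x
  }
  stopifnot(length(x) == length(y))
  npar <- 3L + as.integer(with_offset)
  if (length(x) < npar + 1L) {
    stopf("need at least %d points to fit %d parameters", npar + 1L, npar)
  }
  w <- weights %||% rep(1, length(x))
  par <- as.numeric(init %||% default_init(x, y, with_offset))
  if (length(par) != npar) stopf("init must have %d elements", npar)
  par[1] <- max(par[1], 0); par[3] <- max(par[3], 0)
  sw <- sqrt(w)
  rss_of <- function(p) sum((sw * (y - sigmoid_rhs(p, x, with_offset)$f))^2)
  lambda <- 1e-3
  rss <- rss_of(par)
  converged <- FALSE
  for (it in seq_len(500)) {
    r <- sw * (y - sigmoid_rhs(par, x, with_offset)$f)
    J <- sw * sigmoid_jacobian(par, x, with_offset)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step_ok <- FALSE
    for (tries in seq_len(40)) {
      Haug <- H + lambda * diag(diag(H) + 1e-12, npar)
      step <- tryCatch(solve(Haug, g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- par + as.numeric(step)
      cand[1] <- max(cand[1], 0); cand[3] <- max(cand[3], 0)
      rss_new <- rss_of(cand)
      if (is.finite(rss_new) && rss_new <= rss) {
        improve <- rss - rss_new
        par <- cand; rss <- rss_new
        lambda <- max(lambda / 10, 1e-12)
        step_ok <- TRUE
        if (improve < 1e-12 * (rss + 1e-12)) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) { converged <- rss_of(par) <= rss; break }
    if (converged) break
  }
  if (par[3] <= 0) converged <- FALSE # slope pinned at its lower bound
  fitted_vals <- sigmoid_rhs(par, x, with_offset)$f
  dof <- length(x) - npar
  J <- sw * sigmoid_jacobian(par, x, with_offset)
  sigma2 <- if (dof > 0) rss / dof else NA_real_
  vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  nm <- c("r_max", "r_50", "r_slope", if (with_offset) "r_min")
  names(par) <- nm
  dimnames(vc) <- list(nm, nm)
  structure(list(coefficients = par, vcov = vc, rss = rss, sigma2 = sigma2,
                 df.residual = dof, converged = converged,
                 with_offset = with_offset, kind = kind,
                 data = data.frame(x = x, y = y, w = w),
                 fitted.values = fitted_vals,
                 residuals = y - fitted_vals),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
vcov.sigmoid_fit <- function(object, ...) object$vcov

#' @export
fitted.sigmoid_fit <- function(object, ...) object$fitted.values

#' @export
residuals.sigmoid_fit <- function(object, ...) object$residuals

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  evaluate_sigmoid(object, x)
}

#' @export
confint.sigmoid_fit <- function(object, parm = NULL, level = 0.95, ...) {
  est <- object$coefficients
  se <- sqrt(diag(object$vcov))
  tq <- stats::qt(1 - (1 - level) / 2, max(object$df.residual, 1))
  ci <- cbind(est - tq * se, est + tq * se)
  colnames(ci) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.sigmoid_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Sigmoid stimulus-response fit (%s%s)\n", x$kind,
              if (x$with_offset) ", free floor" else ""))
  print(round(x$coefficients, digits))
  cat(sprintf("RSS %.4g on %d residual df; converged: %s\n",
              x$rss, x$df.residual, x$converged))
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(abs(tval), max(object$df.residual, 1), lower.tail = FALSE)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  out <- list(coefficients = tab, rss = object$rss,
              sigma = sqrt(object$sigma2), df = object$df.residual,
              converged = object$converged, kind = object$kind)
  class(out) <- "summary.sigmoid_fit"
  out
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid stimulus-response fit (%s)\n\n", x$kind))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual SE %.4g on %d df; converged: %s\n",
              x$sigma, x$df, x$converged))
  invisible(x)
}

#' @export
plot.sigmoid_fit <- function(x, n = 200, ...) {
  xx <- seq(min(x$data$x), max(x$data$x), length.out = n)
  graphics::plot(x$data$x, x$data$y, xlab = x$kind, ylab = "response",
                 main = "sigmoid stimulus-response fit", ...)
  graphics::lines(xx, evaluate_sigmoid(x, xx), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.sigmoid_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(object$sigma2)
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(length(object$fitted.values), 0, s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Parameter-recovery report over repeated fits
#'
#' Per-parameter bias, RMSE and nominal-95 % interval coverage of a list of
#' fits against their generating truth.
#'
#' @param truth named numeric vector (or list) of true parameter values, or a
#'   list of such (one per fit)
#' @param fits list of `sigmoid_fit` objects
#' @return data.frame with columns `parameter`, `truth`, `bias`, `rmse`,
#'   `coverage`
#' @export
recovery_report <- function(truth, fits) {
  if (inherits(fits, "sigmoid_fit")) fits <- list(fits)
  single_truth <- !is.list(truth) || !is.null(names(truth))
  if (single_truth) truth <- rep(list(unlist(truth)), length(fits))
  if (length(truth) != length(fits)) stopf("truth and fits lengths differ")
  pars <- names(stats::coef(fits[[1]]))
  out <- lapply(pars, function(p) {
    est <- vapply(fits, function(f) stats::coef(f)[[p]], numeric(1))
    tru <- vapply(truth, function(tr) tr[[p]], numeric(1))
    cov <- vapply(seq_along(fits), function(i) {
      ci <- stats::confint(fits[[i]])[p, ]
      is.finite(ci[1]) && tru[i] >= ci[1] && tru[i] <= ci[2]
    }, logical(1))
    data.frame(parameter = p, truth = mean(tru), bias = mean(est - tru),
               rmse = sqrt(mean((est - tru)^2)), coverage = mean(cov))
  })
  do.call(rbind, out)
}
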