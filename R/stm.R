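#' State-space description of the stochastic response function
#'
#' Describes the model `I_t = mu_t + alpha_t * X_t + eps_t` with an
#' integrated-random-walk trend (the level `mu` accumulates a slope
#' `delta` that itself random-walks with variance `sigma2_zeta`) and a
#' random-walk response weight `alpha` (variance `sigma2_eta`).  The
#' state is `(mu_t, delta_t, alpha_t)` with the unit-determinant
#' transition matrix `[[1,1,0],[0,1,0],[0,0,1]]` and time-varying
#' observation row `(1, 0, X_t)`.  Initialization is diffuse,
#' implemented as a large-but-finite prior variance
#' (`1e7 * var(I)`); a state whose disturbance variance is pinned to
#' zero in [fit_stm()] is also initialized degenerately where noted
#' there.
#'
#' @param I Response series (numeric; NAs allowed, handled by the filter
#'   as prediction-only steps).
#' @param X Predictor series, same length, no NAs where I is observed.
#' @return List with `T` (transition), `Zrows` (n x 3 observation rows),
#'   `a0`, `P0`, `n`.
#' @export
build_state_space <- function(I, X) {
  I <- as.numeric(I); X <- as.numeric(X)
  if (length(I) != length(X))
    stop_ringtruth("I and X must be aligned (equal length)", "domain_error")
  if (sum(is.finite(I)) < 10L)
    stop_ringtruth("need at least 10 observed values", "precondition_error")
  if (any(is.finite(I) & !is.finite(X)))
    stop_ringtruth("X must be present wherever I is observed",
                   "domain_error")
  Tm <- matrix(c(1, 0, 0,
                 1, 1, 0,
                 0, 0, 1), 3, 3)
  Zrows <- cbind(1, 0, X)
  kappa <- 1e7 * stats::var(I, na.rm = TRUE)
  list(T = Tm, Zrows = Zrows,
       a0 = c(mean(I, na.rm = TRUE), 0, 0),
       P0 = diag(rep(kappa, 3)), n = length(I))
}

stm_filter <- function(I, X, sig2, a0, P0, burn = 3L, smooth = TRUE) {
  kalman_run(as.numeric(I), as.numeric(X),
             sig2[["eps"]], sig2[["zeta"]], sig2[["eta"]],
             a0, P0, as.integer(burn), smooth)
}

#' Fit the stochastic response function by maximum likelihood
#'
#' Estimates the three disturbance variances (observation
#' `sigma2_eps`, trend-slope `sigma2_zeta`, response-walk `sigma2_eta`)
#' by numerical maximization of the prediction-error-decomposition
#' log-likelihood over log-variances, from five data-scaled starting
#' points (ties broken by likelihood, then by the smaller
#' `sigma2_eta`).  Fixed-interval smoothing at the optimum yields the
#' time-resolved trend and response weight with pointwise variances and
#' 95\% bands.  The fit is deterministic given the data.
#'
#' Any variance named in `fix` is held at the given value instead of
#' being estimated.  Pinning `zeta = 0` also suppresses the slope state
#' entirely (degenerate initialization), so the trend reduces to a
#' constant level and, with `eta = 0` as well, the model collapses to
#' the ordinary regression `I = mu + alpha * X`.
#'
#' @param I,X Aligned annual series (numeric vectors or data.frames with
#'   `year`/`value`; NAs in I are skipped by the filter).
#' @param years Optional year labels (taken from data.frames if given).
#' @param fix Named numeric vector fixing any of `eps`, `zeta`, `eta`.
#' @param control List: `maxit` per optimizer start.
#' @return An object of class `stm_fit` with components `years`, `I`,
#'   `X`, `mu_hat`, `mu_var`, `alpha_hat`, `alpha_var` (smoothed),
#'   `mu_filt`, `alpha_filt` and their variances, `sig2`, `loglik`,
#'   `var_explained` (smoothed), `var_explained_filtered`, `band_mult`,
#'   `convergence`.
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' y <- 0.5 * x + rnorm(60, sd = 0.3)
#' fit <- fit_stm(y, x, fix = c(zeta = 0, eta = 0))
#' coef(fit)
#' @export
fit_stm <- function(I, X, years = NULL, fix = NULL,
                    control = list(maxit = 500)) {
  if (is.data.frame(I)) { ai <- as_annual(I); years <- years %||% ai$year; I <- ai$value }
  if (is.data.frame(X)) { X <- as_annual(X)$value }
  ss <- build_state_space(I, X)
  years <- years %||% seq_along(I)
  a0 <- ss$a0; P0 <- ss$P0
  fix <- fix %||% numeric(0)
  if ("zeta" %in% names(fix) && fix[["zeta"]] == 0) {
    P0[2, 2] <- 0; a0[2] <- 0          # no slope: constant-level trend
  }
  free <- setdiff(c("eps", "zeta", "eta"), names(fix))
  vy <- stats::var(I, na.rm = TRUE)
  vx <- stats::var(X, na.rm = TRUE)
  if (!is.finite(vx) || vx == 0) vx <- 1

  make_sig2 <- function(theta) {
    s <- c(eps = NA_real_, zeta = NA_real_, eta = NA_real_)
    s[names(fix)] <- as.numeric(fix)
    s[free] <- exp(theta)
    s
  }
  negll <- function(theta) {
    s <- make_sig2(theta)
    if (any(!is.finite(s)) || any(s < 0)) return(1e10)
    kf <- stm_filter(I, X, s, a0, P0, smooth = FALSE)
    ll <- kf$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- list(
    c(eps = 0.5 * vy,  zeta = 1e-5 * vy, eta = 1e-3 * vy / vx),
    c(eps = 0.2 * vy,  zeta = 1e-3 * vy, eta = 1e-2 * vy / vx),
    c(eps = 0.8 * vy,  zeta = 1e-7 * vy, eta = 1e-5 * vy / vx),
    c(eps = 0.3 * vy,  zeta = 1e-4 * vy, eta = 1e-1 * vy / vx),
    c(eps = 0.9 * vy,  zeta = 1e-6 * vy, eta = 1e-4 * vy / vx))

  best <- NULL
  if (length(free)) {
    for (st in starts) {
      th0 <- log(st[free])
      opt <- if (length(th0) == 1L)
        stats::optim(th0, negll, method = "Brent",
                     lower = th0 - 25, upper = th0 + 25)
      else stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(maxit = control$maxit %||% 500,
                                       reltol = 1e-10))
      cand <- list(theta = opt$par, value = opt$value,
                   convergence = opt$convergence,
                   sig2 = make_sig2(opt$par))
      if (is.null(best) ||
          cand$value < best$value - 1e-9 ||
          (abs(cand$value - best$value) <= 1e-9 &&
           cand$sig2[["eta"]] < best$sig2[["eta"]]))
        best <- cand
    }
    if (!is.finite(best$value) || best$value >= 1e10)
      stop_ringtruth("variance optimization failed to find a finite likelihood",
                     "optim_error")
  } else {
    best <- list(theta = numeric(0), value = negll(numeric(0)),
                 convergence = 0L, sig2 = make_sig2(numeric(0)))
  }

  sig2 <- best$sig2
  kf <- stm_filter(I, X, sig2, a0, P0, smooth = TRUE)
  mu_hat <- kf$a_smooth[1, ]
  alpha_hat <- kf$a_smooth[3, ]
  mu_var <- pmax(kf$P_smooth_diag[1, ], 0)
  alpha_var <- pmax(kf$P_smooth_diag[3, ], 0)
  mu_f <- kf$a_filt[1, ]
  alpha_f <- kf$a_filt[3, ]

  fit <- structure(list(
    years = years, I = I, X = X,
    mu_hat = mu_hat, mu_var = mu_var,
    alpha_hat = alpha_hat, alpha_var = alpha_var,
    mu_filt = mu_f, mu_filt_var = pmax(kf$P_filt_diag[1, ], 0),
    alpha_filt = alpha_f, alpha_filt_var = pmax(kf$P_filt_diag[3, ], 0),
    sig2 = sig2, loglik = -best$value, band_mult = 1.96,
    var_explained = NA_real_, var_explained_filtered = NA_real_,
    convergence = best$convergence, fixed = fix),
    class = "stm_fit")
  fit$var_explained <- explained_variance(I, X, mu_hat, alpha_hat)
  fit$var_explained_filtered <- explained_variance(I, X, mu_f, alpha_f)
  fit
}

#' Explained variance of the stochastic response function
#'
#' `100 * (1 - var(I - mu_hat - alpha_hat * X) / var(I - mu_hat))`:
#' the share of the trend-removed variance accounted for by adding the
#' climate predictor.  Sample variances over the observed fit period.
#'
#' @param I,X Data series.
#' @param mu_hat,alpha_hat Estimated trend and response weight.
#' @return Percent (<= 100).
#' @export
explained_variance <- function(I, X, mu_hat, alpha_hat) {
  ok <- is.finite(I) & is.finite(X)
  resid_full <- I[ok] - mu_hat[ok] - alpha_hat[ok] * X[ok]
  resid_trend <- I[ok] - mu_hat[ok]
  v0 <- stats::var(resid_trend)
  if (!is.finite(v0) || v0 == 0)
    stop_ringtruth("var(I - mu_hat) is zero: explained variance undefined",
                   "undefined_error")
  100 * (1 - stats::var(resid_full) / v0)
}

#' Significance trace and stability onset of the response weight
#'
#' A year is significant when zero lies strictly outside the 95\% band
#' of the smoothed response weight (a band exactly touching zero counts
#' as non-significant).  The stability onset is the earliest year from
#' which significance persists to the end of the series.
#'
#' @param fit An `stm_fit`.
#' @return List with `trace` (data.frame year, alpha, lower, upper,
#'   significant) and `onset` (year or NA).
#' @export
stability_trace <- function(fit) {
  stopifnot(inherits(fit, "stm_fit"))
  half <- fit$band_mult * sqrt(fit$alpha_var)
  lower <- fit$alpha_hat - half
  upper <- fit$alpha_hat + half
  sig <- lower > 0 | upper < 0
  onset <- NA
  if (any(sig)) {
    runs <- rev(cumprod(rev(sig)))   # 1 where significant to the end
    if (runs[length(runs)] == 1 || any(runs == 1))
      onset <- fit$years[which(runs == 1)[1]]
  }
  list(trace = data.frame(year = fit$years, alpha = fit$alpha_hat,
                          lower = lower, upper = upper,
                          significant = sig),
       onset = onset)
}

#' @export
print.stm_fit <- function(x, ...) {
  cat("Stochastic response function (Kalman-filter ML fit)\n")
  cat(sprintf("  n = %d, log-likelihood = %.3f\n",
              sum(is.finite(x$I)), x$loglik))
  cat(sprintf("  sigma2: eps = %.4g, zeta = %.4g, eta = %.4g\n",
              x$sig2[["eps"]], x$sig2[["zeta"]], x$sig2[["eta"]]))
  cat(sprintf("  explained variance: %.1f%% (smoothed), %.1f%% (filtered)\n",
              x$var_explained, x$var_explained_filtered))
  invisible(x)
}

#' @export
summary.stm_fit <- function(object, ...) {
  print(object)
  st <- stability_trace(object)
  cat(sprintf("  response weight: mean %.3f, range [%.3f, %.3f]\n",
              mean(object$alpha_hat), min(object$alpha_hat),
              max(object$alpha_hat)))
  cat(sprintf("  significant years: %d of %d; stability onset: %s\n",
              sum(st$trace$significant), nrow(st$trace),
              ifelse(is.na(st$onset), "none", st$onset)))
  invisible(object)
}

#' @export
coef.stm_fit <- function(object, ...) object$sig2

#' @export
logLik.stm_fit <- function(object, ...) {
  structure(object$loglik, df = sum(!(names(object$sig2) %in%
                                        names(object$fixed))),
            class = "logLik")
}

#' @export
fitted.stm_fit <- function(object, ...) {
  object$mu_hat + object$alpha_hat * object$X
}

#' @export
residuals.stm_fit <- function(object, ...) {
  object$I - fitted(object)
}

#' @export
plot.stm_fit <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  half <- x$band_mult * sqrt(x$mu_var)
  graphics::plot(x$years, x$mu_hat, type = "l", col = "red",
                 ylim = range(c(x$mu_hat - half, x$mu_hat + half, x$I),
                              na.rm = TRUE),
                 ylab = expression(mu[t]), xlab = "", ...)
  graphics::points(x$years, x$I, pch = 16, cex = 0.4)
  graphics::lines(x$years, x$mu_hat - half, lty = 3, col = "red")
  graphics::lines(x$years, x$mu_hat + half, lty = 3, col = "red")
  half <- x$band_mult * sqrt(x$alpha_var)
  graphics::plot(x$years, x$alpha_hat, type = "l", col = "blue",
                 ylim = range(c(x$alpha_hat - half, x$alpha_hat + half, 0)),
                 ylab = expression(alpha[t]), xlab = "year")
  graphics::lines(x$years, x$alpha_hat - half, lty = 3, col = "blue")
  graphics::lines(x$years, x$alpha_hat + half, lty = 3, col = "blue")
  graphics::abline(h = 0, lty = 1, col = "grey")
  invisible(x)
}

#' @export
simulate.stm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$I)
  doit <- function() {
    zeta <- stats::rnorm(n, sd = sqrt(object$sig2[["zeta"]]))
    eta <- stats::rnorm(n, sd = sqrt(object$sig2[["eta"]]))
    delta <- cumsum(zeta)
    mu <- object$mu_hat[1] + cumsum(c(0, delta[-n]))
    alpha <- object$alpha_hat[1] + cumsum(eta) - eta[1]
    mu + alpha * object$X + stats::rnorm(n, sd = sqrt(object$sig2[["eps"]]))
  }
  sims <- if (!is.null(seed)) with_seed(seed, replicate(nsim, doit()))
          else replicate(nsim, doit())
  as.data.frame(sims)
}

#' Write an STM fit as CSV + JSON summary
#'
#' @param fit An `stm_fit`.
#' @param csv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, the fit.
#' @export
write_stm <- function(fit, csv_path = NULL, json_path = NULL) {
  st <- stability_trace(fit)
  if (!is.null(csv_path)) {
    half_m <- fit$band_mult * sqrt(fit$mu_var)
    df <- data.frame(year = fit$years,
                     mu = fit$mu_hat, mu_lo = fit$mu_hat - half_m,
                     mu_hi = fit$mu_hat + half_m,
                     alpha = fit$alpha_hat,
                     alpha_lo = st$trace$lower, alpha_hi = st$trace$upper,
                     significant = st$trace$significant)
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      sigma2 = as.list(fit$sig2), loglik = fit$loglik,
      var_explained = fit$var_explained,
      var_explained_filtered = fit$var_explained_filtered,
      onset = if (is.na(st$onset)) NULL else st$onset),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}
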