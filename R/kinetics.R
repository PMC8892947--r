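# 1:1 (Langmuir) interaction model for surface plasmon resonance sensorgrams.
#
# Association phase (analyte at concentration C injected, t <= t_switch):
#   R(t) = R_eq * (1 - exp(-(k_on*C + k_off) * t)),
#   R_eq = R_max * C / (C + K_D),   K_D = k_off / k_on
# Dissociation phase (buffer only, t > t_switch):
#   R(t) = R(t_switch) * exp(-k_off * (t - t_switch))
#
# Curves recorded at several analyte concentrations are fitted jointly with a
# single global (k_on, k_off, R_max); K_D is reported as k_off/k_on.

#' Construct a 1:1 kinetic parameter set
#'
#' @param k_on Association rate constant, 1/(M*s); > 0.
#' @param k_off Dissociation rate constant, 1/s; >= 0.
#' @param R_max Surface capacity, response units; > 0.
#' @return A list of class `kinetic_params` with the derived `K_D = k_off/k_on`
#'   (molar).
#' @export
kinetic_params <- function(k_on, k_off, R_max) {
  stopifnot(k_on > 0, k_off >= 0, R_max > 0)
  structure(list(k_on = k_on, k_off = k_off, R_max = R_max,
                 K_D = k_off / k_on),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, digits = 3, ...) {
  cat(sprintf("k_on  = %s 1/(M*s)\nk_off = %s 1/s\nR_max = %s RU\nK_D   = %s M\n",
              signif(x$k_on, digits), signif(x$k_off, digits),
              signif(x$R_max, digits), signif(x$K_D, digits)))
  invisible(x)
}

#' Equilibrium dissociation constant
#'
#' @param params A [kinetic_params()] or [fit_one_to_one()] object.
#' @return `k_off / k_on`, in molar.
#' @export
dissociation_constant <- function(params) {
  if (inherits(params, "one_to_one_fit")) params <- params$params
  stopifnot(inherits(params, "kinetic_params"))
  params$k_off / params$k_on
}

# Noise-free 1:1 model response at the given times.
.one_to_one_response <- function(k_on, k_off, R_max, conc, times, t_switch) {
  k_obs <- k_on * conc + k_off
  K_D <- k_off / k_on
  R_eq <- R_max * conc / (conc + K_D)
  r <- numeric(length(times))
  assoc <- times <= t_switch
  r[assoc] <- R_eq * (1 - exp(-k_obs * times[assoc]))
  if (any(!assoc)) {
    R_sw <- R_eq * (1 - exp(-k_obs * t_switch))
    r[!assoc] <- R_sw * exp(-k_off * (times[!assoc] - t_switch))
  }
  r
}

#' Simulate a two-phase 1:1 sensorgram
#'
#' @param params A [kinetic_params()].
#' @param conc Analyte concentration, M.
#' @param times Strictly increasing time grid, s.
#' @param t_switch Association-to-dissociation switch time, s (within the
#'   time range).
#' @param noise_sd Additive Gaussian noise standard deviation, response units.
#' @param seed Optional RNG seed for the noise draw.
#' @return A list of class `sensorgram` with `conc`, `times`, `response`,
#'   `t_switch`.
#' @export
simulate_sensorgram <- function(params, conc, times, t_switch,
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"), conc > 0, noise_sd >= 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (t_switch < min(times) || t_switch > max(times)) {
    stop("t_switch must lie within the time range")
  }
  r <- .one_to_one_response(params$k_on, params$k_off, params$R_max,
                            conc, times, t_switch)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    r <- r + stats::rnorm(length(r), sd = noise_sd)
  }
  structure(list(conc = conc, times = times, response = r,
                 t_switch = t_switch),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram: %g M analyte, %d points, switch at %g s>\n",
              x$conc, length(x$times), x$t_switch))
  invisible(x)
}

#' Read sensorgrams from CSV
#'
#' Expects columns `time`, `response`, `concentration` and `phase`
#' (`association`/`dissociation`); one curve per concentration.
#'
#' @param path CSV path.
#' @return List of `sensorgram` objects.
#' @export
read_sensorgrams <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time", "response", "concentration", "phase")
  if (!all(req %in% names(d))) {
    stop("sensorgram CSV needs columns: ", paste(req, collapse = ", "))
  }
  lapply(split(d, d$concentration), function(dd) {
    dd <- dd[order(dd$time), ]
    t_sw <- max(dd$time[dd$phase == "association"])
    structure(list(conc = dd$concentration[1], times = dd$time,
                   response = dd$response, t_switch = t_sw),
              class = "sensorgram")
  })
}

# Feature-based starting values: R_max from the largest observed response,
# k_off from a log-linear fit of the highest-concentration dissociation tail,
# k_on from per-curve observed association rates.
.init_one_to_one <- function(curves) {
  r_all <- unlist(lapply(curves, `[[`, "response"))
  R_max0 <- 1.2 * max(r_all)
  top <- curves[[which.max(vapply(curves, `[[`, numeric(1), "conc"))]]
  tail_i <- which(top$times > top$t_switch & top$response > 0)
  k_off0 <- 1e-3
  if (length(tail_i) >= 3L) {
    sl <- stats::coef(stats::lm(log(top$response[tail_i]) ~ top$times[tail_i]))[2]
    if (is.finite(sl) && sl < 0) k_off0 <- -sl
  }
  k_off0 <- max(k_off0, 1e-8)
  k_on0s <- vapply(curves, function(cv) {
    a <- cv$times <= cv$t_switch
    plateau <- max(cv$response[a])
    if (plateau <= 0) return(NA_real_)
    half_t <- cv$times[a][which(cv$response[a] >= plateau / 2)[1]]
    if (is.na(half_t) || half_t <= 0) return(NA_real_)
    k_obs <- log(2) / half_t
    max(k_obs - k_off0, 0.1 * k_obs) / cv$conc
  }, numeric(1))
  k_on0 <- stats::median(k_on0s, na.rm = TRUE)
  if (!is.finite(k_on0) || k_on0 <= 0) k_on0 <- 1e4
  kinetic_params(k_on0, k_off0, R_max0)
}

#' Fit the global 1:1 binding model to sensorgrams
#'
#' Joint nonlinear least squares over all curves, which share one global
#' (`k_on`, `k_off`, `R_max`). Parameters are optimized on the log scale
#' (Levenberg-Marquardt, via minpack.lm); starting values default to curve
#' features (`R_max` from 1.2x the largest response, `k_off` from the
#' dissociation tail, `k_on` from observed association rates). Per-parameter
#' standard errors come from the residual-variance-scaled parameter
#' covariance, propagated from the log scale.
#'
#' @param curves List of `sensorgram` objects (>= 1).
#' @param init Optional [kinetic_params()] starting values.
#' @param control Passed to [minpack.lm::nls.lm.control()] entries.
#' @return An object of class `one_to_one_fit`; see [coef.one_to_one_fit()],
#'   [summary.one_to_one_fit()], [predict.one_to_one_fit()].
#' @export
fit_one_to_one <- function(curves, init = NULL, control = list()) {
  if (inherits(curves, "sensorgram")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "sensorgram")))
  if (length(curves) == 1L &&
      stats::sd(curves[[1]]$response) < 1e-12 * max(abs(curves[[1]]$response), 1)) {
    warning("single flat curve: the fit is ill-conditioned")
  }
  if (is.null(init)) init <- .init_one_to_one(curves)
  resid_fn <- function(logp) {
    p <- exp(logp)
    unlist(lapply(curves, function(cv) {
      .one_to_one_response(p[1], p[2], p[3], cv$conc, cv$times, cv$t_switch) -
        cv$response
    }))
  }
  ctrl <- utils::modifyList(
    list(maxiter = 500, ftol = 1e-14, ptol = 1e-14, gtol = 0),
    control)
  start <- log(c(init$k_on, max(init$k_off, 1e-10), init$R_max))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = do.call(minpack.lm::nls.lm.control, ctrl))
  if (!(fit$info %in% 1:4)) {
    stop(sprintf("1:1 fit did not converge (info %d); final sum of squares %g",
                 fit$info, fit$deviance))
  }
  p <- exp(fit$par)
  params <- kinetic_params(p[1], p[2], p[3])
  n_obs <- sum(vapply(curves, function(cv) length(cv$times), integer(1)))
  dof <- n_obs - 3L
  sigma2 <- fit$deviance / max(dof, 1L)
  vcov_log <- tryCatch(sigma2 * solve(fit$hessian),
                       error = function(e) matrix(NA_real_, 3, 3))
  se_log <- sqrt(pmax(diag(vcov_log), 0))
  se <- p * se_log                      # delta method, log -> natural scale
  kd_se <- params$K_D * sqrt(se_log[2]^2 + se_log[1]^2 -
                               2 * vcov_log[1, 2])
  fitted <- lapply(curves, function(cv) {
    .one_to_one_response(p[1], p[2], p[3], cv$conc, cv$times, cv$t_switch)
  })
  structure(list(params = params,
                 se = stats::setNames(c(se, kd_se),
                                      c("k_on", "k_off", "R_max", "K_D")),
                 vcov_log = vcov_log,
                 curves = curves, fitted = fitted,
                 ssr = fit$deviance, sigma = sqrt(sigma2), df.residual = dof,
                 init = init, niter = fit$niter, info = fit$info,
                 call = match.call()),
            class = "one_to_one_fit")
}

#' @export
coef.one_to_one_fit <- function(object, ...) {
  with(object$params,
       c(k_on = k_on, k_off = k_off, R_max = R_max, K_D = K_D))
}

#' @export
print.one_to_one_fit <- function(x, digits = 3, ...) {
  cat("Global 1:1 binding fit\n")
  cat(sprintf("  %d curve(s), %d observations, residual SE %.3g\n",
              length(x$curves), sum(lengths(lapply(x$curves, `[[`, "times"))),
              x$sigma))
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
summary.one_to_one_fit <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(estimate = est, std.error = object$se[names(est)])
  structure(list(coefficients = tab, sigma = object$sigma, ssr = object$ssr,
                 df.residual = object$df.residual, niter = object$niter),
            class = "summary.one_to_one_fit")
}

#' @export
print.summary.one_to_one_fit <- function(x, digits = 3, ...) {
  cat("Global 1:1 binding fit\n\nCoefficients:\n")
  print(signif(as.matrix(x$coefficients), digits))
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom (%d iterations)\n",
              x$sigma, x$df.residual, x$niter))
  invisible(x)
}

#' Predict model responses
#'
#' @param object A `one_to_one_fit`.
#' @param newdata Optional list of `sensorgram`-like lists (`conc`, `times`,
#'   `t_switch`); defaults to the fitted curves.
#' @param ... Unused.
#' @return List of numeric response vectors, one per curve.
#' @export
predict.one_to_one_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!is.null(newdata$conc)) newdata <- list(newdata)
  p <- object$params
  lapply(newdata, function(cv) {
    .one_to_one_response(p$k_on, p$k_off, p$R_max, cv$conc, cv$times,
                         cv$t_switch)
  })
}

#' @export
residuals.one_to_one_fit <- function(object, ...) {
  lapply(seq_along(object$curves), function(i) {
    object$curves[[i]]$response - object$fitted[[i]]
  })
}

#' @export
plot.one_to_one_fit <- function(x, ...) {
  all_t <- unlist(lapply(x$curves, `[[`, "times"))
  all_r <- unlist(lapply(x$curves, `[[`, "response"))
  graphics::plot(NA, xlim = range(all_t), ylim = range(c(all_r, 0)),
                 xlab = "time (s)", ylab = "response (RU)", ...)
  for (i in seq_along(x$curves)) {
    graphics::points(x$curves[[i]]$times, x$curves[[i]]$response,
                     pch = 16, cex = 0.3, col = "grey60")
    graphics::lines(x$curves[[i]]$times, x$fitted[[i]], col = i, lwd = 2)
  }
  invisible(x)
}

#' Simulate sensorgrams from a fitted 1:1 model
#'
#' @param object A `one_to_one_fit`.
#' @param nsim Number of replicate curve sets.
#' @param seed Optional RNG seed.
#' @param noise_sd Gaussian noise SD; defaults to the fit's residual SE.
#' @param ... Unused.
#' @return List of `nsim` lists of `sensorgram`s matching the fitted design.
#' @export
simulate.one_to_one_fit <- function(object, nsim = 1, seed = NULL,
                                    noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- object$sigma
  lapply(seq_len(nsim), function(i) {
    lapply(object$curves, function(cv) {
      simulate_sensorgram(object$params, cv$conc, cv$times, cv$t_switch,
                          noise_sd = noise_sd)
    })
  })
}
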