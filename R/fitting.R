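#' Fit configuration
#'
#' Controls the weighted nonlinear least-squares fit. Defaults: only the
#' first 15 minutes of the scan are fitted (the carbon-11 signal decays too
#' fast for later frames to be informative); weights
#' `w_i = dt_i * exp(-lambda t_mid,i)` (inverse-variance up to the activity
#' term under the frame-weighted Gaussian noise model); bounds
#' K1 in \[0,5\] mL/min/g, k2 in \[0,2\]/min, k3 in \[0,1\]/min, Vb in
#' \[0,1\]; 5 multi-starts jittered by a seeded RNG around the initial
#' values. The blood fraction Vb is fitted for the myocardium but fixed
#' (default 0.10) for the renal cortex, where segmentation avoids large
#' vessels; set `fit_vb` accordingly.
#'
#' @param window_min fit window in minutes, `c(start, end)`.
#' @param weights `"frame_duration_decay"` or `"uniform"`.
#' @param init a [kinetic_params()] of initial values.
#' @param bounds named list of `c(lower, upper)` for K1, k2, k3, Vb.
#' @param fit_vb logical: estimate Vb (TRUE) or fix it at `vb_fixed`.
#' @param vb_fixed fixed blood fraction used when `fit_vb = FALSE`.
#' @param multi_start number of seeded restarts (>= 1).
#' @param max_iter maximum optimizer iterations per start.
#' @param seed RNG seed for the restart jitter.
#' @param halflife minutes, for the decay weighting.
#' @param step_s model-evaluation fine-grid step, seconds.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(window_min = c(0, 15),
                       weights = c("frame_duration_decay", "uniform"),
                       init = kinetic_params(0.5, 0.1, 0.01, 0.3),
                       bounds = list(K1 = c(0, 5), k2 = c(0, 2),
                                     k3 = c(0, 1), Vb = c(0, 1)),
                       fit_vb = TRUE, vb_fixed = 0.10,
                       multi_start = 5, max_iter = 200, seed = 1,
                       halflife = 20.364, step_s = 0.5) {
  weights <- match.arg(weights)
  if (window_min[2] <= window_min[1]) stop("invalid fit window")
  for (nm in c("K1", "k2", "k3", "Vb")) {
    b <- bounds[[nm]]
    if (is.null(b) || b[1] > init[[nm]] || b[2] < init[[nm]])
      stop("bounds for ", nm, " must contain the initial value")
  }
  structure(list(window_min = window_min, weights = weights, init = init,
                 bounds = bounds, fit_vb = fit_vb, vb_fixed = vb_fixed,
                 multi_start = multi_start, max_iter = max_iter, seed = seed,
                 halflife = halflife, step_s = step_s),
            class = "fit_config")
}

#' Fit a compartment model to a TAC
#'
#' Minimizes the weighted residual sum of squares
#' `sum_i w_i (y_i - yhat_i(theta))^2` over the kinetic parameters within
#' bounds, using bounded Levenberg-Marquardt ([minpack.lm::nls.lm()]) with
#' `cfg$multi_start` seeded restarts; the best start by weighted RSS wins.
#' The model prediction is computed exactly as the simulator computes a
#' frame: fine-grid convolution followed by frame averaging, so noiseless
#' simulated data are recovered to numerical precision. Deterministic under
#' a fixed `cfg$seed`.
#'
#' @param x a decay-corrected [tac()] in kBq/mL.
#' @param Cp plasma parent input function (metabolite-corrected).
#' @param Cb whole-blood input function (defaults to `Cp`).
#' @param model `"1tc"` or `"2tc_irr"`.
#' @param cfg a [fit_config()].
#' @return An object of class `fit_result` with elements `params`
#'   ([kinetic_params()]), `rss` (weighted), `n`, `p`, `aic`, `converged`,
#'   `degenerate`, `residuals`, `fitted`, `model`, and the data used.
#' @export
fit_model <- function(x, Cp, Cb = Cp, model = c("1tc", "2tc_irr"),
                      cfg = fit_config()) {
  model <- match.arg(model)
  if (!inherits(x, "tac")) stop("x must be a tac")
  if (!x$decay_corrected) stop("TAC must be decay-corrected before fitting")
  fs <- x$schedule
  keep <- fs$frame_start >= cfg$window_min[1] * 60 - 1e-9 &
    fs$frame_end <= cfg$window_min[2] * 60 + 1e-9
  if (sum(keep) < 4) stop("fit window contains too few frames")
  sub <- frame_schedule(fs$frame_start[keep], fs$frame_end[keep])
  y <- x$value[keep]
  tg <- fine_grid(sub, cfg$step_s)
  h <- tg[2] - tg[1]
  cp <- eval_input_function(Cp, tg)
  cb <- eval_input_function(Cb, tg)
  lambda <- log(2) / cfg$halflife
  w <- switch(cfg$weights,
              uniform = rep(1, sum(keep)),
              frame_duration_decay =
                frame_duration(sub, "min") *
                exp(-lambda * frame_mid(sub, "min")))
  sw <- sqrt(w / mean(w))

  free <- c("K1", "k2", if (model == "2tc_irr") "k3",
            if (cfg$fit_vb) "Vb")
  lower <- vapply(free, function(nm) cfg$bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) cfg$bounds[[nm]][2], numeric(1))

  predict_fn <- function(theta) {
    th <- as.list(theta)
    K1 <- th$K1; k2 <- th$k2
    k3 <- if (model == "2tc_irr") th$k3 else 0
    Vb <- if (cfg$fit_vb) th$Vb else cfg$vb_fixed
    ct <- tissue_curve_2tc_irr(K1, k2, k3, cp, h)
    frame_average((1 - Vb) * ct + Vb * cb, tg, sub)
  }
  resid_fn <- function(theta) {
    names(theta) <- free
    sw * (y - predict_fn(theta))
  }

  init_full <- unlist(cfg$init[c("K1", "k2", "k3", "Vb")])
  starts <- list(pmin(pmax(init_full[free], lower), upper))
  if (cfg$multi_start > 1) {
    # jitter from a private stream so fitting never disturbs caller RNG
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(cfg$seed)
    for (j in seq_len(cfg$multi_start - 1)) {
      jit <- starts[[1]] * exp(stats::rnorm(length(free), 0, 0.6))
      jit[starts[[1]] == 0] <- stats::runif(sum(starts[[1]] == 0)) *
        (upper - lower)[starts[[1]] == 0] * 0.1
      starts[[j + 1]] <- pmin(pmax(jit, lower), upper)
    }
  }

  best <- NULL
  any_converged <- FALSE
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = cfg$max_iter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    ok <- fit$info %in% 1:4
    any_converged <- any_converged || ok
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  names(theta) <- free
  fitted <- predict_fn(theta)
  res <- y - fitted
  rss <- sum(w / mean(w) * res^2)
  n <- length(y); p <- length(free)
  degenerate <- all(abs(y) < 1e-12) || theta[["K1"]] <= lower[["K1"]] + 1e-12
  kp <- kinetic_params(
    K1 = theta[["K1"]], k2 = theta[["k2"]],
    k3 = if (model == "2tc_irr") theta[["k3"]] else 0,
    Vb = if (cfg$fit_vb) theta[["Vb"]] else cfg$vb_fixed)
  structure(list(params = kp, rss = rss, n = n, p = p,
                 aic = compute_aic(rss, n, p),
                 converged = any_converged, degenerate = degenerate,
                 residuals = res, fitted = fitted, weights = w / mean(w),
                 model = model, window_min = cfg$window_min, y = y,
                 cfg = cfg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s: K1=%.4f k2=%.4f k3=%.4f Vb=%.3f | wRSS=%.4g AIC=%.2f%s\n",
    x$model, x$params$K1, x$params$k2, x$params$k3, x$params$Vb,
    x$rss, x$aic,
    if (!x$converged) " (NOT CONVERGED)"
    else if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Akaike information criterion from a weighted RSS
#'
#' Uses the least-squares convention `AIC = n log(RSS/n) + 2p` (absolute
#' values are convention-dependent; only differences between models fitted
#' to the same data are meaningful). `AICc` adds the small-sample term
#' `2p(p+1)/(n-p-1)`.
#'
#' @param rss weighted residual sum of squares (> 0).
#' @param n number of fitted frames.
#' @param p number of estimated parameters (`n > p` required).
#' @param correct logical: return AICc.
#' @return AIC value; `-Inf` with a warning when `rss == 0`.
#' @export
compute_aic <- function(rss, n, p, correct = FALSE) {
  if (n <= p) stop("n must exceed p")
  if (rss < 0) stop("rss must be >= 0")
  if (rss == 0) {
    warning("rss is exactly 0; AIC is -Inf")
    return(-Inf)
  }
  aic <- n * log(rss / n) + 2 * p
  if (correct) aic <- aic + 2 * p * (p + 1) / (n - p - 1)
  aic
}

#' Compare two fitted models by AIC
#'
#' @param fit_a,fit_b [fit_model()] results on the same TAC and window.
#' @param threshold absolute AIC difference below which the two models are
#'   declared equivalent (default 2, the usual rule of thumb).
#' @return A list with `delta_aic` (`AIC_a - AIC_b`), `preferred`
#'   (`"a"`, `"b"`, or `"tie"`), and `equivalent`.
#' @export
compare_models <- function(fit_a, fit_b, threshold = 2) {
  if (!inherits(fit_a, "fit_result") || !inherits(fit_b, "fit_result"))
    stop("both arguments must be fit_result objects")
  if (fit_a$n != fit_b$n || !isTRUE(all.equal(fit_a$y, fit_b$y)) ||
      !identical(fit_a$window_min, fit_b$window_min))
    stop("fits are not on the same TAC and window")
  d <- fit_a$aic - fit_b$aic
  list(delta_aic = d,
       preferred = if (d < 0) "a" else if (d > 0) "b" else "tie",
       equivalent = abs(d) < threshold,
       threshold = threshold)
}
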