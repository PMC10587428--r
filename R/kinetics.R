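#' Kinetic parameters of a compartment model
#'
#' `K1` (mL/min/g) is the blood-to-tissue transport (uptake/perfusion) rate,
#' `k2` (per minute) the tissue clearance rate, `k3` (per minute) the rate of
#' irreversible local accumulation (0 selects the one-tissue model), and `Vb`
#' the fractional blood (spillover/partial-volume) contribution to the
#' measured signal.
#'
#' @param K1 mL/min/g, >= 0.
#' @param k2 per minute, >= 0.
#' @param k3 per minute, >= 0; `k3 = 0` identifies the one-tissue model.
#' @param Vb fraction in \[0, 1\].
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, Vb = 0) {
  if (K1 < 0 || k2 < 0 || k3 < 0) stop("K1, k2, k3 must be >= 0")
  if (Vb < 0 || Vb > 1) stop("Vb must be in [0, 1]")
  structure(list(K1 = K1, k2 = k2, k3 = k3, Vb = Vb),
            class = "kinetic_params")
}

# Exact convolution of a piecewise-linear curve y(t) (sampled on a uniform
# grid, step h minutes) with exp(-beta t):
#   z(t_i) = int_0^{t_i} y(s) exp(-beta (t_i - s)) ds
# Each segment contributes a closed-form increment; the running value decays
# by exp(-beta h) per step, which is a first-order recursive filter.
conv_exp_plin <- function(y, h, beta) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  if (beta * h < 1e-8) {
    # beta ~ 0: plain cumulative trapezoid
    return(c(0, cumsum((y[-1] + y[-n]) / 2 * h)))
  }
  E <- exp(-beta * h)
  a <- (1 - E) / beta                       # int_0^h e^{-beta(h-u)} du
  b <- (1 - (1 - E) / (beta * h)) / beta    # int_0^h (u/h) e^{-beta(h-u)} du
  d <- diff(y)
  q <- y[-n] * a + d * b
  c(0, as.numeric(stats::filter(q, E, method = "recursive")))
}

# Cumulative integral of a piecewise-linear curve on a uniform grid (exact).
cum_trapz <- function(y, h) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * h))
}

# Tissue impulse responses convolved with a sampled plasma curve cp on a
# uniform grid (step h, minutes). Returns the tissue concentration C_t.
tissue_curve_1tc <- function(K1, k2, cp, h) {
  K1 * conv_exp_plin(cp, h, k2)
}

tissue_curve_2tc_irr <- function(K1, k2, k3, cp, h) {
  if (k2 + k3 <= 0) return(K1 * cum_trapz(cp, h))       # pure trapping
  if (k3 == 0) return(tissue_curve_1tc(K1, k2, cp, h))  # exact 1TC nesting
  # C_t = K1/(k2+k3) * [k3 * 1 + k2 * e^{-(k2+k3)t}] (x) Cp
  K1 / (k2 + k3) *
    (k3 * cum_trapz(cp, h) + k2 * conv_exp_plin(cp, h, k2 + k3))
}

#' One-tissue compartment model curve
#'
#' Computes the measured model curve `(1 - Vb) C_t(t) + Vb C_b(t)` on a time
#' grid, where the tissue concentration follows
#' `dC_t/dt = K1 Cp - k2 C_t`, i.e.
#' \eqn{C_t(t) = K_1 \int_0^t C_p(s) e^{-k_2 (t-s)} ds}. The convolution is
#' computed exactly for the piecewise-linear sampled plasma curve (no FFT),
#' which is accurate on uneven late frames.
#'
#' @param params a [kinetic_params()] with `k3 = 0`.
#' @param Cp plasma (parent) input function, an `input_function`.
#' @param Cb whole-blood input function (defaults to `Cp`).
#' @param t_grid uniform time grid in minutes, starting at 0.
#' @return Numeric vector: model curve on `t_grid` (kBq/mL).
#' @export
model_1tc <- function(params, Cp, Cb = Cp, t_grid) {
  if (params$k3 != 0) stop("model_1tc requires k3 = 0; use model_2tc_irr")
  h <- check_uniform_grid(t_grid)
  cp <- eval_input_function(Cp, t_grid)
  cb <- eval_input_function(Cb, t_grid)
  ct <- tissue_curve_1tc(params$K1, params$k2, cp, h)
  (1 - params$Vb) * ct + params$Vb * cb
}

#' Irreversible two-tissue compartment model curve
#'
#' Tissue concentration `C_t = C_1 + C_2` with
#' `dC1/dt = K1 Cp - (k2 + k3) C1`, `dC2/dt = k3 C1`, computed by exact
#' convolution of the closed-form impulse response
#' \eqn{K_1/(k_2+k_3) [k_3 + k_2 e^{-(k_2+k_3) t}]} with the piecewise-linear
#' plasma curve. With `k3 = 0` this reduces exactly to [model_1tc()] (same
#' code path); with `k2 + k3 = 0` it falls back to pure integration
#' `K1 * int Cp`. Blood mixing as in [model_1tc()].
#'
#' @inheritParams model_1tc
#' @param params a [kinetic_params()].
#' @return Numeric vector: model curve on `t_grid` (kBq/mL).
#' @export
model_2tc_irr <- function(params, Cp, Cb = Cp, t_grid) {
  h <- check_uniform_grid(t_grid)
  cp <- eval_input_function(Cp, t_grid)
  cb <- eval_input_function(Cb, t_grid)
  ct <- tissue_curve_2tc_irr(params$K1, params$k2, params$k3, cp, h)
  (1 - params$Vb) * ct + params$Vb * cb
}

check_uniform_grid <- function(t_grid) {
  if (length(t_grid) < 2L) stop("t_grid needs at least 2 points")
  if (abs(t_grid[1]) > 1e-12) stop("t_grid must start at 0")
  h <- diff(t_grid)
  if (max(abs(h - h[1])) > 1e-9 * max(h))
    stop("t_grid must be uniform")
  h[1]
}

#' Average a continuous curve over acquisition frames
#'
#' Averages a curve sampled on a uniform fine grid over the frames of a
#' schedule, by trapezoidal integration; this is the package's definition
#' of "the TAC value of a frame". Frame boundaries must fall on grid
#' points, which [fine_grid()] guarantees.
#'
#' @param z curve values on the fine grid.
#' @param t_grid_min uniform fine grid in minutes (from [fine_grid()]).
#' @param fs a [frame_schedule()].
#' @return Numeric vector of per-frame averages.
#' @export
frame_average <- function(z, t_grid_min, fs) {
  start_min <- fs$frame_start / 60
  end_min <- fs$frame_end / 60
  h <- t_grid_min[2] - t_grid_min[1]
  i0 <- round(start_min / h) + 1L
  i1 <- round(end_min / h) + 1L
  if (max(i1) > length(z))
    stop("fine grid does not cover the frame schedule")
  vapply(seq_along(i0), function(k) {
    idx <- i0[k]:i1[k]
    zz <- z[idx]
    sum((zz[-1] + zz[-length(zz)]) / 2) * h / (end_min[k] - start_min[k])
  }, numeric(1))
}

#' Uniform fine time grid covering a frame schedule
#'
#' Builds a uniform grid in minutes with step at most `step_s` seconds,
#' shrunk if necessary so that every frame boundary lands exactly on a
#' grid point.
#'
#' @param fs a [frame_schedule()].
#' @param step_s requested maximum step in seconds.
#' @return Numeric vector of times in minutes starting at 0.
#' @export
fine_grid <- function(fs, step_s = 0.5) {
  bounds <- sort(unique(c(fs$frame_start, fs$frame_end)))
  g <- gcd_vec(round(bounds[bounds > 0] * 1000))
  step <- min(step_s * 1000, g)
  # shrink to a divisor of g no larger than requested
  while (g %% step != 0) step <- step - 1
  seq(0, max(fs$frame_end), by = step / 1000) / 60
}

gcd_vec <- function(x) Reduce(function(a, b) {
  while (b) { t <- b; b <- a %% b; a <- t }
  a
}, x)
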