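#' Organ-level ground truth for simulation
#'
#' Bundles the kinetic parameters of a region with, for the renal pelvis
#' under the ketone tracer, the parameters of the delayed second excretion
#' peak (a gamma-variate component riding on the early vascular transit).
#'
#' @param region one of `"myocardium"`, `"renal_cortex"`, `"renal_pelvis"`,
#'   `"lv_blood"`.
#' @param params a [kinetic_params()] (ignored for `lv_blood`).
#' @param second_peak `NULL`, or (renal pelvis only) a list with elements
#'   `amplitude` (kBq/mL, peak height), `mode_min` (time of the mode,
#'   minutes, > 0), `onset_min` (appearance time, minutes, < mode) and
#'   `shape` (gamma-variate shape alpha > 0).
#' @param vascular_fraction fraction of the whole-blood curve seen in the
#'   pelvis as the early transit component (pelvis only).
#' @return An object of class `organ_truth`.
#' @export
organ_truth <- function(region = c("myocardium", "renal_cortex",
                                   "renal_pelvis", "lv_blood"),
                        params = kinetic_params(0, 0),
                        second_peak = NULL, vascular_fraction = 0.25) {
  region <- match.arg(region)
  if (!inherits(params, "kinetic_params"))
    stop("params must be kinetic_params")
  if (!is.null(second_peak)) {
    if (region != "renal_pelvis")
      stop("second_peak is only meaningful for the renal pelvis")
    req <- c("amplitude", "mode_min", "onset_min", "shape")
    if (!all(req %in% names(second_peak)))
      stop("second_peak needs elements: ", paste(req, collapse = ", "))
    if (second_peak$mode_min <= 0) stop("second-peak mode_min must be > 0")
    if (second_peak$onset_min >= second_peak$mode_min)
      stop("second-peak onset must precede its mode")
    if (second_peak$shape <= 0) stop("second-peak shape must be > 0")
    if (second_peak$amplitude < 0) stop("second-peak amplitude must be >= 0")
  }
  if (vascular_fraction < 0) stop("vascular_fraction must be >= 0")
  structure(list(region = region, params = params,
                 second_peak = second_peak,
                 vascular_fraction = vascular_fraction),
            class = "organ_truth")
}

#' Simulate a tissue time-activity curve
#'
#' Forward-simulates the measured regional TAC
#' `(1 - Vb) C_t(t) + Vb C_b(t)` on a fine uniform grid (step <= `step_s`
#' seconds) and averages it over the frames of the schedule by trapezoidal
#' integration. The tissue curve follows the one-tissue model, or the
#' irreversible two-tissue model when `truth$params$k3 > 0`. Output is
#' noiseless and decay-corrected; see [add_noise()].
#'
#' @param truth an [organ_truth()].
#' @param p plasma (parent) input function driving the tissue.
#' @param fs a [frame_schedule()].
#' @param blood_fraction fractional blood signal Vb in \[0,1\]; defaults to
#'   `truth$params$Vb`.
#' @param Cb whole-blood input function mixed into the signal
#'   (defaults to `p`).
#' @param step_s fine-grid step in seconds (<= 0.5 recommended).
#' @return A [tac()] in kBq/mL.
#' @export
simulate_tissue_tac <- function(truth, p, fs,
                                blood_fraction = truth$params$Vb,
                                Cb = p, step_s = 0.5) {
  if (!inherits(truth, "organ_truth")) stop("truth must be an organ_truth")
  if (blood_fraction < 0 || blood_fraction > 1)
    stop("blood_fraction must be in [0, 1]")
  tg <- fine_grid(fs, step_s)
  kp <- truth$params
  cp <- eval_input_function(p, tg)
  cb <- eval_input_function(Cb, tg)
  ct <- tissue_curve_2tc_irr(kp$K1, kp$k2, kp$k3, cp, tg[2] - tg[1])
  z <- (1 - blood_fraction) * ct + blood_fraction * cb
  tac(fs, frame_average(z, tg, fs), units = "kBq/mL",
      decay_corrected = TRUE, region = truth$region)
}

# gamma-variate pulse: peaks at value `amplitude` when t = mode_min
gamma_variate <- function(t, amplitude, mode_min, onset_min, shape) {
  u <- (t - onset_min) / (mode_min - onset_min)
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- amplitude * u[pos]^shape * exp(shape * (1 - u[pos]))
  out
}

#' Simulate a renal-pelvis time-activity curve
#'
#' The pelvis signal is the sum of an early vascular-transit component (a
#' scaled whole-blood curve) and, when `truth$second_peak` is set, a delayed
#' gamma-variate excretion component. The second component models the
#' delayed urinary appearance of label seen with the ketone tracer (and its
#' downstream metabolite), producing a second, typically larger, peak
#' several minutes post injection; with the second component disabled the
#' curve is single-peaked, as observed with acetate.
#'
#' @inheritParams simulate_tissue_tac
#' @param truth an [organ_truth()] with `region = "renal_pelvis"`.
#' @return A [tac()] in kBq/mL.
#' @export
simulate_pelvis_tac <- function(truth, p, fs, step_s = 0.5) {
  if (!inherits(truth, "organ_truth") || truth$region != "renal_pelvis")
    stop("truth must be an organ_truth for the renal pelvis")
  tg <- fine_grid(fs, step_s)
  z <- truth$vascular_fraction * eval_input_function(p, tg)
  if (!is.null(truth$second_peak)) {
    sp <- truth$second_peak
    z <- z + gamma_variate(tg, sp$amplitude, sp$mode_min, sp$onset_min,
                           sp$shape)
  }
  tac(fs, frame_average(z, tg, fs), units = "kBq/mL",
      decay_corrected = TRUE, region = "renal_pelvis")
}

#' Frame-weighted Gaussian noise specification
#'
#' Noise standard deviation per frame follows the standard decay-corrected
#' PET TAC heteroscedasticity:
#' `SD_i = scale * sqrt(max(value_i, 0) * exp(lambda * t_mid_i) / dt_i)`
#' with `lambda = log(2)/halflife`, `t_mid` the frame mid-time and `dt` the
#' frame duration (minutes): short early frames and decay-inflated late
#' frames are noisier.
#'
#' @param scale dimensionless noise scale (>= 0); 0 means noiseless.
#' @param seed integer seed for reproducible noise, or `NULL` to draw from
#'   the current RNG stream.
#' @return An object of class `noise_spec` (model tag
#'   `"frame_weighted_gaussian"`).
#' @export
noise_spec <- function(scale = 0.05, seed = NULL) {
  if (scale < 0) stop("scale must be >= 0")
  structure(list(scale = scale, seed = seed,
                 model = "frame_weighted_gaussian"),
            class = "noise_spec")
}

#' Add frame-weighted Gaussian noise to a TAC
#'
#' @param x a [tac()].
#' @param spec a [noise_spec()].
#' @param halflife physical half-life in minutes (default carbon-11).
#' @return The noisy [tac()]; identical to `x` when `spec$scale == 0`.
#' @export
add_noise <- function(x, spec = noise_spec(), halflife = 20.364) {
  if (!inherits(x, "tac")) stop("x must be a tac")
  if (!inherits(spec, "noise_spec")) stop("spec must be a noise_spec")
  if (spec$scale == 0) return(x)
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  lambda <- log(2) / halflife
  sd <- spec$scale * sqrt(pmax(x$value, 0) * exp(lambda * tac_mid_min(x)) /
                            tac_dur_min(x))
  x$value <- x$value + stats::rnorm(length(sd), 0, sd)
  x
}

#' Noise standard deviation implied by a noise specification
#'
#' Closed-form per-frame SD used by [add_noise()]; exposed for calibration
#' checks.
#'
#' @inheritParams add_noise
#' @return Numeric vector of per-frame standard deviations.
#' @export
noise_sd <- function(x, spec, halflife = 20.364) {
  lambda <- log(2) / halflife
  spec$scale * sqrt(pmax(x$value, 0) * exp(lambda * tac_mid_min(x)) /
                      tac_dur_min(x))
}
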