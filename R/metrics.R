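#' Subject vitals
#'
#' @param HR heart rate, beats/min (> 0).
#' @param SBP systolic blood pressure, mmHg (> 0).
#' @param dose_MBq injected activity, MBq (> 0).
#' @param weight_kg body weight, kg (> 0).
#' @return An object of class `subject_vitals`.
#' @export
subject_vitals <- function(HR, SBP, dose_MBq, weight_kg) {
  v <- c(HR = HR, SBP = SBP, dose_MBq = dose_MBq, weight_kg = weight_kg)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all vitals must be finite and > 0")
  structure(as.list(v), class = "subject_vitals")
}

#' Convert a TAC to standardized uptake value units
#'
#' `SUV(t) = C(t) / (injected dose / body weight)` with activity in kBq/mL,
#' dose converted MBq -> kBq and weight kg -> g (tissue density taken as
#' 1 g/mL), i.e. numerically `SUV = C * weight_kg / dose_MBq`.
#'
#' @param x a decay-corrected [tac()] in kBq/mL.
#' @param vitals a [subject_vitals()].
#' @return The [tac()] rescaled, `units = "SUV"`.
#' @export
suv_curve <- function(x, vitals) {
  if (!inherits(x, "tac")) stop("x must be a tac")
  if (x$units != "kBq/mL") stop("TAC must be in kBq/mL")
  if (!x$decay_corrected) stop("TAC must be decay-corrected")
  if (!inherits(vitals, "subject_vitals"))
    stop("vitals must be subject_vitals")
  x$value <- x$value * vitals$weight_kg / vitals$dose_MBq
  x$units <- "SUV"
  x
}

#' Global peak of a TAC
#'
#' Maximum frame value and the mid-time of that frame; ties are broken by
#' the earliest frame.
#'
#' @param x a [tac()] with at least one frame.
#' @return data.frame with `peak` (`"first"`), `SUV_max` (peak value, in the
#'   TAC's units) and `T_max` (minutes).
#' @export
peak_stats <- function(x) {
  if (!inherits(x, "tac") || length(x$value) < 1) stop("non-empty tac needed")
  i <- which.max(x$value)
  data.frame(peak = "first", SUV_max = x$value[i],
             T_max = tac_mid_min(x)[i])
}

# prominence of the local maximum at index i: height above the higher of
# the two key saddles (lowest value between the peak and the nearest
# equal-or-higher sample on that side, or the curve end)
peak_prominence <- function(v, i) {
  side_base <- function(step) {
    j <- i + step
    if (j < 1 || j > length(v)) return(-Inf)
    m <- Inf
    stopped_higher <- FALSE
    while (j >= 1 && j <= length(v)) {
      if (v[j] > v[i]) { stopped_higher <- TRUE; break }
      if (v[j] < v[i]) m <- min(m, v[j])  # equal values: plateau, walk on
      j <- j + step
    }
    if (is.infinite(m)) {
      # never descended on this side: plateau into higher ground (no
      # prominence) or plateau to the curve end (side unbounded)
      if (stopped_higher) v[i] else -Inf
    } else m
  }
  v[i] - max(side_base(-1L), side_base(1L))
}

#' Detect up to two prominent peaks in a TAC
#'
#' Finds local maxima (plateau-tolerant) with topographic prominence at
#' least `min_prominence`, ordered by time; at most the first two are
#' returned. On a monotone TAC at most one peak is reported. The default
#' prominence threshold is 5% of the TAC's dynamic range, which suppresses
#' frame-noise wiggles while keeping genuine vascular and excretion peaks.
#'
#' @param x a [tac()] with >= 3 frames.
#' @param min_prominence prominence threshold in the TAC's value units;
#'   `NULL` for the 5%-of-range default.
#' @return data.frame with columns `peak` (`"first"`, `"second"`),
#'   `SUV_max`, `T_max` (minutes); zero rows if no peak qualifies.
#' @export
detect_peaks <- function(x, min_prominence = NULL) {
  if (!inherits(x, "tac") || length(x$value) < 3) stop(">= 3 frames needed")
  v <- x$value
  if (is.null(min_prominence))
    min_prominence <- 0.05 * diff(range(v))
  n <- length(v)
  # local maxima: strictly above previous distinct value and >= next
  cand <- integer(0)
  for (i in seq_len(n)) {
    lo <- if (i > 1) v[i] > v[i - 1] else v[i] > v[min(i + 1, n)]
    hi <- if (i < n) v[i] >= v[i + 1] else v[i] > v[max(i - 1, 1)]
    if (lo && hi) cand <- c(cand, i)
  }
  cand <- cand[vapply(cand, function(i) peak_prominence(v, i),
                      numeric(1)) >= min_prominence]
  cand <- utils::head(cand, 2)
  if (!length(cand)) {
    return(data.frame(peak = character(0), SUV_max = numeric(0),
                      T_max = numeric(0)))
  }
  data.frame(peak = c("first", "second")[seq_along(cand)],
             SUV_max = v[cand], T_max = tac_mid_min(x)[cand])
}

#' Rate-pressure product
#'
#' Cardiac workload index computed from heart rate and systolic blood
#' pressure as `RPP = HR * SBP / 1e4`. The 1e4 scaling makes the scaled
#' uptake `K1s = K1 / RPP` come out in the conventional magnitude (typical
#' resting RPP ~ 0.75); see the methods vignette for why this scaling, and
#' not 1e3, is the dimensionally consistent reading.
#'
#' @param vitals a [subject_vitals()].
#' @return RPP (dimensionless, order 1).
#' @export
rate_pressure_product <- function(vitals) {
  if (!inherits(vitals, "subject_vitals"))
    stop("vitals must be subject_vitals")
  vitals$HR * vitals$SBP / 1e4
}

#' Workload-scaled uptake rate
#'
#' `K1s = K1 / RPP`, removing between-scan differences in cardiac workload
#' from the uptake rate.
#'
#' @param K1 uptake rate, mL/min/g.
#' @param RPP rate-pressure product (> 0), from [rate_pressure_product()].
#' @return Scaled uptake `K1s` (mL/min/g).
#' @export
scaled_k1 <- function(K1, RPP) {
  if (any(RPP <= 0)) stop("RPP must be > 0")
  K1 / RPP
}

#' Myocardial oxygen consumption from acetate clearance
#'
#' `MVO2 = (1.35 * k2 - 9.6e-3) * 100` mL/100g/min, floored at 0: the
#' established linear calibration of acetate washout against oxygen
#' consumption, reported per 100 g of tissue.
#'
#' @param k2 acetate clearance rate, per minute (>= 0).
#' @return MVO2 in mL/100g/min.
#' @export
mvo2_from_k2 <- function(k2) {
  if (any(k2 < 0)) stop("k2 must be >= 0")
  pmax((1.35 * k2 - 9.6e-3) * 100, 0)
}

#' Renkin-Crone forward map: uptake from flow
#'
#' `K1 = MBF * (1 - a * exp(-b / MBF))`: the generalized Renkin-Crone
#' relation between perfusion and the unidirectional extraction of acetate.
#' Constants `a` (dimensionless) and `b` (mL/min/g) are configuration
#' values; the defaults are the standard acetate parameterization.
#'
#' @param MBF myocardial blood flow, mL/min/g (> 0).
#' @param a in (0, 1).
#' @param b > 0, mL/min/g.
#' @return K1 in mL/min/g.
#' @export
renkin_crone_k1 <- function(MBF, a = 0.64, b = 1.20) {
  if (a <= 0 || a >= 1) stop("a must be in (0, 1)")
  if (b <= 0) stop("b must be > 0")
  if (any(MBF <= 0)) stop("MBF must be > 0")
  MBF * (1 - a * exp(-b / MBF))
}

#' Myocardial blood flow from acetate uptake (Renkin-Crone inversion)
#'
#' Solves `K1 = MBF * (1 - a * exp(-b/MBF))` for MBF by monotone bracketed
#' root finding (the forward map is strictly increasing in MBF), to a
#' tolerance of 1e-8.
#'
#' @param K1 acetate uptake rate, mL/min/g (> 0).
#' @param a,b Renkin-Crone constants, see [renkin_crone_k1()].
#' @return MBF in mL/min/g.
#' @export
mbf_from_k1_acetate <- function(K1, a = 0.64, b = 1.20) {
  if (a <= 0 || a >= 1) stop("a must be in (0, 1)")
  if (b <= 0) stop("b must be > 0")
  vapply(K1, function(k) {
    if (k <= 0)
      stop("K1 must exceed the attainable lower bound 0 mL/min/g")
    f <- function(F) renkin_crone_k1(F, a, b) - k
    upper <- max(1, k / (1 - a))
    while (f(upper) < 0) upper <- upper * 2
    stats::uniroot(f, c(1e-12, upper), tol = 1e-10)$root
  }, numeric(1))
}

#' Uptake-to-clearance kinetic ratio
#'
#' `K1 / k2` (mL/g), the apparent distribution volume of the reversible
#' compartment; similar values across organs suggest similar uptake and
#' clearance pathways.
#'
#' @param K1 mL/min/g.
#' @param k2 per minute (> 0).
#' @return K1/k2 in mL/g.
#' @export
kinetic_ratio <- function(K1, k2) {
  if (any(k2 <= 0)) stop("k2 must be > 0")
  K1 / k2
}

#' Fold change relative to a reference
#'
#' @param x value(s).
#' @param ref reference value(s) (> 0).
#' @return `x / ref`.
#' @export
fold_change <- function(x, ref) {
  if (any(ref <= 0)) stop("reference must be > 0")
  x / ref
}

#' Percent difference relative to a reference value
#'
#' Reports `|x - ref| / ref * 100`, i.e. the difference expressed relative
#' to the reference (by convention the larger, reference-tracer value),
#' together with the direction. With `x = 0.063`, `ref = 0.081` this yields
#' 22.2% ("x lower than reference").
#'
#' @param x value being compared.
#' @param ref reference value (> 0).
#' @return A list with `percent`, `direction` (`"lower"`, `"higher"`,
#'   `"equal"`), and `reference` (the convention record).
#' @export
percent_diff_vs_ref <- function(x, ref) {
  if (any(ref <= 0)) stop("reference must be > 0")
  list(percent = abs(x - ref) / ref * 100,
       direction = ifelse(x < ref, "lower", ifelse(x > ref, "higher",
                                                   "equal")),
       reference = "relative to reference value")
}

#' Early-window summed SUV of a pelvis TAC
#'
#' Sum of frame SUV values over an early window (default 0--2 min); a
#' simple summary of the initial vascular transit through the renal pelvis.
#' The definition of this summary is a package convention.
#'
#' @param x a [tac()] in SUV units.
#' @param window_min `c(start, end)` in minutes.
#' @return Summed SUV over frames fully inside the window.
#' @export
pelvis_early_sum <- function(x, window_min = c(0, 2)) {
  if (!inherits(x, "tac")) stop("x must be a tac")
  keep <- x$schedule$frame_start >= window_min[1] * 60 - 1e-9 &
    x$schedule$frame_end <= window_min[2] * 60 + 1e-9
  sum(x$value[keep])
}
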