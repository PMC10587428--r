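#' Default kinetic truth distributions
#'
#' Cohort mean (SD) kinetic parameters used as simulator defaults,
#' representative of healthy resting adults for the two carbon-11 tracers:
#' acetoacetate (`acac`) and acetate (`ac`). Myocardium and renal cortex are
#' simulated with the one-tissue model, except cortical acetoacetate which
#' carries a small irreversible accumulation rate `k3` and is simulated with
#' the irreversible two-tissue model. Draws are truncated at zero.
#'
#' @return A data.frame keyed by (`region`, `tracer`, `model`) with columns
#'   `<param>_mean` / `<param>_sd` for `K1`, `k2`, `k3`, `Vb`.
#' @export
default_kinetic_truth <- function() {
  tab <- rbind(
    data.frame(region = "myocardium",   tracer = "acac", model = "1tc",
               K1_mean = 0.61, K1_sd = 0.07, k2_mean = 0.063, k2_sd = 0.021,
               k3_mean = 0,     k3_sd = 0,    Vb_mean = 0.40,  Vb_sd = 0.05),
    data.frame(region = "myocardium",   tracer = "ac",   model = "1tc",
               K1_mean = 0.69, K1_sd = 0.10, k2_mean = 0.081, k2_sd = 0.022,
               k3_mean = 0,     k3_sd = 0,    Vb_mean = 0.40,  Vb_sd = 0.05),
    data.frame(region = "renal_cortex", tracer = "acac", model = "1tc",
               K1_mean = 0.83, K1_sd = 0.10, k2_mean = 0.31,  k2_sd = 0.04,
               k3_mean = 0,     k3_sd = 0,    Vb_mean = 0.10,  Vb_sd = 0),
    data.frame(region = "renal_cortex", tracer = "acac", model = "2tc_irr",
               K1_mean = 0.87, K1_sd = 0.10, k2_mean = 0.37,  k2_sd = 0.06,
               k3_mean = 0.021, k3_sd = 0.015, Vb_mean = 0.10, Vb_sd = 0),
    data.frame(region = "renal_cortex", tracer = "ac",   model = "1tc",
               K1_mean = 1.77, K1_sd = 0.43, k2_mean = 0.21,  k2_sd = 0.02,
               k3_mean = 0,     k3_sd = 0,    Vb_mean = 0.10,  Vb_sd = 0)
  )
  tab
}

#' Default pelvis second-peak distributions
#'
#' Delayed excretion-peak truth for the renal pelvis under the ketone
#' tracer: peak height in SUV units (converted per subject using injected
#' dose and weight), mode time in minutes, gamma-variate shape and onset.
#'
#' @return A list of means/SDs and truncation bounds.
#' @export
default_pelvis_truth <- function() {
  list(amp_suv_mean = 38.6, amp_suv_sd = 31.5, amp_suv_range = c(5, 150),
       mode_mean = 7.0, mode_sd = 2.0, mode_range = c(3, 15),
       onset_frac = 0.25, shape = 3, vascular_fraction = 0.25)
}

#' Default subject-vitals distributions
#'
#' Heart rate (beats/min), systolic blood pressure (mmHg), injected dose
#' (MBq) and body weight (kg) for a healthy young adult cohort; normal draws
#' truncated to physiological ranges.
#'
#' @return A list of means/SDs and truncation bounds per vital.
#' @export
default_vitals_distributions <- function() {
  list(HR = list(mean = 62, sd = 8, range = c(40, 120)),
       SBP = list(mean = 121, sd = 11, range = c(90, 180)),
       dose_MBq = list(mean = 319, sd = 53, range = c(150, 500)),
       weight_kg = list(mean = 70, sd = 10, range = c(45, 110)))
}

rtruncnorm1 <- function(mean, sd, range) {
  if (sd < 0) stop("distribution SD must be >= 0")
  if (sd == 0) return(min(max(mean, range[1]), range[2]))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  min(max(mean, range[1]), range[2])
}

draw_params <- function(row) {
  kinetic_params(
    K1 = rtruncnorm1(row$K1_mean, row$K1_sd, c(0, Inf)),
    k2 = rtruncnorm1(row$k2_mean, row$k2_sd, c(0, Inf)),
    k3 = rtruncnorm1(row$k3_mean, row$k3_sd, c(0, Inf)),
    Vb = rtruncnorm1(row$Vb_mean, row$Vb_sd, c(0, 1))
  )
}

#' Metabolite model conventionally used for a tracer
#'
#' Acetoacetate uses the linear CO2 accumulation model (default slope
#' 1.323 % of plasma activity per minute); acetate uses the interpolated
#' parent-fraction table.
#'
#' @param tracer `"acac"` or `"ac"`.
#' @return A [metabolite_model()].
#' @export
tracer_metabolite_model <- function(tracer = c("acac", "ac")) {
  tracer <- match.arg(tracer)
  if (tracer == "acac") metabolite_model("linear_co2", slope = 1.323)
  else metabolite_model("table_interpolated",
                        table = default_acetate_parent_table())
}

#' Generate a virtual dual-tracer cohort
#'
#' Simulates `n` subjects, each scanned with both tracers (or a subset):
#' subject vitals, a subject-specific arterial input function (bolus
#' amplitude scaled by injected dose per body weight), and noisy TACs for
#' the left-ventricle blood pool, myocardium, renal cortex and renal pelvis,
#' with the generating kinetic truth stored alongside. Renal-cortex
#' acetoacetate is simulated from the irreversible two-tissue truth; all
#' other tissue regions from the one-tissue truth. The delayed pelvis
#' excretion peak is present only for acetoacetate.
#'
#' @param n number of subjects (>= 1).
#' @param truth_distributions data.frame as [default_kinetic_truth()].
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param tracers subset of `c("acac", "ac")`.
#' @param noise a [noise_spec()] (its `seed` is ignored; the cohort stream
#'   is used).
#' @param fs a [frame_schedule()].
#' @param vitals_distributions list as [default_vitals_distributions()].
#' @param pelvis_truth list as [default_pelvis_truth()].
#' @param step_s simulation fine-grid step, seconds.
#' @return An object of class `pet_cohort`: list with `subjects` (each
#'   holding `vitals`, nested `tacs[[tracer]][[region]]`, `truth` records and
#'   the subject AIF), plus the schedule and seed.
#' @export
generate_cohort <- function(n, truth_distributions = default_kinetic_truth(),
                            seed = 1, tracers = c("acac", "ac"),
                            noise = noise_spec(0.05),
                            fs = default_frame_schedule(),
                            vitals_distributions =
                              default_vitals_distributions(),
                            pelvis_truth = default_pelvis_truth(),
                            step_s = 0.5) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  sd_cols <- grep("_sd$", names(truth_distributions), value = TRUE)
  if (any(truth_distributions[sd_cols] < 0))
    stop("truth distribution SDs must be >= 0")
  tracers <- match.arg(tracers, several.ok = TRUE)
  set.seed(seed)
  vd <- vitals_distributions
  subjects <- lapply(seq_len(n), function(i) {
    vit <- subject_vitals(
      HR = rtruncnorm1(vd$HR$mean, vd$HR$sd, vd$HR$range),
      SBP = rtruncnorm1(vd$SBP$mean, vd$SBP$sd, vd$SBP$range),
      dose_MBq = rtruncnorm1(vd$dose_MBq$mean, vd$dose_MBq$sd,
                             vd$dose_MBq$range),
      weight_kg = rtruncnorm1(vd$weight_kg$mean, vd$weight_kg$sd,
                              vd$weight_kg$range))
    aif <- feng_params(A1 = 2000 * (vit$dose_MBq / 319) *
                         (70 / vit$weight_kg))
    truth_rows <- list(); tacs <- list()
    for (tr in tracers) {
      cp <- metabolite_correct(aif, tracer_metabolite_model(tr))
      blood <- tac(fs, frame_average(
        eval_input_function(aif, fine_grid(fs, step_s)),
        fine_grid(fs, step_s), fs), region = "lv_blood", tracer = tr)
      tt <- list(lv_blood = add_noise(blood, noise_spec(noise$scale)))
      for (reg in c("myocardium", "renal_cortex")) {
        model <- if (reg == "renal_cortex" && tr == "acac") "2tc_irr"
                 else "1tc"
        row <- truth_distributions[
          truth_distributions$region == reg &
            truth_distributions$tracer == tr &
            truth_distributions$model == model, , drop = FALSE]
        if (nrow(row) != 1) stop("no truth distribution for ", reg, "/", tr)
        kp <- draw_params(row)
        tru <- organ_truth(reg, kp)
        tt[[reg]] <- add_noise(
          simulate_tissue_tac(tru, cp, fs, Cb = aif, step_s = step_s),
          noise_spec(noise$scale))
        truth_rows[[paste(tr, reg)]] <- data.frame(
          subject_id = sprintf("S%02d", i), tracer = tr, region = reg,
          model = model, K1 = kp$K1, k2 = kp$k2, k3 = kp$k3, Vb = kp$Vb)
      }
      pt <- pelvis_truth
      sp <- NULL
      if (tr == "acac") {
        amp_suv <- rtruncnorm1(pt$amp_suv_mean, pt$amp_suv_sd,
                               pt$amp_suv_range)
        mode_min <- rtruncnorm1(pt$mode_mean, pt$mode_sd, pt$mode_range)
        sp <- list(amplitude = amp_suv * vit$dose_MBq / vit$weight_kg,
                   mode_min = mode_min, onset_min = pt$onset_frac * mode_min,
                   shape = pt$shape)
      }
      ptru <- organ_truth("renal_pelvis", kinetic_params(0, 0),
                          second_peak = sp,
                          vascular_fraction = pt$vascular_fraction)
      tt$renal_pelvis <- add_noise(
        simulate_pelvis_tac(ptru, aif, fs, step_s = step_s),
        noise_spec(noise$scale))
      for (reg in names(tt)) {
        tt[[reg]]$tracer <- tr
        tt[[reg]]$subject_id <- sprintf("S%02d", i)
        tt[[reg]]$region <- reg
      }
      tacs[[tr]] <- tt
    }
    list(subject_id = sprintf("S%02d", i), vitals = vit, aif = aif,
         tacs = tacs, truth = do.call(rbind, truth_rows))
  })
  structure(list(subjects = subjects, schedule = fs, seed = seed,
                 noise = noise, tracers = tracers),
            class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort> %d subjects, tracers: %s, seed %d\n",
              length(x$subjects), paste(x$tracers, collapse = "/"), x$seed))
  invisible(x)
}

#' Cohort truth records as a data.frame
#'
#' @param cohort a `pet_cohort`.
#' @return data.frame with one row per subject/tracer/region truth record.
#' @export
cohort_truth_table <- function(cohort) {
  do.call(rbind, c(lapply(cohort$subjects, `[[`, "truth"),
                   make.row.names = FALSE))
}

#' Cohort vitals as a data.frame
#'
#' @param cohort a `pet_cohort`.
#' @return data.frame of subject vitals.
#' @export
cohort_vitals_table <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, HR = s$vitals$HR,
               SBP = s$vitals$SBP, dose_MBq = s$vitals$dose_MBq,
               weight_kg = s$vitals$weight_kg)))
}
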