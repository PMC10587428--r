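#' Read a TAC table from CSV
#'
#' The TAC CSV dialect has columns `subject_id`, `tracer` (`acac`|`ac`),
#' `region`, `frame_start_s`, `frame_end_s`, `value`, `value_units`
#' (`kBq/mL`|`SUV`), `decay_corrected` (logical). Frames must be ordered and
#' non-overlapping within each (subject, tracer, region) group, and units
#' consistent within a group. Malformed rows are reported with their data
#' row numbers.
#'
#' @param path CSV file path.
#' @return A validated data.frame of class `tac_table`.
#' @export
read_tac_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tac_table(tab)
}

#' @rdname read_tac_csv
#' @param tab a data.frame in the TAC CSV dialect.
#' @export
validate_tac_table <- function(tab) {
  req <- c("subject_id", "tracer", "region", "frame_start_s", "frame_end_s",
           "value", "value_units", "decay_corrected")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop(errorCondition(paste("missing column(s):",
                              paste(missing_cols, collapse = ", ")),
                        class = c("petkin_missing_column", "error")))
  bad <- which(tab$frame_end_s <= tab$frame_start_s)
  if (length(bad))
    stop(errorCondition(paste("frame_end_s <= frame_start_s at row(s):",
                              paste(bad, collapse = ", ")),
                        class = c("petkin_bad_frame", "error")))
  if (!all(tab$tracer %in% c("acac", "ac")))
    stop(errorCondition("tracer must be 'acac' or 'ac'",
                        class = c("petkin_bad_tracer", "error")))
  grp <- interaction(tab$subject_id, tab$tracer, tab$region, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    s <- tab$frame_start_s[idx]
    e <- tab$frame_end_s[idx]
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)] - 1e-9))
      stop(errorCondition(
        paste0("frames out of order or overlapping in group ", g,
               " (rows ", idx[1], "-", idx[length(idx)], ")"),
        class = c("petkin_bad_frame_order", "error")))
    if (length(unique(tab$value_units[idx])) != 1)
      stop(errorCondition(paste("mixed units within group", g),
                          class = c("petkin_mixed_units", "error")))
  }
  structure(tab, class = c("tac_table", "data.frame"))
}

#' Write a TAC table to CSV
#'
#' @param tab a `tac_table` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly. Write-then-read round-trips losslessly.
#' @export
write_tac_csv <- function(tab, path) {
  tab <- validate_tac_table(as.data.frame(tab))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten a simulated cohort into a TAC table
#'
#' @param cohort a `pet_cohort` from [generate_cohort()].
#' @return A `tac_table` data.frame.
#' @export
cohort_tac_table <- function(cohort) {
  rows <- list()
  for (s in cohort$subjects)
    for (tr in names(s$tacs))
      for (reg in names(s$tacs[[tr]]))
        rows[[paste(s$subject_id, tr, reg)]] <-
          as.data.frame(s$tacs[[tr]][[reg]])
  validate_tac_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Reassemble TAC objects from a TAC table
#'
#' @param tab a `tac_table`.
#' @return Nested list `x[[subject_id]][[tracer]][[region]]` of [tac()]s.
#' @export
tacs_from_table <- function(tab) {
  tab <- validate_tac_table(as.data.frame(tab))
  out <- list()
  grp <- unique(tab[c("subject_id", "tracer", "region")])
  for (i in seq_len(nrow(grp))) {
    g <- grp[i, ]
    sel <- tab[tab$subject_id == g$subject_id & tab$tracer == g$tracer &
                 tab$region == g$region, ]
    out[[g$subject_id]][[g$tracer]][[g$region]] <-
      tac(frame_schedule(sel$frame_start_s, sel$frame_end_s), sel$value,
          units = sel$value_units[1],
          decay_corrected = as.logical(sel$decay_corrected[1]),
          region = g$region, tracer = g$tracer, subject_id = g$subject_id)
  }
  out
}

#' Fit compartment models across a simulated cohort
#'
#' For each subject and tracer, builds the input function from the
#' left-ventricle blood-pool TAC (linear interpolation), applies the
#' tracer's metabolite correction to obtain the parent plasma curve, and
#' fits: myocardium with the one-tissue model (Vb estimated), renal cortex
#' with the one-tissue model (Vb fixed), and additionally the irreversible
#' two-tissue model for cortical acetoacetate.
#'
#' @param cohort a `pet_cohort`.
#' @param cfg_myocardium,cfg_cortex [fit_config()]s for the two organs.
#' @return A data.frame with one row per fit (subject, tracer, region,
#'   model, K1, k2, k3, Vb, rss, aic, converged).
#' @export
fit_cohort <- function(cohort,
                       cfg_myocardium = fit_config(fit_vb = TRUE),
                       cfg_cortex = fit_config(fit_vb = FALSE)) {
  rows <- list()
  for (s in cohort$subjects) {
    for (tr in names(s$tacs)) {
      tt <- s$tacs[[tr]]
      Cb <- as_input_function(tt$lv_blood)
      Cp <- metabolite_correct(Cb, tracer_metabolite_model(tr))
      jobs <- list(list(region = "myocardium", model = "1tc",
                        cfg = cfg_myocardium),
                   list(region = "renal_cortex", model = "1tc",
                        cfg = cfg_cortex))
      if (tr == "acac")
        jobs <- c(jobs, list(list(region = "renal_cortex",
                                  model = "2tc_irr", cfg = cfg_cortex)))
      for (j in jobs) {
        f <- fit_model(tt[[j$region]], Cp, Cb, model = j$model, cfg = j$cfg)
        rows[[paste(s$subject_id, tr, j$region, j$model)]] <- data.frame(
          subject_id = s$subject_id, tracer = tr, region = j$region,
          model = j$model, K1 = f$params$K1, k2 = f$params$k2,
          k3 = f$params$k3, Vb = f$params$Vb, rss = f$rss, aic = f$aic,
          converged = f$converged)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Derive per-subject physiological metrics
#'
#' Combines cohort TACs, fit results and vitals into the long metric table
#' consumed by [build_summary_table()]: SUV peaks per region, kinetic
#' parameters per model, workload-scaled uptake, MBF and MVO2 (acetate,
#' myocardium), renal-pelvis early sum and first/second excretion peaks.
#'
#' @param cohort a `pet_cohort`.
#' @param fits data.frame from [fit_cohort()].
#' @return Long data.frame: `subject_id`, `tracer`, `region`, `metric`,
#'   `value`.
#' @export
derive_metrics <- function(cohort, fits) {
  rows <- list()
  add <- function(sid, tr, reg, metric, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = sid, tracer = tr, region = reg, metric = metric,
      value = value)
  }
  for (s in cohort$subjects) {
    vit <- s$vitals
    rpp <- rate_pressure_product(vit)
    for (tr in names(s$tacs)) {
      tt <- s$tacs[[tr]]
      for (reg in c("myocardium", "renal_cortex")) {
        suv <- suv_curve(tt[[reg]], vit)
        pk <- peak_stats(suv)
        add(s$subject_id, tr, reg, "SUV_max", pk$SUV_max)
        add(s$subject_id, tr, reg, "T_max", pk$T_max)
        frow <- fits[fits$subject_id == s$subject_id & fits$tracer == tr &
                       fits$region == reg & fits$model == "1tc", ]
        add(s$subject_id, tr, reg, "K1_1tc", frow$K1)
        add(s$subject_id, tr, reg, "k2_1tc", frow$k2)
        add(s$subject_id, tr, reg, "K1_over_k2",
            kinetic_ratio(frow$K1, frow$k2))
        if (reg == "myocardium") {
          add(s$subject_id, tr, reg, "K1s_1tc", scaled_k1(frow$K1, rpp))
          if (tr == "ac") {
            add(s$subject_id, tr, reg, "MBF", mbf_from_k1_acetate(frow$K1))
            add(s$subject_id, tr, reg, "MVO2", mvo2_from_k2(frow$k2))
          }
        }
        if (reg == "renal_cortex" && tr == "acac") {
          f2 <- fits[fits$subject_id == s$subject_id & fits$tracer == tr &
                       fits$region == reg & fits$model == "2tc_irr", ]
          if (nrow(f2)) {
            add(s$subject_id, tr, reg, "K1_2tc", f2$K1)
            add(s$subject_id, tr, reg, "k2_2tc", f2$k2)
            add(s$subject_id, tr, reg, "k3_2tc", f2$k3)
          }
        }
      }
      suvp <- suv_curve(tt$renal_pelvis, vit)
      add(s$subject_id, tr, "renal_pelvis", "sum_early",
          pelvis_early_sum(suvp))
      pks <- detect_peaks(suvp)
      if (nrow(pks) >= 1) {
        add(s$subject_id, tr, "renal_pelvis", "T_max", pks$T_max[1])
        add(s$subject_id, tr, "renal_pelvis", "SUV_max", pks$SUV_max[1])
      }
      if (nrow(pks) >= 2) {
        add(s$subject_id, tr, "renal_pelvis", "SUV_max_2nd", pks$SUV_max[2])
        add(s$subject_id, tr, "renal_pelvis", "T_max_2nd", pks$T_max[2])
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the simulate -> fit -> derive -> summarize pipeline
#'
#' Executes the requested stages in order on a fully synthetic cohort and
#' writes all artifacts plus a JSON manifest (configuration, seed, package
#' version, MD5 hash of every output file) to `out_dir`. Re-running with an
#' identical configuration reproduces identical outputs and hashes; all
#' randomness flows from `seed`.
#'
#' @param n number of subjects.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param tracers subset of `c("acac", "ac")`.
#' @param noise_scale noise scale for [noise_spec()].
#' @param stages character vector, ordered subset of
#'   `c("simulate", "fit", "derive", "cohort")`; later stages require the
#'   earlier ones.
#' @param cfg_myocardium,cfg_cortex [fit_config()]s passed to
#'   [fit_cohort()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(n = 10, seed = 1, out_dir = tempdir(),
                         tracers = c("acac", "ac"), noise_scale = 0.05,
                         stages = c("simulate", "fit", "derive", "cohort"),
                         cfg_myocardium = fit_config(fit_vb = TRUE),
                         cfg_cortex = fit_config(fit_vb = FALSE)) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- c("simulate", "fit", "derive", "cohort")
  if (!identical(stages, need[seq_along(stages)]))
    stop("stages must be an ordered prefix of simulate/fit/derive/cohort")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files[[name]] <<- p
    p
  }
  cohort <- generate_cohort(n, seed = seed, tracers = tracers,
                            noise = noise_spec(noise_scale))
  put(cohort_tac_table(cohort), "tacs.csv")
  put(cohort_truth_table(cohort), "truth.csv")
  put(cohort_vitals_table(cohort), "vitals.csv")
  fits <- metrics <- NULL
  if ("fit" %in% stages) {
    fits <- fit_cohort(cohort, cfg_myocardium, cfg_cortex)
    put(fits, "fits.csv")
  }
  if ("derive" %in% stages) {
    metrics <- derive_metrics(cohort, fits)
    put(metrics, "metrics.csv")
  }
  if ("cohort" %in% stages) {
    put(as.data.frame(build_summary_table(metrics)), "summary.csv")
  }
  manifest <- list(
    package = "petkin",
    version = as.character(utils::packageVersion("petkin")),
    seed = seed, n = n, tracers = tracers, noise_scale = noise_scale,
    stages = stages,
    outputs = lapply(files, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
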