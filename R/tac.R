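#' Time-activity curve container
#'
#' A TAC holds one region's activity concentration per frame, together with
#' its frame schedule, units, and decay-correction state. All simulated TACs
#' are produced decay-corrected to injection time (the conventional PET
#' output); [decay_correct()] flips the state tag.
#'
#' @param schedule a [frame_schedule()].
#' @param value numeric vector of activity concentrations, one per frame.
#' @param units `"kBq/mL"` or `"SUV"`.
#' @param decay_corrected logical; is physical decay removed from `value`?
#' @param region,tracer,subject_id optional metadata labels.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, value, units = "kBq/mL", decay_corrected = TRUE,
                region = NA_character_, tracer = NA_character_,
                subject_id = NA_character_) {
  if (!inherits(schedule, "frame_schedule"))
    stop("schedule must be a frame_schedule")
  value <- as.numeric(value)
  if (length(value) != nrow(schedule))
    stop("value length (", length(value), ") must equal number of frames (",
         nrow(schedule), ")")
  if (!units %in% c("kBq/mL", "SUV")) stop("units must be 'kBq/mL' or 'SUV'")
  structure(
    list(schedule = schedule, value = value, units = units,
         decay_corrected = isTRUE(decay_corrected),
         region = region, tracer = tracer, subject_id = subject_id),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, %s%s, region=%s, tracer=%s\n",
              nrow(x$schedule), x$units,
              if (x$decay_corrected) " (decay-corrected)" else "",
              x$region, x$tracer))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(
    subject_id = x$subject_id, tracer = x$tracer, region = x$region,
    frame_start_s = x$schedule$frame_start,
    frame_end_s = x$schedule$frame_end,
    value = x$value, value_units = x$units,
    decay_corrected = x$decay_corrected,
    stringsAsFactors = FALSE
  )
}

tac_mid_min <- function(x) frame_mid(x$schedule, "min")
tac_dur_min <- function(x) frame_duration(x$schedule, "min")
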