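#' Radioactive decay specification
#'
#' @param halflife physical half-life in minutes; default 20.364 (carbon-11).
#' @param reference_time time (minutes) activities are referenced to;
#'   default 0 (injection).
#' @return An object of class `decay_spec`.
#' @export
decay_spec <- function(halflife = 20.364, reference_time = 0) {
  if (halflife <= 0) stop("halflife must be > 0")
  structure(list(halflife = halflife, reference_time = reference_time),
            class = "decay_spec")
}

#' Apply or remove physical decay correction
#'
#' Decay correction multiplies each frame value by `exp(lambda * t_mid)`
#' with `lambda = log(2) / halflife`, referencing activities to injection
#' time; removal divides. The TAC's `decay_corrected` tag tracks the state,
#' and re-applying a correction in the same direction is an error rather
#' than a silent double scaling.
#'
#' @param x a [tac()].
#' @param spec a [decay_spec()].
#' @param direction `"apply"` (raw -> corrected) or `"remove"`.
#' @return The corrected [tac()] with the state tag flipped.
#' @export
decay_correct <- function(x, spec = decay_spec(),
                          direction = c("apply", "remove")) {
  direction <- match.arg(direction)
  if (!inherits(x, "tac")) stop("x must be a tac")
  if (direction == "apply" && x$decay_corrected)
    stop("TAC is already decay-corrected; refusing to apply twice")
  if (direction == "remove" && !x$decay_corrected)
    stop("TAC is not decay-corrected; nothing to remove")
  lambda <- log(2) / spec$halflife
  f <- exp(lambda * (tac_mid_min(x) - spec$reference_time))
  x$value <- if (direction == "apply") x$value * f else x$value / f
  x$decay_corrected <- !x$decay_corrected
  x
}

#' Plasma metabolite model
#'
#' Describes the fraction of total plasma activity that is still parent
#' tracer as a function of time. Three forms:
#' \describe{
#'   \item{`linear_co2`}{labelled CO2 grows linearly with time, in percent of
#'     total plasma activity per minute: parent fraction
#'     `1 - min(slope * t / 100, 1)`. Default slope 1.323 %/min, the
#'     measured plasma 11C-CO2 accumulation rate for acetoacetate.}
#'   \item{`table_interpolated`}{parent fraction linearly interpolated from a
#'     `(time_min, parent_fraction)` table, as used for acetate where the
#'     correction comes from published curves.}
#'   \item{`none`}{parent fraction identically 1.}
#' }
#'
#' @param model one of `"linear_co2"`, `"table_interpolated"`, `"none"`.
#' @param slope percent of plasma activity per minute (`linear_co2` only).
#' @param table data.frame with columns `time_min`, `parent_fraction`
#'   (`table_interpolated` only); fractions in \[0,1\], fraction 1 at t = 0.
#' @return An object of class `metabolite_model`.
#' @export
metabolite_model <- function(model = c("linear_co2", "table_interpolated",
                                       "none"),
                             slope = 1.323, table = NULL) {
  model <- match.arg(model)
  if (model == "linear_co2") {
    if (slope < 0) stop("slope must be >= 0")
  }
  if (model == "table_interpolated") {
    if (is.null(table) || !all(c("time_min", "parent_fraction") %in%
                               names(table)))
      stop("table with columns time_min, parent_fraction required")
    if (any(table$parent_fraction < 0 | table$parent_fraction > 1))
      stop("parent_fraction must be in [0, 1]")
    if (is.unsorted(table$time_min, strictly = TRUE))
      stop("table time_min must be strictly increasing")
    f0 <- stats::approx(table$time_min, table$parent_fraction, xout = 0,
                        rule = 2)$y
    if (abs(f0 - 1) > 1e-6) stop("parent_fraction must be 1 at t = 0")
  }
  structure(list(model = model, slope = slope, table = table),
            class = "metabolite_model")
}

#' Default acetate parent-fraction table
#'
#' A smooth mono-exponential-plateau parent-fraction curve typical of
#' published arterial acetate metabolite data in humans, provided as a
#' user-replaceable default for the `table_interpolated` model; any
#' laboratory-specific curve can be supplied instead via
#' [metabolite_model()].
#'
#' @return A data.frame with columns `time_min`, `parent_fraction`.
#' @export
default_acetate_parent_table <- function() {
  t <- c(0, 1, 2, 3, 5, 7.5, 10, 15, 20, 30)
  data.frame(time_min = t,
             parent_fraction = round(0.25 + 0.75 * exp(-t / 6), 4))
}

#' Parent fraction at given times
#'
#' @param m a [metabolite_model()].
#' @param t times in minutes.
#' @return Numeric vector of parent fractions in \[0, 1\].
#' @export
parent_fraction <- function(m, t) {
  if (!inherits(m, "metabolite_model")) stop("m must be a metabolite_model")
  switch(m$model,
    none = rep(1, length(t)),
    linear_co2 = pmax(1 - pmin(m$slope * t / 100, 1), 0),
    table_interpolated = stats::approx(m$table$time_min,
                                       m$table$parent_fraction,
                                       xout = t, rule = 2)$y
  )
}

#' Metabolite-correct an input function
#'
#' Attaches a metabolite model to a total-plasma input function so that
#' [eval_input_function()] returns the parent-only concentration
#' `Cp_parent(t) = Cp_total(t) * parent_fraction(t)`, clamped at 0.
#'
#' @param Cp_total an `input_function` for total plasma activity.
#' @param m a [metabolite_model()].
#' @return An `input_function` evaluating to the parent concentration.
#' @export
metabolite_correct <- function(Cp_total, m) {
  if (!inherits(Cp_total, "input_function"))
    stop("Cp_total must be an input_function")
  if (!inherits(m, "metabolite_model")) stop("m must be a metabolite_model")
  Cp_total$parent_model <- m
  Cp_total
}

#' Read a metabolite parent-fraction table from CSV
#'
#' Two-column CSV `time_min, parent_fraction`.
#'
#' @param path file path.
#' @return A [metabolite_model()] of type `table_interpolated`.
#' @export
read_metabolite_table <- function(path) {
  tab <- utils::read.csv(path)
  metabolite_model("table_interpolated", table = tab)
}
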