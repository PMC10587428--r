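#' Paired two-condition comparison
#'
#' Two-sided paired test on the per-subject differences, by Student's
#' paired t-test or the Wilcoxon signed-rank test. A zero-variance
#' difference vector is flagged degenerate instead of erroring through the
#' underlying test: identical samples return statistic 0 and p = 1; a
#' constant non-zero shift returns p = 0 (the difference is certain under
#' the paired design).
#'
#' @param a,b numeric vectors of equal length (>= 3), same subject order.
#' @param method `"t"` or `"wilcoxon"`.
#' @return A list with `method`, `statistic`, `p_value`, `mean_diff`
#'   (`mean(a - b)`), `n`, `degenerate`.
#' @export
paired_compare <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need n >= 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(method = method,
                statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), n = length(a), degenerate = TRUE))
  }
  ht <- if (method == "t") stats::t.test(a, b, paired = TRUE)
        else stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value, mean_diff = mean(d), n = length(a),
       degenerate = FALSE)
}

#' Pearson correlation of a paired sample
#'
#' @param a,b numeric vectors of equal length (>= 3) with non-zero variance.
#' @return A list with `r`, `r2`, `p_value`, `n`.
#' @export
correlate <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need n >= 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(a, b, method = "pearson")
  r <- unname(ht$estimate)
  list(r = r, r2 = r^2, p_value = ht$p.value, n = length(a))
}

#' Repeated-measures one-way ANOVA with Tukey comparisons
#'
#' Within-subject one-way ANOVA for a complete subject x condition design
#' (fitted as the randomized-block model `value ~ condition + subject`),
#' followed by Tukey HSD pairwise comparisons of the condition means.
#'
#' @param data data.frame with columns `subject`, `condition`, `value`;
#'   every subject must appear exactly once in each of >= 3 conditions.
#' @return A list with `F`, `df`, `p_value` for the condition effect, and
#'   `tukey`: a data.frame of pairwise differences with adjusted p-values.
#' @export
rm_anova_tukey <- function(data) {
  req <- c("subject", "condition", "value")
  if (!all(req %in% names(data))) stop("columns subject, condition, value")
  data$subject <- factor(data$subject)
  data$condition <- factor(data$condition)
  tab <- table(data$subject, data$condition)
  if (nlevels(data$condition) < 3) stop("need >= 3 conditions")
  if (any(tab != 1)) stop("incomplete design: each subject must appear once
 per condition")
  fit <- stats::aov(value ~ condition + subject, data = data)
  an <- summary(fit)[[1]]
  i <- which(trimws(rownames(an)) == "condition")
  tk <- stats::TukeyHSD(fit, which = "condition")$condition
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  f_val <- an[i, "F value"]
  p_val <- an[i, "Pr(>F)"]
  # degenerate design (condition sum of squares ~ 0 at machine precision):
  # no condition effect at all, report F = 0 rather than a 0/0 artifact
  if (an[i, "Sum Sq"] <= 1e-12 * sum(an[, "Sum Sq"])) {
    f_val <- 0; p_val <- 1
    tukey$p_adj <- 1
  }
  list(F = f_val, df = c(an[i, "Df"], an[nrow(an), "Df"]),
       p_value = p_val, tukey = tukey)
}

#' Fold-change summary under both conventions
#'
#' Cohort fold differences can be summarized as the mean (SD) of
#' per-subject ratios, or as the ratio of cohort means; the two differ for
#' skewed ratios, so both are always reported and labelled.
#'
#' @param x numeric vector (numerator metric, one value per subject).
#' @param ref numeric vector (reference metric, same subjects, > 0).
#' @return A list with `mean_of_ratios`, `sd_of_ratios`,
#'   `ratio_of_means`, `n`.
#' @export
fold_summary <- function(x, ref) {
  if (length(x) != length(ref)) stop("x and ref must have equal length")
  if (any(ref <= 0)) stop("reference values must be > 0")
  r <- x / ref
  list(mean_of_ratios = mean(r),
       sd_of_ratios = if (length(r) > 1) stats::sd(r) else NA_real_,
       ratio_of_means = mean(x) / mean(ref), n = length(x))
}

#' Significance marker at the conventional tiers
#'
#' @param p p-value.
#' @return `"***"` (p <= 0.001), `"**"` (<= 0.01), `"*"` (<= 0.05), or "".
#' @export
significance_marker <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp <= 0.001) "***"
    else if (pp <= 0.01) "**" else if (pp <= 0.05) "*" else ""
  }, character(1))
}

#' Cohort summary table of kinetic metrics
#'
#' Aggregates per-subject metric values into a publication-style table:
#' one row per (organ, metric, tracer) with mean, SD, n, and - where both
#' tracer arms exist for a metric - a paired test against the reference
#' tracer with the conventional significance marker.
#'
#' @param metrics long data.frame with columns `subject_id`, `tracer`,
#'   `region`, `metric`, `value`.
#' @param reference_tracer tracer the markers compare against
#'   (default `"ac"`).
#' @param method `"t"` or `"wilcoxon"`, used for all paired tests.
#' @return A data.frame of class `summary_table` with columns `region`,
#'   `metric`, `tracer`, `mean`, `sd`, `n`, `p_vs_ref`, `marker`.
#' @export
build_summary_table <- function(metrics, reference_tracer = "ac",
                                method = "t") {
  req <- c("subject_id", "tracer", "region", "metric", "value")
  if (!all(req %in% names(metrics)))
    stop("metrics must have columns ", paste(req, collapse = ", "))
  if (!reference_tracer %in% metrics$tracer)
    stop("reference tracer '", reference_tracer, "' missing from metrics")
  key <- unique(metrics[c("region", "metric", "tracer")])
  key <- key[order(key$region, key$metric, key$tracer), ]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    sel <- metrics[metrics$region == k$region & metrics$metric == k$metric &
                     metrics$tracer == k$tracer, ]
    out <- data.frame(region = k$region, metric = k$metric,
                      tracer = k$tracer, mean = mean(sel$value),
                      sd = if (nrow(sel) > 1) stats::sd(sel$value)
                           else NA_real_,
                      n = nrow(sel), p_vs_ref = NA_real_, marker = "")
    if (k$tracer != reference_tracer) {
      refsel <- metrics[metrics$region == k$region &
                          metrics$metric == k$metric &
                          metrics$tracer == reference_tracer, ]
      common <- intersect(sel$subject_id, refsel$subject_id)
      if (length(common) >= 3) {
        aa <- sel$value[match(common, sel$subject_id)]
        bb <- refsel$value[match(common, refsel$subject_id)]
        pc <- paired_compare(aa, bb, method = method)
        out$p_vs_ref <- pc$p_value
        out$marker <- significance_marker(pc$p_value)
      }
    }
    out
  })
  structure(do.call(rbind, rows), class = c("summary_table", "data.frame"))
}
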