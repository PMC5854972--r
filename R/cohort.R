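## Beat-to-subject aggregation and the two-group contrast machinery:
## per-metric mean +/- SD by group and a two-sample t-test (Welch by
## default), chi-square with continuity correction for 2x2 categorical
## covariates. Raw p-values at alpha = 0.05; no multiple-testing
## correction is applied, and that choice is recorded in the summary.

#' Aggregate per-beat metrics to one row per subject
#'
#' @param beatRows data.frame of per-beat metric rows (as returned by
#'   [analyzeWindows()]), possibly covering several subjects.
#' @param labels optional named character vector mapping subject_id to
#'   group label.
#' @param method beat-to-subject aggregation: `"mean"` (default) or
#'   `"median"`.
#' @return data.frame with one row per subject: `subject_id`,
#'   `group_label`, `n_beats`, and the aggregated metrics.
#' @export
aggregateSubjects <- function(beatRows, labels = NULL,
                              method = c("mean", "median")) {
  method <- match.arg(method)
  if (!nrow(beatRows)) stop("no beat rows to aggregate")
  fun <- if (method == "mean") mean else stats::median
  metrics <- intersect(.METRIC_NAMES, names(beatRows))
  split_ <- split(beatRows, beatRows$subject_id)
  out <- do.call(rbind, lapply(split_, function(d) {
    agg <- vapply(metrics, function(m) fun(d[[m]]), numeric(1))
    cbind(data.frame(subject_id = d$subject_id[1],
                     group_label = if (!is.null(labels))
                       unname(labels[d$subject_id[1]]) else NA_character_,
                     n_beats = nrow(d)),
          as.data.frame(as.list(agg)))
  }))
  rownames(out) <- NULL
  out
}

#' Two-group comparison of subject-level metrics
#'
#' Per metric: group means, SDs and sizes plus a two-sample t-test
#' (Welch's unequal-variance variant by default; the group SDs of the
#' high-frequency metrics typically differ by an order of magnitude,
#' which makes pooled variance indefensible). Optional categorical
#' covariates are contrasted with a chi-square test (continuity-corrected
#' for 2x2 tables). Degenerate contrasts (a group with fewer than 2
#' subjects, or zero variance in both groups) yield no p-value and are
#' flagged.
#'
#' @param subjects data.frame from [aggregateSubjects()] with filled
#'   `group_label`.
#' @param alpha significance threshold recorded with the summary
#'   (default 0.05).
#' @param varEqual use the pooled-variance t-test instead of Welch.
#' @param categorical optional named list of logical/factor vectors
#'   (parallel to `subjects`) to contrast by chi-square.
#' @return a [CohortSummary-class].
#' @examples
#' s <- data.frame(subject_id = letters[1:10],
#'                 group_label = rep(c("control", "patient"), each = 5),
#'                 n_beats = 1,
#'                 total_power = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6))
#' compareGroups(s)@metricsTable$t  # Welch t = -1
#' @export
compareGroups <- function(subjects, alpha = 0.05, varEqual = FALSE,
                          categorical = NULL) {
  stopifnot(all(c("subject_id", "group_label") %in% names(subjects)))
  g <- subjects$group_label
  if (!all(g %in% c("control", "patient")))
    stop("group_label must be 'control' or 'patient' for every subject")
  if (!any(g == "control") || !any(g == "patient"))
    stop("both groups must be non-empty")
  metrics <- intersect(.METRIC_NAMES, names(subjects))
  if (!length(metrics)) metrics <- setdiff(names(subjects),
                                           c("subject_id", "group_label",
                                             "n_beats"))
  rows <- lapply(metrics, function(m) {
    x <- subjects[[m]][g == "control"]
    y <- subjects[[m]][g == "patient"]
    row <- data.frame(metric = m,
                      control_mean = mean(x), control_sd = stats::sd(x),
                      control_n = length(x),
                      patient_mean = mean(y), patient_sd = stats::sd(y),
                      patient_n = length(y),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      flag = "")
    if (length(x) < 2L || length(y) < 2L) {
      row$flag <- "group with < 2 subjects"
      return(row)
    }
    tt <- tryCatch(stats::t.test(x, y, var.equal = varEqual),
                   error = function(e) NULL)
    if (is.null(tt)) {
      row$flag <- "degenerate (zero variance)"
      return(row)
    }
    row$t <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p <- tt$p.value
    row
  })
  metricsTable <- do.call(rbind, rows)

  catTable <- data.frame(variable = character(), chisq = numeric(),
                         df = numeric(), p = numeric())
  for (nm in names(categorical)) {
    tab <- table(g, categorical[[nm]])
    ct <- suppressWarnings(stats::chisq.test(tab))
    catTable <- rbind(catTable,
                      data.frame(variable = nm,
                                 chisq = unname(ct$statistic),
                                 df = unname(ct$parameter),
                                 p = ct$p.value))
  }
  new("CohortSummary", metricsTable = metricsTable,
      categoricalTable = catTable, alpha = alpha, varEqual = varEqual)
}

#' Render a cohort summary in display units
#'
#' Power and intensity metrics are divided by 10^3 (reported as
#' 10^3 nV^2 Hz^-1 and 10^3 nV^2 Hz^-1 s^-1); times (ms) and the
#' dimensionless ratio are untouched.
#'
#' @param summary a [CohortSummary-class].
#' @param displayUnits divide power/intensity rows by 10^3 (default TRUE).
#' @return data.frame shaped like the published summary tables: metric,
#'   per-group mean and SD, p-value.
#' @export
formatCohortTable <- function(summary, displayUnits = TRUE) {
  tab <- summary@metricsTable
  scaleRows <- !grepl("time_to_peak|ratio", tab$metric)
  div <- ifelse(displayUnits & scaleRows, 1e3, 1)
  data.frame(metric = tab$metric,
             control = sprintf("%.4g (+/- %.4g)", tab$control_mean / div,
                               tab$control_sd / div),
             patient = sprintf("%.4g (+/- %.4g)", tab$patient_mean / div,
                               tab$patient_sd / div),
             p = signif(tab$p, 3))
}
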