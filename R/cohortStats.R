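# Longitudinal cohort statistics: scheme x week two-way ANOVA with Tukey
# post-hoc on lesion volumes, one-way ANOVA with Tukey on histology grades,
# and mean +/- SD summaries.

.asMeasurementFrame <- function(records, modality = NULL) {
  need <- c("subject_id", "scheme_label", "week", "modality", "volume_mm3")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("measurement records lack columns: ", paste(missing, collapse = ", "))
  d <- as.data.frame(records)
  if (!is.null(modality)) d <- d[d$modality == modality, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records", if (!is.null(modality))
    paste0(" of modality '", modality, "'") else "")
  if (length(unique(d$modality)) > 1L)
    stop("records span several modalities; select one with `modality`")
  key <- paste(d$subject_id, d$week, d$modality, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, week, modality) records: ",
         paste(unique(d$subject_id[duplicated(key)]), collapse = ", "))
  d
}

.anovaFrame <- function(tab) {
  # car::Anova type-III table -> tidy data.frame, intercept dropped
  out <- data.frame(term = rownames(tab), df = tab$Df, sumsq = tab$`Sum Sq`,
                    F = tab$`F value`, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  out[out$term != "(Intercept)", , drop = FALSE]
}

#' Two-way ANOVA (scheme x week) with Tukey post-hoc on lesion volumes
#'
#' Fixed-effects two-way ANOVA of lesion volume on radiation scheme and
#' imaging week (both treated as categorical factors), with Type III sums of
#' squares under sum-to-zero contrasts, followed by Tukey--Kramer adjusted
#' pairwise scheme comparisons at each week. If the scheme x week design has
#' empty cells -- as happens when an arm is censored early -- the
#' interaction is inestimable and is dropped with a warning recorded in the
#' report's `note`.
#'
#' @param records measurement records: a data.frame with columns
#'   `subject_id`, `scheme_label`, `week`, `modality`, `volume_mm3` (the
#'   output of [volumetryBatch()]).
#' @param modality restrict to one modality; required if `records` spans
#'   several.
#' @param doTukey compute the pairwise table (set `FALSE` to get only the
#'   ANOVA, e.g. in simulations).
#' @return an [AnovaTukeyReport-class] with factors
#'   `c("scheme", "week", "scheme:week")` (interaction present only if
#'   estimable). Pairwise rows compare schemes within each week.
#' @seealso [oneWayAnovaTukey()], [summarizeLongitudinal()]
#' @export
twoWayAnovaTukey <- function(records, modality = NULL, doTukey = TRUE) {
  d <- .asMeasurementFrame(records, modality)
  d$scheme <- factor(d$scheme_label)
  d$week <- factor(d$week)
  if (nlevels(d$scheme) < 2L) stop("need at least 2 schemes")
  if (nlevels(d$week) < 2L) stop("need at least 2 weeks")
  if (stats::var(d$volume_mm3) == 0)
    stop("degenerate data: zero total variance in lesion volume")
  cells <- table(d$scheme, d$week)
  note <- ""
  if (any(cells == 0L)) {
    note <- "interaction dropped: design has empty scheme x week cells"
    warning(note, call. = FALSE)
    form <- volume_mm3 ~ scheme + week
  } else {
    form <- volume_mm3 ~ scheme * week
  }
  fit <- stats::lm(form, data = d,
                   contrasts = list(scheme = "contr.sum", week = "contr.sum"))
  tab <- as.data.frame(car::Anova(fit, type = 3))
  av <- .anovaFrame(tab)
  av$term <- sub("^scheme:week$", "scheme:week", av$term)
  pw <- data.frame()
  if (doTukey) {
    em <- emmeans::emmeans(fit, ~ scheme | week)
    adj <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey")))
    una <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise", adjust = "none")))
    gg <- strsplit(as.character(adj$contrast), " - ", fixed = TRUE)
    pw <- data.frame(groupA = vapply(gg, `[`, character(1), 1L),
                     groupB = vapply(gg, `[`, character(1), 2L),
                     week = as.character(adj$week),
                     meanDiff = adj$estimate,
                     adjustedP = adj$p.value,
                     unadjustedP = una$p.value,
                     stringsAsFactors = FALSE)
  }
  new("AnovaTukeyReport",
      factors = setdiff(av$term, "Residuals"),
      anova = av, pairwise = pw, note = note)
}

#' One-way ANOVA with Tukey post-hoc on histology grades
#'
#' Ordinary one-way ANOVA of (numeric) histology grade on treatment group,
#' with Tukey--Kramer adjusted all-pairs comparisons. Grades are ordinal but
#' treated as numeric, as in an "ordinary" ANOVA.
#'
#' @param records a data.frame with columns `subject_id`, `scheme_label`,
#'   `grade` (non-negative integers on the grading scale).
#' @return an [AnovaTukeyReport-class] with a single factor `scheme`.
#' @export
oneWayAnovaTukey <- function(records) {
  need <- c("subject_id", "scheme_label", "grade")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("histology records lack columns: ", paste(missing, collapse = ", "))
  d <- as.data.frame(records)
  d$scheme <- factor(d$scheme_label)
  if (nlevels(d$scheme) < 2L) stop("need at least 2 groups")
  sizes <- table(d$scheme)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stop("groups with fewer than 2 records: ", paste(small, collapse = ", "))
  if (stats::var(d$grade) == 0)
    stop("degenerate data: zero total variance in grade")
  fit <- stats::aov(grade ~ scheme, data = d)
  s <- summary(fit)[[1]]
  av <- data.frame(term = trimws(rownames(s)), df = s$Df, sumsq = s$`Sum Sq`,
                   F = s$`F value`, p = s$`Pr(>F)`, stringsAsFactors = FALSE)
  em <- emmeans::emmeans(fit, ~ scheme)
  adj <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey")))
  una <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise", adjust = "none")))
  gg <- strsplit(as.character(adj$contrast), " - ", fixed = TRUE)
  pw <- data.frame(groupA = vapply(gg, `[`, character(1), 1L),
                   groupB = vapply(gg, `[`, character(1), 2L),
                   meanDiff = adj$estimate,
                   adjustedP = adj$p.value,
                   unadjustedP = una$p.value,
                   stringsAsFactors = FALSE)
  new("AnovaTukeyReport", factors = "scheme", anova = av, pairwise = pw,
      note = "")
}

#' Mean +/- SD summary per (scheme, week, modality) cell
#'
#' Group means, (n-1) standard deviations and counts of lesion volume.
#' Cells with a single observation report `NA` for the SD.
#'
#' @param records measurement records as for [twoWayAnovaTukey()].
#' @return a data.frame with columns `scheme_label`, `week`, `modality`,
#'   `n`, `mean_mm3`, `sd_mm3`, sorted by scheme then week.
#' @export
summarizeLongitudinal <- function(records) {
  need <- c("scheme_label", "week", "modality", "volume_mm3")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("measurement records lack columns: ", paste(missing, collapse = ", "))
  d <- as.data.frame(records)
  if (nrow(d) == 0L) stop("no records to summarise")
  key <- interaction(d$scheme_label, d$week, d$modality, drop = TRUE)
  agg <- lapply(split(d, key), function(g) {
    data.frame(scheme_label = g$scheme_label[1], week = g$week[1],
               modality = g$modality[1], n = nrow(g),
               mean_mm3 = mean(g$volume_mm3),
               sd_mm3 = if (nrow(g) > 1L) stats::sd(g$volume_mm3) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$scheme_label, out$week, out$modality), , drop = FALSE]
  rownames(out) <- NULL
  out
}
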