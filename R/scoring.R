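#' Score one diary day against a compendium
#'
#' Computes the per-day metrics for a complete 96-slot day. With `met_i` the
#' MET of slot `i`:
#' \itemize{
#'   \item `mean_met = sum(met_i) / 96` — the 24-hour mean MET;
#'   \item `met_hours = sum(met_i) * 0.25` (identically `24 * mean_met`);
#'   \item `mvpa_met_hours = sum over slots with met_i >= 3 of met_i * 0.25`
#'     — moderate-to-vigorous physical activity; the threshold is inclusive
#'     and the full (not net) MET of qualifying slots is summed;
#'   \item per-category minutes and MET-hours over the five categories;
#'   \item per-subcategory minutes and MET-hours over every subcategory tag
#'     present in the compendium.
#' }
#'
#' @param day a complete [diary_day()].
#' @param compendium a `compendium`.
#' @return a named list of class `daily_metrics`; the decomposition maps are
#'   named numeric vectors (`category_minutes`, `category_met_hours`,
#'   `subcategory_minutes`, `subcategory_met_hours`).
#' @export
#' @examples
#' comp <- default_compendium()
#' day <- diary_day(rep(c("SLEEP", "W01", "L01"), each = 32), "weekday")
#' score_day(day, comp)$mean_met
score_day <- function(day, compendium) {
  stopifnot(inherits(day, "diary_day"))
  if (anyNA(day)) {
    stop("cannot score an incomplete day (", sum(is.na(day)),
         " missing slots)", call. = FALSE)
  }
  m <- score_matrix(matrix(unclass(day), nrow = 1L), compendium)
  row <- as.list(m[1L, ])
  structure(list(
    mean_met = row$mean_met,
    met_hours = row$met_hours,
    mvpa_met_hours = row$mvpa_met_hours,
    category_minutes = unlist_prefix(row, "cat_min_"),
    category_met_hours = unlist_prefix(row, "cat_meth_"),
    subcategory_minutes = unlist_prefix(row, "sub_min_"),
    subcategory_met_hours = unlist_prefix(row, "sub_meth_")
  ), class = "daily_metrics")
}

unlist_prefix <- function(row, prefix) {
  sel <- startsWith(names(row), prefix)
  v <- unlist(row[sel])
  names(v) <- substring(names(row)[sel], nchar(prefix) + 1L)
  v
}

# vectorised scorer over an n x 96 code matrix -> data.frame, one row per day
score_matrix <- function(codes, compendium) {
  stopifnot(inherits(compendium, "compendium"))
  n <- nrow(codes)
  idx <- compendium_index(compendium, codes)
  dim(idx) <- dim(codes)
  met <- matrix(compendium$met[idx], n, N_SLOTS)
  total <- rowSums(met)
  out <- data.frame(
    mean_met = total / N_SLOTS,
    met_hours = total * (SLOT_MIN / 60),
    mvpa_met_hours = rowSums(met * (met >= MVPA_THRESHOLD)) * (SLOT_MIN / 60)
  )
  cat_of_slot <- matrix(compendium$category[idx], n, N_SLOTS)
  for (cc in CATEGORIES) {
    in_cat <- cat_of_slot == cc
    out[[paste0("cat_min_", cc)]] <- rowSums(in_cat) * SLOT_MIN
    out[[paste0("cat_meth_", cc)]] <- rowSums(met * in_cat) * (SLOT_MIN / 60)
  }
  sub_of_slot <- matrix(compendium$subcategory[idx], n, N_SLOTS)
  for (ss in sort(unique(compendium$subcategory))) {
    in_sub <- sub_of_slot == ss
    out[[paste0("sub_min_", ss)]] <- rowSums(in_sub) * SLOT_MIN
    out[[paste0("sub_meth_", ss)]] <- rowSums(met * in_sub) * (SLOT_MIN / 60)
  }
  out
}

#' Weekday/weekend weighting
#'
#' Combines a weekday value and a weekend value into a typical-day value as
#' `(5 * weekday + 2 * weekend) / 7`: five weekdays and two weekend days per
#' week.
#'
#' @param weekday_value,weekend_value finite numeric vectors (recycled).
#' @return the weighted combination.
#' @export
weekly_weight <- function(weekday_value, weekend_value) {
  stopifnot(all(is.finite(weekday_value)), all(is.finite(weekend_value)))
  (5 * weekday_value + 2 * weekend_value) / 7
}

#' Score one participant's two-day record
#'
#' Scores the weekday and weekend diary with [score_day()] and combines every
#' metric with [weekly_weight()]. Covariates are passed through.
#'
#' @param record a complete `participant_record`.
#' @param compendium a `compendium`.
#' @return a `weekly_metrics` list: the same fields as `daily_metrics`, each
#'   weekday/weekend weighted, plus the covariates.
#' @export
score_participant <- function(record, compendium) {
  stopifnot(inherits(record, "participant_record"))
  if (!is_complete(record)) {
    stop("record ", record$participant_id, " is incomplete", call. = FALSE)
  }
  wd <- score_day(record$weekday_diary, compendium)
  we <- score_day(record$weekend_diary, compendium)
  out <- mapply(function(a, b) weekly_weight(a, b), unclass(wd), unclass(we),
                SIMPLIFY = FALSE)
  out$participant_id <- record$participant_id
  out$covariates <- record[setdiff(COVARIATE_COLS, "participant_id")]
  structure(out, class = "weekly_metrics")
}

#' Score a complete cohort
#'
#' Vectorised scoring of every participant: one row of weekday/weekend
#' weighted metrics per participant, in input order, with covariates bound
#' on the left. Decomposition maps become flat columns `cat_min_*`,
#' `cat_meth_*`, `sub_min_*`, `sub_meth_*`.
#'
#' @param cohort a `cohort` whose records are all complete (apply
#'   [filter_complete()] first).
#' @param compendium a `compendium`.
#' @return a data frame of class `cohort_scores`.
#' @export
score_cohort <- function(cohort, compendium) {
  stopifnot(inherits(cohort, "cohort"))
  ok <- complete_mask(cohort)
  if (!all(ok)) {
    stop("cohort contains incomplete records: ",
         paste(utils::head(cohort$covariates$participant_id[!ok], 5),
               collapse = ", "),
         if (sum(!ok) > 5) ", ..." else "",
         "; run filter_complete() first", call. = FALSE)
  }
  if (length(cohort) == 0L) {
    wd <- score_matrix(cohort$weekday, compendium)
    return(structure(cbind(cohort$covariates, wd),
                     class = c("cohort_scores", "data.frame")))
  }
  wd <- score_matrix(cohort$weekday, compendium)
  we <- score_matrix(cohort$weekend, compendium)
  weighted <- as.data.frame(mapply(weekly_weight, wd, we, SIMPLIFY = FALSE))
  out <- cbind(cohort$covariates, weighted)
  rownames(out) <- NULL
  structure(out, class = c("cohort_scores", "data.frame"))
}

#' Distribution summary of one scored metric
#'
#' @param table a `cohort_scores` data frame.
#' @param field name of a numeric metric column, e.g. `"mean_met"`.
#' @param breaks histogram break specification passed to [graphics::hist()]
#'   semantics via [base::cut()]; default chooses ~20 equal-width bins.
#' @return a list of class `summary_stats`: `n`, `mean`, `sd` (n-1
#'   denominator; 0 with `sd_undefined = TRUE` when n = 1), `median`, `q25`,
#'   `q75`, `iqr` (quantiles use linear interpolation between order
#'   statistics, [stats::quantile()] type 7), and `histogram` (data frame of
#'   bin left/right edges and counts).
#' @export
distribution_summary <- function(table, field, breaks = NULL) {
  if (!field %in% names(table)) {
    stop("no such metric field: ", field, call. = FALSE)
  }
  x <- table[[field]]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty table", call. = FALSE)
  sd_undefined <- length(x) < 2L
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (is.null(breaks)) {
    breaks <- pretty(range(x), n = 20)
  }
  counts <- table(cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE))
  structure(list(
    field = field,
    n = length(x),
    mean = mean(x),
    sd = if (sd_undefined) 0 else stats::sd(x),
    sd_undefined = sd_undefined,
    median = qs[2],
    q25 = qs[1],
    q75 = qs[3],
    iqr = qs[3] - qs[1],
    histogram = data.frame(left = utils::head(breaks, -1),
                           right = breaks[-1],
                           count = as.integer(counts))
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> ", x$field, " (n=", x$n, ")\n", sep = "")
  cat(sprintf("  mean %.3f (SD %.3f)  median %.3f  IQR %.2f-%.2f\n",
              x$mean, x$sd, x$median, x$q25, x$q75))
  invisible(x)
}
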