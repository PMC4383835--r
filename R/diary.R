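#' Construct a single diary day
#'
#' A diary day is an ordered sequence of 96 activity codes, one per 15-minute
#' slot; slot `i` (0-based) covers the half-open clock interval
#' `[15*i, 15*(i+1))` minutes after midnight. Unfilled slots are `NA`.
#'
#' @param codes character vector of length 96 (activity codes, `NA` for
#'   missing slots).
#' @param day_type `"weekday"` or `"weekend"`.
#' @return a `diary_day` object.
#' @export
diary_day <- function(codes, day_type = c("weekday", "weekend")) {
  day_type <- match.arg(day_type)
  codes <- as.character(codes)
  if (length(codes) != N_SLOTS) {
    stop("a diary day must have exactly ", N_SLOTS, " slots, got ",
         length(codes), call. = FALSE)
  }
  structure(codes, day_type = day_type, class = "diary_day")
}

#' @export
print.diary_day <- function(x, ...) {
  n_missing <- sum(is.na(x))
  cat("<diary_day> ", attr(x, "day_type"), ", ", N_SLOTS - n_missing, "/",
      N_SLOTS, " slots filled\n", sep = "")
  invisible(x)
}

COVARIATE_COLS <- c("participant_id", "sex", "age", "area", "occupation",
                    "income_band", "marital_status", "exercise_habit",
                    "weight", "bmi")

SEX_LEVELS <- c("man", "woman")
AREA_LEVELS <- c("urban", "urban_rural", "rural")
OCCUPATION_LEVELS <- c("employee", "self_employed", "housewife_fulltime",
                       "housewife_parttime", "student", "unemployed", "other")
INCOME_LEVELS <- c("lt3", "3to5", "5to7", "7to10", "gt10")
MARITAL_LEVELS <- c("married", "unmarried")
EXERCISE_LEVELS <- c("none", "twice_weekly_30min")

# internal cohort constructor: covariates data.frame + two n x 96 code
# matrices (NA = missing slot), rows aligned with covariates
new_cohort <- function(covariates, weekday, weekend, provenance = "") {
  stopifnot(is.data.frame(covariates),
            all(COVARIATE_COLS %in% names(covariates)),
            is.matrix(weekday), is.matrix(weekend),
            nrow(weekday) == nrow(covariates),
            nrow(weekend) == nrow(covariates),
            ncol(weekday) == N_SLOTS, ncol(weekend) == N_SLOTS)
  if (anyDuplicated(covariates$participant_id)) {
    stop("participant_id must be unique within a cohort", call. = FALSE)
  }
  rownames(weekday) <- rownames(weekend) <- covariates$participant_id
  structure(list(covariates = covariates, weekday = weekday,
                 weekend = weekend, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$covariates), " participants",
      if (nzchar(x$provenance)) paste0(" (", x$provenance, ")"), "\n",
      sep = "")
  cat("  complete two-day diaries: ", sum(complete_mask(x)), "\n", sep = "")
  invisible(x)
}

#' @export
length.cohort <- function(x) nrow(x$covariates)

#' Extract one participant record from a cohort
#'
#' @param cohort a `cohort` object.
#' @param i row index or participant id.
#' @return a `participant_record`: the covariate fields plus `weekday_diary`
#'   and `weekend_diary` ([diary_day()] objects).
#' @export
get_record <- function(cohort, i) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.character(i)) {
    i <- match(i, cohort$covariates$participant_id)
    if (is.na(i)) stop("unknown participant id", call. = FALSE)
  }
  rec <- as.list(cohort$covariates[i, , drop = FALSE])
  rec$weekday_diary <- diary_day(cohort$weekday[i, ], "weekday")
  rec$weekend_diary <- diary_day(cohort$weekend[i, ], "weekend")
  structure(rec, class = "participant_record")
}

#' Read a diary cohort from long-format CSV files
#'
#' The diary file is long format, one row per filled slot, with header
#' `participant_id,day_type,slot,activity_code`; `day_type` is `weekday` or
#' `weekend` and `slot` an integer in 0-95. The covariate file has header
#' `participant_id,sex,age,area,occupation,income_band,marital_status,`
#' `exercise_habit,weight,bmi`. Every covariate row becomes one participant;
#' slots with no diary row are left missing. Diary rows whose id has no
#' covariate row are a format error, as are slot indices outside 0-95 and
#' activity codes absent from the compendium.
#'
#' @param diary_file,covariate_file CSV paths.
#' @param compendium a `compendium` used to validate activity codes.
#' @return a `cohort` object.
#' @export
read_diaries <- function(diary_file, covariate_file, compendium) {
  stopifnot(inherits(compendium, "compendium"))
  diaries <- utils::read.csv(diary_file, stringsAsFactors = FALSE,
                             colClasses = c(participant_id = "character",
                                            activity_code = "character"))
  covars <- utils::read.csv(covariate_file, stringsAsFactors = FALSE,
                            colClasses = c(participant_id = "character"))
  need <- c("participant_id", "day_type", "slot", "activity_code")
  if (!all(need %in% names(diaries))) {
    stop("diary file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(COVARIATE_COLS %in% names(covars))) {
    stop("covariate file must have columns ",
         paste(COVARIATE_COLS, collapse = ", "), call. = FALSE)
  }
  if (any(diaries$slot < 0 | diaries$slot > (N_SLOTS - 1))) {
    stop("slot index outside 0-", N_SLOTS - 1, " in diary file",
         call. = FALSE)
  }
  if (!all(diaries$day_type %in% c("weekday", "weekend"))) {
    stop("day_type must be 'weekday' or 'weekend'", call. = FALSE)
  }
  orphan <- setdiff(unique(diaries$participant_id), covars$participant_id)
  if (length(orphan) > 0) {
    stop("diary rows without covariate row for id(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  compendium_index(compendium, diaries$activity_code)  # validates codes

  n <- nrow(covars)
  wd <- matrix(NA_character_, n, N_SLOTS)
  we <- matrix(NA_character_, n, N_SLOTS)
  row_i <- match(diaries$participant_id, covars$participant_id)
  col_i <- diaries$slot + 1L
  is_wd <- diaries$day_type == "weekday"
  wd[cbind(row_i[is_wd], col_i[is_wd])] <- diaries$activity_code[is_wd]
  we[cbind(row_i[!is_wd], col_i[!is_wd])] <- diaries$activity_code[!is_wd]
  new_cohort(covars[COVARIATE_COLS], wd, we,
             provenance = paste0("read:", basename(diary_file)))
}

#' Write a cohort's diaries and covariates to CSV
#'
#' Inverse of [read_diaries()]; missing slots produce no row.
#'
#' @param cohort a `cohort`.
#' @param diary_file,covariate_file output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_diaries <- function(cohort, diary_file, covariate_file) {
  stopifnot(inherits(cohort, "cohort"))
  long_one <- function(mat, day_type) {
    filled <- which(!is.na(mat), arr.ind = TRUE)
    filled <- filled[order(filled[, 1], filled[, 2]), , drop = FALSE]
    data.frame(
      participant_id = cohort$covariates$participant_id[filled[, 1]],
      day_type = day_type,
      slot = filled[, 2] - 1L,
      activity_code = mat[filled],
      stringsAsFactors = FALSE)
  }
  long <- rbind(long_one(cohort$weekday, "weekday"),
                long_one(cohort$weekend, "weekend"))
  long <- long[order(long$participant_id, long$day_type, long$slot), ]
  utils::write.csv(long, diary_file, row.names = FALSE)
  utils::write.csv(cohort$covariates, covariate_file, row.names = FALSE)
  invisible(c(diary_file, covariate_file))
}

#' Is a participant record complete?
#'
#' A record is complete when all 96 slots of both its weekday and weekend
#' diary are filled. A single missing slot on either day makes the record
#' incomplete — the strictest reading of a "complete two-day dataset"; no
#' imputation is attempted.
#'
#' @param record a `participant_record` from [get_record()].
#' @return `TRUE` or `FALSE`.
#' @export
is_complete <- function(record) {
  stopifnot(inherits(record, "participant_record"))
  !anyNA(record$weekday_diary) && !anyNA(record$weekend_diary)
}

complete_mask <- function(cohort) {
  rowSums(is.na(cohort$weekday)) == 0L & rowSums(is.na(cohort$weekend)) == 0L
}

#' Filter a cohort to complete records
#'
#' Applies the completeness exclusion rule: participants missing any slot on
#' either day are excluded. Idempotent: filtering a filtered cohort changes
#' nothing.
#'
#' @param cohort a `cohort`.
#' @return a list with elements `cohort` (the retained records) and `report`
#'   (class `exclusion_report`: counts, percentage excluded to 2 decimals,
#'   and the excluded ids).
#' @export
filter_complete <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- complete_mask(cohort)
  retained <- new_cohort(cohort$covariates[keep, , drop = FALSE],
                         cohort$weekday[keep, , drop = FALSE],
                         cohort$weekend[keep, , drop = FALSE],
                         provenance = cohort$provenance)
  n <- length(keep)
  report <- structure(list(
    n_input = n,
    n_retained = sum(keep),
    n_excluded = sum(!keep),
    pct_excluded = if (n == 0) 0 else round(100 * sum(!keep) / n, 2),
    excluded_ids = cohort$covariates$participant_id[!keep]
  ), class = "exclusion_report")
  list(cohort = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report> ", x$n_input, " records: ", x$n_retained,
      " retained, ", x$n_excluded, " (", sprintf("%.2f", x$pct_excluded),
      "%) excluded for incomplete diaries\n", sep = "")
  invisible(x)
}
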