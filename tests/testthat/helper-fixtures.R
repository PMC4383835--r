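# fixtures built in code: a small known-MET compendium, CSV writers for
# hand-made cohorts, a brute-force scoring oracle, and a cached default
# synthetic cohort shared across test files

test_compendium_df <- function() {
  data.frame(
    code = c("M09", "M10", "M13", "M15", "M24", "M30", "M35", "M60"),
    label = c("sleeping", "resting", "light leisure", "desk work",
              "cooking", "standing work", "brisk commute walk", "sport"),
    category = c("uncategorized", "leisure_sports", "leisure_sports",
                 "work", "household", "work", "transportation",
                 "leisure_sports"),
    subcategory = c("sleep", "quiet_leisure", "screen_leisure",
                    "work_sitting", "cooking", "work_standing",
                    "commute_walk", "sport_exercise"),
    met = c(0.9, 1.0, 1.3, 1.5, 2.4, 3.0, 3.5, 6.0),
    stringsAsFactors = FALSE)
}

write_compendium_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_compendium <- function() {
  load_compendium(write_compendium_csv(test_compendium_df()))
}

default_covariates <- function(id) {
  data.frame(participant_id = id, sex = "man", age = 40, area = "urban",
             occupation = "employee", income_band = "5to7",
             marital_status = "married", exercise_habit = "none",
             weight = 65, bmi = 22.5, stringsAsFactors = FALSE)
}

# diaries: named list id -> list(weekday = codes, weekend = codes); codes
# may contain NA (slot omitted from the long file); covariate-only ids can
# pass list() to get fully missing diaries
write_cohort_csvs <- function(diaries, covariates = NULL) {
  rows <- list()
  for (id in names(diaries)) {
    for (dt in names(diaries[[id]])) {
      codes <- diaries[[id]][[dt]]
      filled <- which(!is.na(codes))
      if (length(filled) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = id, day_type = dt, slot = filled - 1L,
          activity_code = codes[filled], stringsAsFactors = FALSE)
      }
    }
  }
  diary_path <- tempfile(fileext = ".csv")
  cov_path <- tempfile(fileext = ".csv")
  long <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(participant_id = character(), day_type = character(),
               slot = integer(), activity_code = character())
  write.csv(long, diary_path, row.names = FALSE)
  if (is.null(covariates)) {
    covariates <- do.call(rbind, lapply(names(diaries), default_covariates))
  }
  write.csv(covariates, cov_path, row.names = FALSE)
  list(diaries = diary_path, covariates = cov_path)
}

make_cohort <- function(diaries, covariates = NULL,
                        compendium = test_compendium()) {
  paths <- write_cohort_csvs(diaries, covariates)
  read_diaries(paths$diaries, paths$covariates, compendium)
}

random_codes <- function(comp, n = 96) {
  sample(comp$code, n, replace = TRUE)
}

# independent brute-force oracle: one explicit loop over all 192 weighted
# slots, never touching the package's scoring path
oracle_score_participant <- function(wd, we, comp) {
  met <- setNames(comp$met, comp$code)
  cat_of <- setNames(comp$category, comp$code)
  sub_of <- setNames(comp$subcategory, comp$code)
  cats <- sort(unique(comp$category))
  subs <- sort(unique(comp$subcategory))
  acc <- list(mean_met = 0, met_hours = 0, mvpa_met_hours = 0,
              cat_min = setNames(numeric(length(cats)), cats),
              cat_meth = setNames(numeric(length(cats)), cats),
              sub_min = setNames(numeric(length(subs)), subs),
              sub_meth = setNames(numeric(length(subs)), subs))
  codes <- c(wd, we)
  weights <- c(rep(5 / 7, 96), rep(2 / 7, 96))
  for (i in seq_along(codes)) {
    m <- met[[codes[i]]]
    w <- weights[i]
    acc$mean_met <- acc$mean_met + w * m / 96
    acc$met_hours <- acc$met_hours + w * m * 15 / 60
    if (m >= 3) acc$mvpa_met_hours <- acc$mvpa_met_hours + w * m * 15 / 60
    cc <- cat_of[[codes[i]]]
    ss <- sub_of[[codes[i]]]
    acc$cat_min[cc] <- acc$cat_min[cc] + w * 15
    acc$cat_meth[cc] <- acc$cat_meth[cc] + w * m * 15 / 60
    acc$sub_min[ss] <- acc$sub_min[ss] + w * 15
    acc$sub_meth[ss] <- acc$sub_meth[ss] + w * m * 15 / 60
  }
  acc
}

# the default calibrated cohort, generated once per test run
default_scores_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      comp <- default_compendium()
      cohort <- suppressWarnings(generate_cohort(default_config()))
      cache <<- score_cohort(cohort, comp)
    }
    cache
  }
})

# a null-configured generator: every area stratum gets the urban schedule
# and composition parameters, so area has no true effect on any metric
null_area_config <- function(seed = 1L, n_total = 300L) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$n_total <- n_total
  urbanize <- function(m) {
    for (a in c("urban_rural", "rural")) m[[a]] <- m[["urban"]]
    m
  }
  cfg$man_prob_by_area <- urbanize(cfg$man_prob_by_area)
  cfg$age_band_probs_by_area <- urbanize(cfg$age_band_probs_by_area)
  cfg$income_probs_by_area <- urbanize(cfg$income_probs_by_area)
  cfg$marriage_prob_by_area <- urbanize(cfg$marriage_prob_by_area)
  cfg$exercise_habit_prob_by_area <- urbanize(cfg$exercise_habit_prob_by_area)
  sc <- cfg$schedule
  sc$work$job_type_probs$man <- urbanize(sc$work$job_type_probs$man)
  sc$work$job_type_probs$woman <- urbanize(sc$work$job_type_probs$woman)
  sc$commute$mode_probs_by_area <- urbanize(sc$commute$mode_probs_by_area)
  sc$commute$walk_oneway_min <- urbanize(sc$commute$walk_oneway_min)
  sc$commute$transit_ride_oneway_min <-
    urbanize(sc$commute$transit_ride_oneway_min)
  sc$commute$car_oneway_min <- urbanize(sc$commute$car_oneway_min)
  sc$errand$weekend_outing_prob <- urbanize(sc$errand$weekend_outing_prob)
  sc$errand$mode_probs_by_area <- urbanize(sc$errand$mode_probs_by_area)
  sc$gardening$prob_by_area <- urbanize(sc$gardening$prob_by_area)
  cfg$schedule <- sc
  cfg
}
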