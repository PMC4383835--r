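#' Format a p-value in journal style
#'
#' Leading-dot style: values below .001 render as `"<.001"`, otherwise two
#' decimals (three when rounding to two would print ".00").
#'
#' @param p a p-value in `[0, 1]`.
#' @return a character scalar.
#' @export
#' @examples
#' format_p(0.0004)  # "<.001"
#' format_p(0.04)    # ".04"
format_p <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("NA")
    if (pi < 0.001) return("<.001")
    s <- sprintf("%.2f", pi)
    if (s == "0.00") s <- sprintf("%.3f", pi)
    sub("^0", "", s)
  }, character(1))
}

format_mean_sd <- function(m, s, digits = 1) {
  sprintf("%.*f (%.*f)", digits, m, digits, s)
}

format_n_pct <- function(n, total, digits = 1) {
  sprintf("%d (%.*f)", n, digits, 100 * n / total)
}

FIG5_BEHAVIORS <- c("work_standing", "work_vigorous", "sport_exercise",
                    "cooking", "cleaning", "cycling_transport",
                    "car_wash_gardening", "childcare", "commute_walk",
                    "work_walking")
ADJUST_COVARIATES <- c("age", "sex", "occupation", "income_band",
                       "marital_status")

#' Run the diary-analysis pipeline
#'
#' Orchestrates `generate` (write synthetic diaries + covariates from a
#' config), `validate` (read back, apply the completeness filter, write the
#' exclusion report), `score` (per-participant weighted metrics), `analyze`
#' (characteristics table, region-comparison table, MVPA regression) and
#' `report` (rendered publication-style tables and histogram bin counts).
#' Stages depend on their predecessors' artifacts; a missing upstream
#' artifact is an error naming the stage to run first. Every number in the
#' outputs is computed by the scoring/statistics modules; this function only
#' sequences them and records a manifest (input hashes, seed, package
#' version) so reruns are auditable.
#'
#' @param config_path path to a generator config JSON (needed by
#'   `generate`).
#' @param stages character vector, subset of
#'   `c("generate", "validate", "score", "analyze", "report")`, executed in
#'   canonical order.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the config seed.
#' @param compendium a `compendium`; defaults to the packaged one.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config_path = NULL,
                         stages = c("generate", "validate", "score",
                                    "analyze", "report"),
                         out_dir, seed = NULL,
                         compendium = default_compendium(),
                         quiet = FALSE) {
  all_stages <- c("generate", "validate", "score", "analyze", "report")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  path <- function(f) file.path(out_dir, f)
  need_artifact <- function(f, produced_by) {
    if (!file.exists(path(f))) {
      stop("missing artifact '", f, "': run stage '", produced_by,
           "' first", call. = FALSE)
    }
  }

  if ("generate" %in% stages) {
    if (is.null(config_path)) stop("generate requires config_path",
                                   call. = FALSE)
    cfg <- load_config(config_path)
    if (!is.null(seed)) cfg$seed <- seed
    say("generate: n_total = ", cfg$n_total)
    cohort <- generate_cohort(cfg)
    write_diaries(cohort, path("diaries.csv"), path("covariates.csv"))
  }

  if ("validate" %in% stages) {
    need_artifact("diaries.csv", "generate")
    cohort <- read_diaries(path("diaries.csv"), path("covariates.csv"),
                           compendium)
    fc <- filter_complete(cohort)
    say("validate: ", fc$report$n_input, " read, ", fc$report$n_excluded,
        " (", sprintf("%.2f", fc$report$pct_excluded), "%) excluded")
    jsonlite::write_json(fc$report[c("n_input", "n_retained", "n_excluded",
                                     "pct_excluded", "excluded_ids")],
                         path("exclusion_report.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if ("score" %in% stages) {
    need_artifact("diaries.csv", "generate")
    cohort <- read_diaries(path("diaries.csv"), path("covariates.csv"),
                           compendium)
    cohort <- filter_complete(cohort)$cohort
    scores <- score_cohort(cohort, compendium)
    say("score: ", nrow(scores), " participants scored")
    utils::write.csv(scores, path("scores.csv"), row.names = FALSE)
  }

  if ("analyze" %in% stages) {
    need_artifact("scores.csv", "score")
    scores <- utils::read.csv(path("scores.csv"), stringsAsFactors = FALSE)
    say("analyze: n = ", nrow(scores))
    an <- analyze_cohort(scores)
    utils::write.csv(an$table1, path("table1.csv"), row.names = FALSE)
    utils::write.csv(an$table2, path("table2.csv"), row.names = FALSE)
    utils::write.csv(an$regression, path("regression.csv"),
                     row.names = FALSE)
    jsonlite::write_json(an$meta, path("analysis_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    need_artifact("table1.csv", "analyze")
    scores <- utils::read.csv(path("scores.csv"), stringsAsFactors = FALSE)
    for (fld in c("mean_met", "mvpa_met_hours")) {
      hs <- distribution_summary(scores, fld)$histogram
      utils::write.csv(hs, path(paste0("hist_", fld, ".csv")),
                       row.names = FALSE)
    }
    rendered <- render_tables(list(
      table1 = utils::read.csv(path("table1.csv")),
      table2 = utils::read.csv(path("table2.csv"))))
    writeLines(rendered, path("tables_rendered.txt"))
    say("report: histograms and rendered tables written")
  }

  manifest <- list(
    command = paste(stages, collapse = ","),
    config_path = config_path,
    config_hash = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    input_hashes = as.list(tools::md5sum(Filter(
      file.exists, c(path("diaries.csv"), path("covariates.csv"))))),
    seed = seed,
    tool_version = as.character(utils::packageVersion("metdiary")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# the full analysis stage: characteristics by area, region comparisons,
# MVPA regression on the behaviour subcategories
analyze_cohort <- function(scores) {
  scores$area <- factor(scores$area, levels = AREA_LEVELS)
  by_area <- split(scores, scores$area)
  n_area <- vapply(by_area, nrow, integer(1))

  # --- characteristics table: mean (SD) + ANOVA p for continuous rows,
  #     n (%) + chi-square p for categorical rows
  t1 <- list()
  for (v in c("age", "weight", "bmi")) {
    a <- one_way_anova(scores, v, "area")
    t1[[length(t1) + 1L]] <- data.frame(
      characteristic = v, level = "",
      urban = mean(by_area$urban[[v]]),
      urban_rural = mean(by_area$urban_rural[[v]]),
      rural = mean(by_area$rural[[v]]),
      sd_urban = stats::sd(by_area$urban[[v]]),
      sd_urban_rural = stats::sd(by_area$urban_rural[[v]]),
      sd_rural = stats::sd(by_area$rural[[v]]),
      statistic = a$f_stat, p_value = a$p_value, test = "anova")
  }
  for (v in c("sex", "occupation", "income_band", "exercise_habit",
              "marital_status")) {
    counts <- table(scores[[v]], scores$area)
    cs <- chi_square_table(counts)
    for (lv in rownames(counts)) {
      t1[[length(t1) + 1L]] <- data.frame(
        characteristic = v, level = lv,
        urban = counts[lv, "urban"],
        urban_rural = counts[lv, "urban_rural"],
        rural = counts[lv, "rural"],
        sd_urban = NA, sd_urban_rural = NA, sd_rural = NA,
        statistic = cs$statistic, p_value = cs$p_value, test = "chi_square")
    }
  }
  table1 <- do.call(rbind, t1)

  # --- region comparisons: raw ANOVA rows and covariate-adjusted rows
  metrics <- c(mean_met = "mean_met", met_hours = "met_hours",
               mvpa_met_hours = "mvpa_met_hours",
               household_met_hours = "cat_meth_household",
               household_minutes = "cat_min_household",
               transport_met_hours = "cat_meth_transportation",
               transport_minutes = "cat_min_transportation",
               work_met_hours = "cat_meth_work",
               work_minutes = "cat_min_work",
               leisure_met_hours = "cat_meth_leisure_sports",
               leisure_minutes = "cat_min_leisure_sports",
               commute_walk_minutes = "sub_min_commute_walk",
               commute_transit_minutes = "sub_min_commute_transit",
               commute_car_minutes = "sub_min_commute_car_sitting",
               work_sitting_minutes = "sub_min_work_sitting",
               work_standing_minutes = "sub_min_work_standing")
  adjusted_rows <- c("met_hours", "mvpa_met_hours", "commute_walk_minutes",
                     "commute_transit_minutes", "commute_car_minutes",
                     "work_sitting_minutes", "work_standing_minutes")
  t2 <- list()
  for (nm in names(metrics)) {
    col <- metrics[[nm]]
    a <- one_way_anova(scores, col, "area")
    t2[[length(t2) + 1L]] <- data.frame(
      metric = nm, adjusted = FALSE,
      urban = mean(by_area$urban[[col]]),
      urban_rural = mean(by_area$urban_rural[[col]]),
      rural = mean(by_area$rural[[col]]),
      sd_urban = stats::sd(by_area$urban[[col]]),
      sd_urban_rural = stats::sd(by_area$urban_rural[[col]]),
      sd_rural = stats::sd(by_area$rural[[col]]),
      f_stat = a$f_stat, df1 = a$df_between, df2 = a$df_within,
      p_value = a$p_value)
    if (nm %in% adjusted_rows) {
      ac <- one_way_ancova(scores, col, "area", ADJUST_COVARIATES)
      t2[[length(t2) + 1L]] <- data.frame(
        metric = nm, adjusted = TRUE,
        urban = ac$adjusted_means[["urban"]],
        urban_rural = ac$adjusted_means[["urban_rural"]],
        rural = ac$adjusted_means[["rural"]],
        sd_urban = NA, sd_urban_rural = NA, sd_rural = NA,
        f_stat = ac$f_stat, df1 = ac$df1, df2 = ac$df2,
        p_value = ac$p_value)
    }
  }
  table2 <- do.call(rbind, t2)

  # --- MVPA regression on the ten behaviour subcategories, total/men/women
  predictors <- paste0("sub_meth_", FIG5_BEHAVIORS)
  reg_rows <- list()
  for (sample_name in c("total", "man", "woman")) {
    sub <- if (sample_name == "total") scores
           else scores[scores$sex == sample_name, ]
    rg <- standardized_regression(sub, "mvpa_met_hours", predictors)
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      sample = sample_name,
      predictor = sub("^sub_meth_", "", names(rg$standardized_betas)),
      beta = unname(rg$standardized_betas),
      r_squared = rg$r_squared, see = rg$see, n = rg$n,
      p_value = rg$p_value)
  }
  regression <- do.call(rbind, reg_rows)

  interaction <- two_way_ancova_interaction(
    scores, "mvpa_met_hours", "sex", "area",
    setdiff(ADJUST_COVARIATES, "sex"))
  tukey <- tukey_hsd(scores, "met_hours", "area")

  list(table1 = table1, table2 = table2, regression = regression,
       meta = list(
         n = nrow(scores), n_by_area = as.list(n_area),
         interaction_sex_area = interaction[c("f_stat", "df1", "df2",
                                              "p_value")],
         tukey_met_hours = tukey$pairwise,
         adjust_covariates = ADJUST_COVARIATES))
}

#' Render analysis tables in publication style
#'
#' Formats the `analyze` stage's characteristics and region-comparison
#' tables with `mean (SD)` / `n (%)` cells, `F (df1, df2)` columns and
#' journal-style p-values (see [format_p()]).
#'
#' @param results a list with data frames `table1` and/or `table2` as
#'   written by [run_pipeline()].
#' @return a character vector of formatted lines.
#' @export
render_tables <- function(results) {
  out <- character()
  t1 <- results$table1
  if (!is.null(t1)) {
    out <- c(out, "== Characteristics by region ==")
    totals <- NULL
    for (i in seq_len(nrow(t1))) {
      r <- t1[i, ]
      cells <- if (r$test == "anova") {
        sprintf("%s", format_mean_sd(c(r$urban, r$urban_rural, r$rural),
                                     c(r$sd_urban, r$sd_urban_rural,
                                       r$sd_rural)))
      } else {
        grp <- t1[t1$characteristic == r$characteristic, ]
        format_n_pct(c(r$urban, r$urban_rural, r$rural),
                     c(sum(grp$urban), sum(grp$urban_rural),
                       sum(grp$rural)))
      }
      out <- c(out, sprintf("%-18s %-22s %-14s %-14s %-14s %s",
                            r$characteristic, r$level, cells[1], cells[2],
                            cells[3], format_p(r$p_value)))
    }
  }
  t2 <- results$table2
  if (!is.null(t2)) {
    out <- c(out, "", "== Physical activity by region ==")
    for (i in seq_len(nrow(t2))) {
      r <- t2[i, ]
      cells <- if (isTRUE(r$adjusted) | isTRUE(is.na(r$sd_urban))) {
        sprintf("%.1f", c(r$urban, r$urban_rural, r$rural))
      } else {
        format_mean_sd(c(r$urban, r$urban_rural, r$rural),
                       c(r$sd_urban, r$sd_urban_rural, r$sd_rural))
      }
      out <- c(out, sprintf("%-26s%s %-14s %-14s %-14s %.2f (%d,%d) %s",
                            r$metric, if (isTRUE(r$adjusted)) "*" else " ",
                            cells[1], cells[2], cells[3], r$f_stat, r$df1,
                            r$df2, format_p(r$p_value)))
    }
    out <- c(out, "* adjusted for age, sex, occupation, income, marriage")
  }
  out
}
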