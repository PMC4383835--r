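comp <- test_compendium()

test_that("score_day matches hand-computed sums", {
  # uniform MET 1.0 day
  d1 <- score_day(diary_day(rep("M10", 96), "weekday"), comp)
  expect_equal(d1$mean_met, 1.0)
  expect_equal(d1$met_hours, 24.0)
  expect_equal(d1$mvpa_met_hours, 0)

  # 32 slots at 0.9, 32 at 1.3, 32 at 3.5:
  # mean (32*0.9+32*1.3+32*3.5)/96 = 1.9; mvpa 32*3.5*0.25 = 28
  d2 <- score_day(diary_day(rep(c("M09", "M13", "M35"), each = 32),
                            "weekday"), comp)
  expect_equal(d2$mean_met, 1.9)
  expect_equal(d2$met_hours, 45.6)
  expect_equal(d2$mvpa_met_hours, 28.0)
  expect_equal(unname(d2$category_minutes["uncategorized"]), 480)
  expect_equal(unname(d2$subcategory_minutes["commute_walk"]), 480)

  # MVPA threshold is inclusive at exactly 3.0: 4 slots at 3.0 -> 3.0
  codes3 <- c(rep("M30", 4), rep("M10", 92))
  d3 <- score_day(diary_day(codes3, "weekday"), comp)
  expect_equal(d3$mvpa_met_hours, 3.0)

  expect_error(score_day(diary_day(replace(rep("M10", 96), 7, NA),
                                   "weekday"), comp), "incomplete")
})

test_that("weekly weighting is (5*weekday + 2*weekend)/7", {
  expect_equal(weekly_weight(1.5, 2.2), 1.7)
  expect_equal(weekly_weight(0, 7), 2.0)
  for (x in c(-3, 0, 0.9, 24, 1e6)) {
    expect_equal(weekly_weight(x, x), x)
  }
})

test_that("score_participant combines days per metric", {
  same <- make_cohort(list(P = list(weekday = rep(c("M10", "M30"), 48),
                                    weekend = rep(c("M10", "M30"), 48))),
                      compendium = comp)
  wm <- score_participant(get_record(same, "P"), comp)
  dm <- score_day(get_record(same, "P")$weekday_diary, comp)
  expect_equal(wm$mean_met, dm$mean_met)
  expect_equal(wm$subcategory_met_hours, dm$subcategory_met_hours)

  # weekday all 1.0, weekend all 2.4 -> (5*1 + 2*2.4)/7 = 1.4
  mixed <- make_cohort(list(P = list(weekday = rep("M10", 96),
                                     weekend = rep("M24", 96))),
                       compendium = comp)
  wm2 <- score_participant(get_record(mixed, "P"), comp)
  expect_equal(wm2$mean_met, 1.4)

  incomplete <- make_cohort(list(P = list(weekday = rep("M10", 96))),
                            compendium = comp)
  expect_error(score_participant(get_record(incomplete, "P"), comp),
               "incomplete")
})

test_that("scoring agrees with a brute-force slot-sum oracle to 1e-12", {
  set.seed(20301)
  for (i in 1:25) {
    wd <- random_codes(comp)
    we <- random_codes(comp)
    cohort <- make_cohort(list(P = list(weekday = wd, weekend = we)),
                          compendium = comp)
    got <- score_participant(get_record(cohort, "P"), comp)
    want <- oracle_score_participant(wd, we, comp)
    expect_equal(got$mean_met, want$mean_met, tolerance = 1e-12)
    expect_equal(got$met_hours, want$met_hours, tolerance = 1e-12)
    expect_equal(got$mvpa_met_hours, want$mvpa_met_hours,
                 tolerance = 1e-12)
    expect_equal(got$category_minutes[names(want$cat_min)], want$cat_min,
                 tolerance = 1e-12)
    expect_equal(got$category_met_hours[names(want$cat_meth)],
                 want$cat_meth, tolerance = 1e-12)
    expect_equal(got$subcategory_minutes[names(want$sub_min)],
                 want$sub_min, tolerance = 1e-12)
    expect_equal(got$subcategory_met_hours[names(want$sub_meth)],
                 want$sub_meth, tolerance = 1e-12)
  }
})

test_that("scoring invariants hold on randomized diaries", {
  set.seed(9913)
  for (i in 1:20) {
    wd <- random_codes(comp)
    we <- random_codes(comp)
    cohort <- make_cohort(list(P = list(weekday = wd, weekend = we)),
                          compendium = comp)
    rec <- get_record(cohort, "P")
    w <- score_participant(rec, comp)
    dwd <- score_day(rec$weekday_diary, comp)
    dwe <- score_day(rec$weekend_diary, comp)

    # conservation over the five categories, and the met_hours identity
    expect_equal(sum(w$category_met_hours), w$met_hours, tolerance = 1e-12)
    expect_equal(w$met_hours, 24 * w$mean_met, tolerance = 1e-12)
    # MVPA bounds
    expect_lte(w$mvpa_met_hours, w$met_hours)
    expect_gte(w$mvpa_met_hours, 0)
    # weighted metrics are convex combinations of the two days
    for (f in c("mean_met", "met_hours", "mvpa_met_hours")) {
      expect_gte(w[[f]], min(dwd[[f]], dwe[[f]]) - 1e-12)
      expect_lte(w[[f]], max(dwd[[f]], dwe[[f]]) + 1e-12)
    }
  }
})

test_that("raising a single slot's MET weakly increases the headline metrics", {
  set.seed(5150)
  base <- random_codes(comp)
  i <- sample(96, 1)
  lo <- replace(base, i, "M10")   # 1.0
  hi <- replace(base, i, "M60")   # 6.0
  slo <- score_day(diary_day(lo, "weekday"), comp)
  shi <- score_day(diary_day(hi, "weekday"), comp)
  expect_gte(shi$mean_met, slo$mean_met)
  expect_gte(shi$met_hours, slo$met_hours)
  expect_gte(shi$mvpa_met_hours, slo$mvpa_met_hours)
})

test_that("score_cohort returns one ordered row per participant", {
  day <- rep(c("M10", "M30"), 48)
  cohort <- make_cohort(list(A = list(weekday = day, weekend = day),
                             B = list(weekday = day, weekend = day),
                             C = list(weekday = day, weekend = day)),
                        compendium = comp)
  sc <- score_cohort(cohort, comp)
  expect_equal(nrow(sc), 3L)
  expect_equal(sc$participant_id, c("A", "B", "C"))
  expect_equal(sc$mean_met, rep(sc$mean_met[1], 3))

  # incomplete record -> error naming the offender
  broken <- make_cohort(list(A = list(weekday = day, weekend = day),
                             BAD = list(weekday = day)),
                        compendium = comp)
  expect_error(score_cohort(broken, comp), "BAD")

  empty <- filter_complete(make_cohort(
    list(Z = list(weekday = replace(day, 1, NA), weekend = day)),
    compendium = comp))$cohort
  expect_equal(nrow(score_cohort(empty, comp)), 0L)
})

test_that("distribution_summary uses n-1 SD and linear-interpolation quantiles", {
  tb <- data.frame(x = c(1, 2, 3, 4))
  s <- distribution_summary(tb, "x")
  expect_equal(s$median, 2.5)
  expect_equal(s$q25, 1.75)
  expect_equal(s$q75, 3.25)
  expect_equal(s$sd, sd(c(1, 2, 3, 4)))
  expect_equal(sum(s$histogram$count), 4L)

  one <- distribution_summary(data.frame(x = 5), "x")
  expect_equal(one$mean, 5)
  expect_equal(one$median, 5)
  expect_equal(one$sd, 0)
  expect_true(one$sd_undefined)

  expect_error(distribution_summary(data.frame(x = numeric()), "x"),
               "empty")
  expect_error(distribution_summary(tb, "nope"), "nope")
})
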