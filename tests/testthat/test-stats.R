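test_that("one-way ANOVA reproduces the textbook decomposition", {
  tb <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                   g = rep(c("a", "b", "c"), each = 3))
  a <- one_way_anova(tb, "y", "g")
  # SSB = 3*(2-3)^2 + 0 + 3*(4-3)^2 = 6; SSW = 6; F = (6/2)/(6/6) = 3
  expect_equal(a$f_stat, 3.0)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)

  flat <- data.frame(y = c(1, 3, 1, 3, 1, 3), g = rep(c("a", "b", "c"), 2))
  expect_lt(one_way_anova(flat, "y", "g")$f_stat, 1e-10)

  expect_error(one_way_anova(data.frame(y = 1:3, g = c("a", "a", "b")),
                             "y", "g"), "fewer than 2")
})

test_that("summary-statistic ANOVA is algebraically identical to raw ANOVA", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    ns <- sample(3:12, k, replace = TRUE)
    y <- rnorm(sum(ns), mean = rep(runif(k, 0, 3), ns))
    g <- rep(letters[1:k], ns)
    tb <- data.frame(y = y, g = g)
    raw <- one_way_anova(tb, "y", "g")
    sums <- anova_from_summary(tapply(y, g, mean), tapply(y, g, sd),
                               as.vector(table(g)))
    expect_equal(sums$f_stat, raw$f_stat, tolerance = 1e-9)
    expect_equal(sums$p_value, raw$p_value, tolerance = 1e-9)
  }

  # two groups: F equals the squared pooled-variance t statistic
  y1 <- c(4.1, 5.2, 6.0, 5.5); y2 <- c(6.2, 7.1, 6.6)
  tt <- t.test(y1, y2, var.equal = TRUE)
  f2 <- anova_from_summary(c(mean(y1), mean(y2)), c(sd(y1), sd(y2)),
                           c(4, 3))
  expect_equal(f2$f_stat, unname(tt$statistic)^2, tolerance = 1e-9)

  expect_equal(anova_from_summary(c(2, 2, 2), c(1, 1, 1),
                                  c(5, 5, 5))$f_stat, 0)
  expect_error(anova_from_summary(1:3, 1:2, c(5, 5, 5)), "equal length")
  expect_error(anova_from_summary(1:2, c(1, 1), c(5, 1)), ">= 2")
})

test_that("ANCOVA with no covariates reduces to one-way ANOVA", {
  set.seed(31)
  tb <- data.frame(y = rnorm(60, rep(c(0, 0.5, 1), 20)),
                   g = rep(c("a", "b", "c"), 20))
  a0 <- one_way_anova(tb, "y", "g")
  ac <- one_way_ancova(tb, "y", "g")
  expect_equal(ac$f_stat, a0$f_stat, tolerance = 1e-9)
  expect_equal(ac$p_value, a0$p_value, tolerance = 1e-9)
  expect_equal(unname(ac$adjusted_means),
               as.vector(tapply(tb$y, tb$g, mean)), tolerance = 1e-9)
})

test_that("ANCOVA adjusts for confounding and recovers known group offsets", {
  set.seed(90210)
  n <- 1500
  g <- sample(c("u", "m", "r"), n, replace = TRUE)
  confounder <- rnorm(n, mean = c(u = 0, m = 1, r = 2)[g])
  offset <- c(u = 0, m = 0.8, r = 1.0)[g]
  y <- offset + 1.5 * confounder + rnorm(n, sd = 0.8)
  tb <- data.frame(y = y, g = g, z = confounder)

  ac <- one_way_ancova(tb, "y", "g", "z")
  est_diff_m <- ac$adjusted_means[["m"]] - ac$adjusted_means[["u"]]
  est_diff_r <- ac$adjusted_means[["r"]] - ac$adjusted_means[["u"]]
  expect_equal(est_diff_m, 0.8, tolerance = 0.15)
  expect_equal(est_diff_r, 1.0, tolerance = 0.15)

  # a zero-effect covariate leaves adjusted means near raw means
  tb$noise <- rnorm(n)
  ac2 <- one_way_ancova(tb, "y", "g", "noise")
  raw <- tapply(tb$y, tb$g, mean)
  expect_equal(unname(ac2$adjusted_means[names(raw)]), as.vector(raw),
               tolerance = 0.05)

  # collinear covariates are refused
  tb$z2 <- 2 * tb$z
  expect_error(one_way_ancova(tb, "y", "g", c("z", "z2")), "collinear")
})

test_that("adjusted means match emmeans proportional-weight least-squares means", {
  skip_if_not_installed("emmeans")
  set.seed(404)
  n <- 400
  tb <- data.frame(
    y = rnorm(n), g = sample(c("a", "b", "c"), n, replace = TRUE),
    z = rnorm(n), w = sample(c("p", "q"), n, replace = TRUE))
  tb$y <- tb$y + 0.6 * tb$z + (tb$g == "b") + 0.3 * (tb$w == "q")
  ours <- one_way_ancova(tb, "y", "g", c("z", "w"))
  fit <- lm(y ~ g + z + w, data = transform(tb, g = factor(g),
                                            w = factor(w)))
  em <- as.data.frame(emmeans::emmeans(fit, "g", weights = "proportional"))
  expect_equal(unname(ours$adjusted_means[em$g]), em$emmean,
               tolerance = 1e-8)
})

test_that("interaction test is symmetric and detects a one-sex group effect", {
  set.seed(1234)
  n <- 1200
  sex <- sample(c("man", "woman"), n, replace = TRUE)
  area <- sample(c("u", "m", "r"), n, replace = TRUE)
  z <- rnorm(n)
  # effect of area only among men
  y <- ifelse(sex == "man", c(u = 0, m = 0.4, r = 0.8)[area], 0) +
    0.5 * z + rnorm(n)
  tb <- data.frame(y = y, sex = sex, area = area, z = z)

  ab <- two_way_ancova_interaction(tb, "y", "sex", "area", "z")
  ba <- two_way_ancova_interaction(tb, "y", "area", "sex", "z")
  expect_equal(ab$f_stat, ba$f_stat, tolerance = 1e-9)
  expect_lt(ab$p_value, 0.05)

  # empty cell is refused
  tb2 <- tb[!(tb$sex == "man" & tb$area == "r"), ]
  expect_error(two_way_ancova_interaction(tb2, "y", "sex", "area", "z"),
               "empty")
})

test_that("Tukey HSD handles unequal n and degenerates correctly", {
  set.seed(8)
  # two groups: adjusted p equals the ANOVA p
  tb2 <- data.frame(y = rnorm(30, rep(c(0, 0.8), c(12, 18))),
                    g = rep(c("a", "b"), c(12, 18)))
  tk2 <- tukey_hsd(tb2, "y", "g")
  a2 <- one_way_anova(tb2, "y", "g")
  expect_equal(tk2$pairwise$p_adjusted, a2$p_value, tolerance = 1e-6)

  # identical groups: all adjusted p near 1
  tb3 <- data.frame(y = rep(c(1, 2, 3, 4), 3),
                    g = rep(c("a", "b", "c"), each = 4))
  expect_true(all(tukey_hsd(tb3, "y", "g")$pairwise$p_adjusted > 0.99))

  # ordered offsets: extreme pair has the smallest adjusted p
  set.seed(99)
  n <- 900
  g <- rep(c("urban", "mid", "rural"), each = n / 3)
  y <- c(rnorm(n / 3, 0), rnorm(n / 3, 0.25), rnorm(n / 3, 0.5))
  tk <- tukey_hsd(data.frame(y = y, g = g), "y", "g")
  pw <- tk$pairwise
  extreme <- pw$p_adjusted[(pw$group_a == "urban" & pw$group_b == "rural") |
                           (pw$group_a == "rural" & pw$group_b == "urban")]
  expect_equal(min(pw$p_adjusted), extreme)

  expect_error(tukey_hsd(data.frame(y = 1:4, g = "a"), "y", "g"),
               "2 groups")
})

test_that("chi-square is Pearson without correction and permutation-invariant", {
  m <- matrix(c(20, 30, 25, 25, 30, 20), nrow = 2, byrow = TRUE)
  cs <- chi_square_table(m)
  expect_equal(cs$df, 2L)

  perm <- m[c(2, 1), c(3, 1, 2)]
  expect_equal(chi_square_table(perm)$statistic, cs$statistic,
               tolerance = 1e-12)

  # a table proportional to its margins has statistic 0
  outer_tab <- outer(c(10, 20), c(5, 15, 30)) / 10
  prop <- chi_square_table(outer_tab)
  expect_equal(prop$statistic, 0, tolerance = 1e-12)
  expect_equal(prop$p_value, 1)

  expect_error(chi_square_table(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("standardized regression has the analytic identities", {
  set.seed(606)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  tb <- data.frame(x1 = x1, x2 = x2, x3 = x3,
                   y1 = 2 + 3 * x1 + rnorm(n),
                   ysum = x1 + x2 + x3)

  # single predictor: beta equals the Pearson correlation
  r1 <- standardized_regression(tb, "y1", "x1")
  expect_equal(unname(r1$standardized_betas), cor(tb$y1, tb$x1),
               tolerance = 1e-12)

  # outcome an exact sum of predictors: R^2 = 1 (perfect-fit lm warning ok)
  rs <- suppressWarnings(
    standardized_regression(tb, "ysum", c("x1", "x2", "x3")))
  expect_equal(rs$r_squared, 1, tolerance = 1e-12)

  # betas invariant to affine rescaling of a predictor
  tb$x1_resc <- 100 * tb$x1 - 7
  ra <- standardized_regression(tb, "y1", c("x1", "x2"))
  rb <- standardized_regression(tb, "y1", c("x1_resc", "x2"))
  expect_equal(unname(sort(abs(ra$standardized_betas))),
               unname(sort(abs(rb$standardized_betas))), tolerance = 1e-12)

  tb$dup <- tb$x1
  expect_error(standardized_regression(tb, "y1", c("x1", "dup")),
               "collinear")
  expect_error(standardized_regression(tb[1:3, ], "y1",
                                       c("x1", "x2", "x3")), "n >")
})
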