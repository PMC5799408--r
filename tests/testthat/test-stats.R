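test_that("mixed ANOVA matches the aov projection oracle on 2x(2) designs", {
  for (s in 1:25) {
    d <- random_mixed_data(16, list(conc = c(4, 16)), seed = s)
    mine <- mixed_anova(d, "unit", "group", "conc", "y")
    orac <- oracle_mixed_anova(d, "unit", "group", "conc", "y")
    map <- c(group = ".b", conc = ".w1", "group:conc" = ".b:.w1")
    for (eff in names(map)) {
      row <- match_effect(mine, eff)
      expect_equal(row$SS, unname(orac[[map[eff]]]["SS"]), tolerance = 1e-8)
      expect_equal(row$df, unname(orac[[map[eff]]]["df"]))
      expect_equal(row$F, unname(orac[[map[eff]]]["F"]), tolerance = 1e-8)
    }
    # df of the sucrose design: F(1, 2n-2) = F(1, 30)
    expect_equal(match_effect(mine, "subjects-in-groups")$df, 30)
  }
})

test_that("mixed ANOVA matches the aov oracle on 2x(6x2) designs on cage means", {
  for (s in 1:25) {
    d <- random_mixed_data(8, list(day = paste0("d", 1:6),
                                   time = c("pre", "post")), seed = 1000 + s)
    mine <- mixed_anova(d, "unit", "group", c("day", "time"), "y")
    orac <- oracle_mixed_anova(d, "unit", "group", c("day", "time"), "y")
    map <- c(group = ".b", day = ".w1", time = ".w2",
             "group:day" = ".b:.w1", "group:time" = ".b:.w2",
             "day:time" = ".w1:.w2", "group:day:time" = ".b:.w1:.w2")
    for (eff in names(map)) {
      row <- match_effect(mine, eff)
      expect_equal(row$SS, unname(orac[[map[eff]]]["SS"]), tolerance = 1e-8)
      expect_equal(row$F, unname(orac[[map[eff]]]["F"]), tolerance = 1e-8)
    }
    expect_equal(match_effect(mine, "subjects-in-groups")$df, 14)
  }
})

test_that("ANOVA strata sum to the total SS and df sum to N - 1", {
  for (s in 1:10) {
    d <- random_mixed_data(6, list(day = paste0("d", 1:3),
                                   time = c("pre", "post")), seed = 2000 + s)
    tab <- mixed_anova(d, "unit", "group", c("day", "time"), "y")
    expect_equal(sum(tab$SS), attr(tab, "total_SS"), tolerance = 1e-8)
    expect_equal(sum(tab$df), attr(tab, "n_obs") - 1)
    expect_true(all(tab$SS >= -1e-12))
  }
})

test_that("F statistics are invariant under affine response transforms", {
  d <- random_mixed_data(10, list(conc = c(4, 16)), seed = 77)
  f0 <- mixed_anova(d, "unit", "group", "conc", "y")$F
  d$y <- -3.7 * d$y + 11
  f1 <- mixed_anova(d, "unit", "group", "conc", "y")$F
  expect_equal(f1, f0, tolerance = 1e-9)
})

test_that("with no within factor the ANOVA reduces to one-way, F = t^2", {
  set.seed(5)
  d <- data.frame(unit = sprintf("u%02d", 1:20),
                  group = rep(c("tail", "tunnel"), each = 10),
                  y = rnorm(20, rep(c(0, 1), each = 10)))
  a <- mixed_anova(d, "unit", "group", character(0), "y")
  t <- unpaired_t(d$y[d$group == "tail"], d$y[d$group == "tunnel"])
  expect_equal(match_effect(a, "group")$F, t$value^2, tolerance = 1e-10)
  expect_equal(match_effect(a, "group")$p, t$p, tolerance = 1e-10)
})

test_that("degenerate responses give zero F, and identical within-differences kill the interaction", {
  d <- expand.grid(unit = sprintf("u%d", 1:8), conc = c(4, 16),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("tail", "tunnel"), each = 4)[match(d$unit, sprintf("u%d", 1:8))]
  d$y <- 5
  tab <- mixed_anova(d, "unit", "group", "conc", "y")
  expect_true(all(tab$F[!is.na(tab$F)] == 0))

  # identical within-subject difference for every unit -> interaction F = 0
  set.seed(9)
  d$y <- rnorm(8)[match(d$unit, sprintf("u%d", 1:8))] + 2 * (d$conc == 16)
  tab <- mixed_anova(d, "unit", "group", "conc", "y")
  expect_equal(match_effect(tab, "group:conc")$F, 0)
})

test_that("unbalanced or incomplete designs are rejected with named cells", {
  d <- random_mixed_data(4, list(conc = c(4, 16)), seed = 3)
  expect_error(mixed_anova(d[d$unit != "u01", ], "unit", "group", "conc", "y"),
               "unbalanced")
  expect_error(mixed_anova(d[-1, ], "unit", "group", "conc", "y"),
               "u01")
})

test_that("log transform changes within-subject F only through genuine nonlinearity", {
  # multiplying all responses by a constant is a location shift after log:
  # every F involving the data's structure is unchanged
  d <- random_mixed_data(8, list(conc = c(4, 16)), seed = 12)
  d$y <- exp(d$y / 4)       # positive
  f0 <- mixed_anova(d, "unit", "group", "conc", "y", transform = "log")$F
  d2 <- d; d2$y <- 7.3 * d2$y
  f1 <- mixed_anova(d2, "unit", "group", "conc", "y", transform = "log")$F
  expect_equal(f1, f0, tolerance = 1e-9)

  expect_error(log_transform(c(1, 0, 2)), "positive")
  expect_error(log_transform(c(1, -2), units = c("m01", "m02")), "m02")
  expect_equal(log_transform(c(1, exp(1), exp(2))), c(0, 1, 2))
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  set.seed(31)
  d <- expand.grid(unit = sprintf("u%02d", 1:16), conc = c(4, 16),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("tail", "tunnel"), each = 8)[match(d$unit, sprintf("u%02d", 1:16))]
  d$y <- rnorm(nrow(d)) + (d$group == "tunnel") * (d$conc == 4) * 2

  fam2 <- bonferroni_pairwise(d, "unit", "y", list(
    list(factor = "group", levels = c("tunnel", "tail"), at = list(conc = 4)),
    list(factor = "group", levels = c("tunnel", "tail"), at = list(conc = 16))))
  expect_equal(fam2$adjusted_p, pmin(1, 2 * fam2$p))

  fam1 <- bonferroni_pairwise(d, "unit", "y", list(
    list(factor = "group", levels = c("tunnel", "tail"), at = list(conc = 4))))
  expect_equal(fam1$adjusted_p, fam1$p)
  expect_equal(fam1$t, fam2$t[1])

  # paired comparison path: within-subject contrast uses differences
  fam_w <- bonferroni_pairwise(d, "unit", "y", list(
    list(factor = "conc", levels = c("16", "4"), paired = TRUE)))
  diffs <- d$y[d$conc == 16][order(d$unit[d$conc == 16])] -
    d$y[d$conc == 4][order(d$unit[d$conc == 4])]
  expect_equal(fam_w$t, unname(t.test(diffs)$statistic), tolerance = 1e-10)

  expect_error(bonferroni_pairwise(d, "unit", "y", list()), "empty")
  expect_error(bonferroni_pairwise(d, "unit", "y", list(
    list(factor = "group", levels = c("tunnel", "cupped")))), "cupped")
})

test_that("Mann-Whitney U: identities, exact enumeration, and agreement with wilcox.test", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$value, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)   # 2/6 rank configurations

  for (s in 1:20) {
    set.seed(400 + s)
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
    r <- mann_whitney_u(x, y)
    expect_equal(r$U1 + r$U2, length(x) * length(y))
    w <- suppressWarnings(wilcox.test(x, y, exact = r$mode == "exact",
                                      correct = TRUE))
    expect_equal(r$U1, unname(w$statistic))
    expect_equal(r$p, w$p.value, tolerance = 1e-8)
  }

  # exact and normal paths agree closely at n1 = n2 = 10
  for (s in 1:10) {
    set.seed(500 + s)
    x <- rnorm(10); y <- rnorm(10)
    pe <- mann_whitney_u(x, y, mode = "exact")$p
    pn <- mann_whitney_u(x, y, mode = "normal_approx")$p
    expect_lt(abs(pe - pn), 0.02)
  }

  # paper-scale group sizes fall back to the normal approximation
  set.seed(6); r <- mann_whitney_u(rnorm(14), rnorm(15))
  expect_equal(r$mode, "normal_approx")
  expect_equal(unname(r$n), c(14, 15))

  # tie correction matches the reference implementation
  set.seed(7)
  x <- sample(1:4, 12, TRUE); y <- sample(2:6, 13, TRUE)
  r <- mann_whitney_u(x, y, mode = "normal_approx")
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p, w$p.value, tolerance = 1e-8)
})

test_that("pooled t test matches t.test and is antisymmetric", {
  set.seed(21)
  x <- rnorm(14); y <- rnorm(16, 1)
  r <- unpaired_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$value, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$df, 28)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  r2 <- unpaired_t(y, x)
  expect_equal(r2$value, -r$value)
  expect_equal(r2$p, r$p)

  expect_equal(unpaired_t(c(1, 2, 3), c(1, 3, 2))$value, 0)
  expect_error(unpaired_t(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("logistic slope equals the 2x2 log odds ratio and matches glm", {
  out <- binary_logistic(c(rep(1, 5), rep(0, 5), rep(1, 2), rep(0, 8)),
                         rep(c("A", "B"), each = 10))
  expect_equal(out$slope, log(4), tolerance = 1e-6)

  for (s in 1:10) {
    set.seed(600 + s)
    g <- rep(c("tail", "tunnel"), each = 15)
    y <- rbinom(30, 1, ifelse(g == "tail", 0.6, 0.3))
    tab <- table(g, y)
    if (any(tab == 0)) next
    r <- binary_logistic(y, g)
    lor <- log((tab["tail", "1"] / tab["tail", "0"]) /
                 (tab["tunnel", "1"] / tab["tunnel", "0"]))
    expect_equal(r$slope, lor, tolerance = 1e-6)
    ref <- glm(y ~ I(g == "tail"), family = binomial)
    expect_equal(r$slope, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(r$p, summary(ref)$coefficients[2, 4], tolerance = 1e-4)
  }

  # equal event rates -> zero slope; separation -> flag, no estimate
  expect_equal(binary_logistic(rep(c(1, 0), 10), rep(c("A", "B"), each = 10))$slope,
               0, tolerance = 1e-8)
  sep <- binary_logistic(c(rep(1, 5), rep(0, 5)), rep(c("A", "B"), each = 5))
  expect_true(sep$separation)
  expect_true(is.na(sep$value))
})

test_that("assumption checks warn but never change the analysis", {
  set.seed(88)
  vals <- c(rexp(20), rnorm(20, 4, 4))
  g <- rep(c("a", "b"), each = 20)
  res <- suppressWarnings(check_assumptions(vals, g))
  expect_named(res, c("shapiro", "levene_p"))
  expect_true(all(res$shapiro >= 0 & res$shapiro <= 1, na.rm = TRUE))
  expect_true(res$levene_p >= 0 && res$levene_p <= 1)
})
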