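# The group-statistics layer: ANOVA, post-hoc t-tests, Kruskal-Wallis,
# Dunn tests and the regression models.

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(10)
  tab <- data.frame(delta_neun = rnorm(24, c(0, 1.5)),
                    material = rep(c("PI", "Si"), 12))
  a <- factorial_anova(tab, "delta_neun", "material")
  tt <- t.test(delta_neun ~ material, tab, var.equal = TRUE)
  expect_equal(a$value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_raw, tt$p.value, tolerance = 1e-10)

  # degenerate constant response handled
  tab$delta_neun <- 3
  d <- factorial_anova(tab, "delta_neun", "material")
  expect_equal(d$value, 0); expect_equal(d$p_raw, 1)
})

test_that("factorial ANOVA reports type-II main effects and interactions", {
  set.seed(11)
  tab <- expand.grid(material = c("PI", "Si"), tether = c("T", "U"),
                     rep = 1:8)
  tab$delta_neun <- rnorm(nrow(tab)) + 2 * (tab$material == "Si")
  a <- factorial_anova(tab, "delta_neun", c("material", "tether"))
  expect_setequal(a$comparison, c("material", "tether", "material:tether"))
  expect_lt(a$p_raw[a$comparison == "material"], 0.01)

  # unbalanced design still fits; empty interaction cell drops interactions
  tab2 <- tab[!(tab$material == "Si" & tab$tether == "U"), ]
  expect_warning(a2 <- factorial_anova(tab2, "delta_neun",
                                       c("material", "tether")),
                 "empty design cells")
  expect_false("material:tether" %in% a2$comparison)

  # single-level factors are dropped with a message
  expect_message(
    a3 <- factorial_anova(tab[tab$tether == "T", ], "delta_neun",
                          c("material", "tether")),
    "single-level")
  expect_equal(a3$comparison, "material")
})

test_that("post-hoc t-tests apply the Bonferroni correction", {
  set.seed(12)
  tab <- data.frame(v = rnorm(30, rep(c(0, 0, 3), each = 10)),
                    g = rep(c("a", "b", "c"), each = 10))
  res <- posthoc_ttests(tab, "v", "g")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3))

  # m = 1: adjusted equals raw
  res1 <- posthoc_ttests(tab[tab$g != "c", ], "v", "g")
  expect_equal(res1$p_adj, res1$p_raw)

  # identical groups: t = 0, p = 1
  tid <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  rid <- posthoc_ttests(tid, "v", "g")
  expect_equal(rid$value, 0)
  expect_equal(rid$p_raw, 1)
})

test_that("Kruskal-Wallis matches the explicit rank-sum computation", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$value, 27 / 7, tolerance = 1e-12)  # 3.857...
  expect_equal(kw$value, oracle_kw_h(c(1:6), rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)

  # all tied: H = 0, p = 1
  kw0 <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(kw0$value, 0); expect_equal(kw0$p_raw, 1)

  # invariant under monotone transformation
  set.seed(13)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(v, g)$value,
               kruskal_wallis(exp(v), g)$value, tolerance = 1e-12)
})

test_that("Dunn z matches the hand computation and is antisymmetric", {
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- dunn_test(v, g)
  # mean ranks 2, 5, 8; N = 9; no ties: z_ac = -6 / sqrt(7.5 * 2/3)
  z_ac <- res$value[res$comparison == "a vs c"]
  expect_equal(z_ac, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(res$value, oracle_dunn_z(v, g), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3))

  # two identical groups: z = 0
  expect_equal(dunn_test(rep(1:3, 2), rep(c("a", "b"), each = 3))$value, 0)

  # relabeling the groups flips the sign
  g2 <- rep(c("c", "b", "a"), each = 3)
  res2 <- dunn_test(v, g2)
  expect_equal(res2$value[res2$comparison == "a vs c"], 6 / sqrt(5),
               tolerance = 1e-12)

  expect_warning(dunn_test(c(1, 2, 3), c("a", "b", "b")), "singleton")
})

test_that("rank tests agree with oracles on exhaustive small inputs", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    v <- sample(1:4, n, replace = TRUE)          # ties guaranteed possible
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(v)) < 2) next
    if (min(tabulate(factor(g))) < 1) next
    expect_equal(kruskal_wallis(v, g)$value, oracle_kw_h(v, g),
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(dunn_test(v, g)$value),
                 oracle_dunn_z(v, g), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("cross-section regression recovers exact and noisy slopes", {
  grid <- expand.grid(material = c("PI", "Si"), tether = c("T", "U"),
                      region = c("upper_cortex", "lower_cortex"),
                      cross_section_um2 = c(525, 1050, 2625), rep = 1:3)
  # exact linear index: slope recovered to machine precision
  grid$idx_tissue_reaction <- 0.2 + 0.0001 * grid$cross_section_um2
  res <- suppressWarnings(cross_section_regression(grid))  # perfect fit
  est <- res$estimate[res$comparison == "cross_section_um2"]
  expect_equal(est, 0.0001, tolerance = 1e-10)

  # constant index: all slopes zero
  grid$idx_tissue_reaction <- 0.3
  res0 <- suppressWarnings(cross_section_regression(grid))
  expect_true(all(abs(res0$estimate[-1]) < 1e-12))

  # white-matter rows are excluded from the fit
  wm <- grid; wm$region <- "white_matter"; wm$idx_tissue_reaction <- 99
  resw <- suppressWarnings(cross_section_regression(rbind(grid, wm)))
  expect_equal(attr(resw, "fit")$df.residual,
               attr(res0, "fit")$df.residual)

  # unbiased recovery under noise
  set.seed(15)
  bias <- replicate(100, {
    g <- grid
    g$idx_tissue_reaction <- 0.2 + 5e-5 * g$cross_section_um2 +
      rnorm(nrow(g), 0, 0.05)
    r <- cross_section_regression(g)
    r$estimate[r$comparison == "cross_section_um2"] - 5e-5
  })
  se <- sd(bias) / sqrt(length(bias))
  expect_lt(abs(mean(bias)), 3 * se + 1e-9)
})

test_that("useful-fraction trend fits per-material slopes", {
  tab <- data.frame(material = rep(c("PI", "Si"), each = 24),
                    week = rep(1:24, 2))
  tab$pct_useful <- ifelse(tab$material == "PI", 80 - 2 * tab$week, 50)
  tr <- suppressWarnings(useful_fraction_trend(tab))  # exact lines
  expect_equal(tr$estimate[tr$material == "PI"], -2, tolerance = 1e-10)
  expect_equal(tr$estimate[tr$material == "Si"], 0, tolerance = 1e-10)
  expect_error(useful_fraction_trend(tab[tab$week < 3, ]), "3 time points")
})
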