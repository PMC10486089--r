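# Frozen oracle values for the published 2x2 cells (741, 154, 66, 679),
# n = 1640, computed with agreement_oracle (direct textbook formulas):
#   p_o = 1420/1640 = 0.8658537, p_e = 1342850/1640^2 = 0.4992752,
#   kappa = 0.7320958, Ppos = 1482/1702 = 0.8707403,
#   Pneg = 1358/1578 = 0.8605830

test_that("tables are built with pairwise deletion and weighted cells", {
  tab <- build_table(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                     c(TRUE, FALSE, FALSE, NA, TRUE))
  expect_equal(tab$n_actual, 4)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 0, 1))
  expect_equal(tab$p_a, 0.5)  # unit weights: proportions are counts/n

  wt <- build_table(c(TRUE, FALSE), c(TRUE, FALSE), weights = c(3, 1))
  expect_equal(wt$p_a, 0.75)
  expect_equal(wt$n_actual, 2)

  expect_error(build_table(c(TRUE, NA), c(TRUE, TRUE)), "complete")
  expect_error(build_table(TRUE, NA), "empty")
  expect_error(suppressWarnings(build_table(logical(0), logical(0))))
})

test_that("overall agreement matches the closed form with a clipped CI", {
  perfect <- table_from_counts(5, 0, 0, 5)
  oa <- overall_agreement(perfect)
  expect_equal(oa$estimate, 1)
  expect_lte(oa$upper, 1)

  none <- table_from_counts(0, 3, 7, 0)
  expect_equal(overall_agreement(none)$estimate, 0)
  expect_gte(overall_agreement(none)$lower, 0)

  pub <- table_from_counts(741, 154, 66, 679)
  oa2 <- overall_agreement(pub)
  expect_equal(oa2$estimate, 1420 / 1640, tolerance = 1e-12)
  expect_equal(oa2$estimate, 0.8658537, tolerance = 1e-6)
})

test_that("kappa matches hand evaluation and an independent library", {
  pub <- table_from_counts(741, 154, 66, 679)
  k <- cohen_kappa(pub)
  oracle <- agreement_oracle(741, 154, 66, 679)
  expect_equal(k$estimate, oracle$kappa, tolerance = 1e-12)
  expect_equal(oracle$p_o, 0.8658537, tolerance = 1e-6)
  expect_equal(oracle$p_e, 0.4992752, tolerance = 1e-6)
  expect_equal(k$estimate, 0.7320958, tolerance = 1e-6)
  expect_true(k$lower < k$estimate && k$estimate < k$upper)

  skip_if_not_installed("e1071")
  m <- matrix(c(741, 154, 66, 679), 2, byrow = TRUE)
  expect_equal(k$estimate, e1071::classAgreement(m)$kappa,
               tolerance = 1e-10)
})

test_that("kappa closed forms hold exactly", {
  # perfect agreement with mixed margins
  expect_equal(cohen_kappa(table_from_counts(4, 0, 0, 6))$estimate, 1)
  # independence: cells proportional to margin products
  ind <- table_from_counts(12, 28, 18, 42)  # margins (0.4,0.6)x(0.3,0.7)
  expect_equal(cohen_kappa(ind)$estimate, 0, tolerance = 1e-12)
  # degenerate margins are an error, not a number
  expect_error(cohen_kappa(table_from_counts(10, 0, 0, 0)), "degenerate")
})

test_that("positive and negative agreement match their formulas", {
  pub <- table_from_counts(741, 154, 66, 679)
  pn <- pos_neg_agreement(pub)
  expect_equal(pn$Ppos$estimate, 1482 / 1702, tolerance = 1e-12)
  expect_equal(pn$Pneg$estimate, 1358 / 1578, tolerance = 1e-12)
  expect_equal(pn$Ppos$estimate, 0.8707403, tolerance = 1e-6)
  expect_equal(pn$Pneg$estimate, 0.8605830, tolerance = 1e-6)

  both <- pos_neg_agreement(table_from_counts(3, 0, 0, 7))
  expect_equal(both$Ppos$estimate, 1)
  expect_equal(both$Pneg$estimate, 1)
  expect_equal(pos_neg_agreement(table_from_counts(0, 2, 3, 5))$Ppos$estimate,
               0)
  # concordant-positive-only table: Pneg has denominator zero
  allpos <- pos_neg_agreement(table_from_counts(5, 0, 0, 0))
  expect_equal(allpos$Ppos$estimate, 1)
  expect_true(is.na(allpos$Pneg$estimate))
})

test_that("agreement statistics are invariant to swapping the two sources", {
  set.seed(13)
  for (i in 1:40) {
    tab <- random_agreement_table()
    tr <- table_from_counts(tab$a, tab$c, tab$b, tab$d)  # transpose b<->c
    expect_equal(cohen_kappa(tab)$estimate, cohen_kappa(tr)$estimate,
                 tolerance = 1e-12)
    expect_equal(overall_agreement(tab)$estimate,
                 overall_agreement(tr)$estimate, tolerance = 1e-12)
    pn <- pos_neg_agreement(tab); pnt <- pos_neg_agreement(tr)
    expect_equal(pn$Ppos$estimate, pnt$Ppos$estimate, tolerance = 1e-12)
    expect_equal(pn$Pneg$estimate, pnt$Pneg$estimate, tolerance = 1e-12)
    # kappa never exceeds observed agreement
    expect_lte(cohen_kappa(tab)$estimate,
               overall_agreement(tab)$estimate + 1e-12)
  }
})

test_that("equal weights reproduce the unweighted statistics", {
  set.seed(29)
  admin <- runif(300) < 0.45
  self <- ifelse(runif(300) < 0.8, admin, !admin)
  self[sample(300, 5)] <- NA
  w_const <- rep(3.7, 300)
  t1 <- build_table(admin, self)
  t2 <- build_table(admin, self, w_const)
  expect_equal(cohen_kappa(t1)$estimate, cohen_kappa(t2)$estimate)
  expect_equal(overall_agreement(t1)$estimate,
               overall_agreement(t2)$estimate)
})

test_that("kappa bands follow the conventional cut points", {
  expect_equal(kappa_band(0.63), "good")
  expect_equal(kappa_band(0.40), "moderate")
  expect_equal(kappa_band(-0.5), "poor")
  expect_equal(kappa_band(c(0.19, 0.20, 0.59, 0.60, 0.79, 0.80, 1)),
               c("poor", "fair", "moderate", "good", "good", "very good",
                 "very good"))
  expect_error(kappa_band(1.2))
})

test_that("bootstrap intervals bracket the point estimates", {
  set.seed(91)
  admin <- runif(150) < 0.5
  self <- ifelse(runif(150) < 0.85, admin, !admin)
  bt <- agreement_boot(admin, self, R = 200, seed = 1)
  tab <- build_table(admin, self)
  expect_equal(bt$kappa$estimate, cohen_kappa(tab)$estimate,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lte(bt$kappa$lower, bt$kappa$estimate)
  expect_gte(bt$kappa$upper, bt$kappa$estimate)
})

test_that("the agreement grid covers every algorithm and self item", {
  set.seed(3)
  n <- 200
  admin <- list(k1 = runif(n) < 0.3, k30 = runif(n) < 0.5)
  sr <- tibble::tibble(
    ever_asthma = ifelse(runif(n) < 0.9, admin$k30, !admin$k30),
    physician_diagnosed = ifelse(runif(n) < 0.85, admin$k30, !admin$k30))
  grid <- agreement_summary(admin, sr)
  expect_equal(nrow(grid), 4)  # 2 algorithms x 2 items
  expect_setequal(unique(grid$algorithm), c("k1", "k30"))
  expect_true(all(grid$kappa <= grid$agreement_pct / 100 + 1e-12))
})
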