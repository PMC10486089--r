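test_that("the agreement outcome is concordance with pairwise exclusion", {
  expect_identical(agreement_outcome(c(TRUE, TRUE, FALSE, FALSE),
                                     c(TRUE, FALSE, TRUE, FALSE)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_true(is.na(agreement_outcome(TRUE, NA)))
  expect_error(agreement_outcome(NA, TRUE), "complete")
})

test_that("intercept-only weighted fit equals the weighted logit closed form", {
  set.seed(17)
  d <- data.frame(y = runif(400) < 0.3)
  w <- runif(400, 0.5, 20)
  fit <- fit_weighted_logistic(y ~ 1, d, w)
  p_w <- sum(w * d$y) / sum(w)
  expect_equal(unname(fit$coef[1]), qlogis(p_w), tolerance = 1e-8)
})

test_that("weights enter as design weights: scale invariance and equality", {
  set.seed(19)
  d <- data.frame(x = rnorm(300), g = sample(c("u", "v"), 300, TRUE))
  d$y <- runif(300) < plogis(-0.3 + 0.8 * d$x)
  w <- runif(300, 1, 10)
  f1 <- fit_weighted_logistic(y ~ x + g, d, w)
  f2 <- fit_weighted_logistic(y ~ x + g, d, w * 7.3)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  # unit weights reduce to the ordinary ML fit
  f3 <- fit_weighted_logistic(y ~ x + g, d)
  ml <- glm(y ~ x + g, binomial(), d)
  expect_equal(unname(f3$coef), unname(coef(ml)), tolerance = 1e-8)
  expect_true(all(diag(f3$vcov) >= 0))
})

test_that("sandwich covariance equals hand-computed B^-1 M B^-1", {
  set.seed(31)
  n <- 250
  d <- data.frame(x = rnorm(n))
  d$y <- runif(n) < plogis(0.2 + 0.6 * d$x)
  w <- runif(n, 1, 15)
  fit <- fit_weighted_logistic(y ~ x, d, w)
  X <- cbind(1, d$x)
  mu <- plogis(drop(X %*% fit$coef))
  B <- t(X) %*% (w * mu * (1 - mu) * X)
  score <- (w * (d$y - mu)) * X
  M <- t(score) %*% score
  V <- solve(B) %*% M %*% solve(B)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-6)
})

test_that("a known odds ratio is recovered in simulation", {
  set.seed(37)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  y <- runif(n) < plogis(-1 + log(2) * x)
  fit <- fit_weighted_logistic(y ~ x, data.frame(x = x, y = y))
  expect_equal(fit$or_table$or[2], 2, tolerance = 0.15)
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(y = c(TRUE, FALSE, TRUE, FALSE),
                  x = c(1, 2, 3, 4))
  d$z <- d$x * 2  # aliased
  expect_error(fit_weighted_logistic(y ~ x + z, d), "aliased.*z")
  # complete separation
  sep <- data.frame(y = rep(c(TRUE, FALSE), each = 30),
                    x = rep(c(1, 0), each = 30))
  expect_error(suppressWarnings(fit_weighted_logistic(y ~ x, sep)),
               "separation")
})

test_that("multi-df Wald tests collapse to the z-test for one column", {
  set.seed(41)
  d <- data.frame(x = rnorm(200))
  d$y <- runif(200) < plogis(0.4 * d$x)
  fit <- fit_weighted_logistic(y ~ x, d)
  expect_equal(fit$term_tests$p[1], fit$or_table$p[2], tolerance = 1e-10)
  expect_equal(fit$term_tests$df[1], 1)
})

test_that("purposeful selection keeps strong signals and drops noise", {
  set.seed(43)
  n <- 900
  d <- data.frame(strong = sample(c("no", "yes"), n, TRUE))
  for (j in 1:4) d[[paste0("null", j)]] <- sample(c("a", "b", "c"), n, TRUE)
  d$y <- runif(n) < plogis(-0.5 + 1.2 * (d$strong == "yes"))
  sel <- purposeful_selection(d, "y", c("strong", paste0("null", 1:4)))
  expect_true(sel$trace$retained[sel$trace$variable == "strong"])
  expect_true(all(sel$trace$entered[sel$trace$retained]))
  expect_true(all(is.na(sel$trace$multivariable_p[!sel$trace$entered])))
  expect_s3_class(sel$final, "weighted_logit")
  expect_true("strong" %in% all.vars(sel$final$formula))
})

test_that("selection falls back to intercept-only when nothing passes", {
  set.seed(47)
  n <- 400
  d <- data.frame(y = runif(n) < 0.5,
                  n1 = sample(c("a", "b"), n, TRUE))
  # force a high univariable p by using pure noise and a tight threshold
  expect_warning(
    sel <- purposeful_selection(d, "y", "n1", threshold = 1e-6),
    "intercept-only")
  expect_equal(length(sel$final$coef), 1)
})

test_that("the imputer fills only missing values from observed categories", {
  set.seed(53)
  n <- 300
  d <- data.frame(y = runif(n) < 0.5,
                  stratum = sample(c("s1", "s2"), n, TRUE),
                  v = sample(c("a", "b", "c"), n, TRUE))
  d$v[sample(n, 40)] <- NA
  obs <- d$v
  out <- impute_categorical(d, "v", "y", "stratum")
  expect_false(anyNA(out$v))
  expect_identical(out$v[!is.na(obs)], obs[!is.na(obs)])
  expect_true(all(out$v %in% c("a", "b", "c")))
  d$all_na <- NA_character_
  expect_error(impute_categorical(d, "all_na", "y", "stratum"),
               "100% missing")
})

test_that("Rubin pooling is exact in its degenerate cases", {
  set.seed(59)
  n <- 400
  d <- data.frame(y = runif(n) < 0.4,
                  stratum = sample(c("s1", "s2"), n, TRUE),
                  v = sample(c("lo", "hi"), n, TRUE))
  w <- runif(n, 1, 5)
  single <- fit_weighted_logistic(y ~ v, d, w)
  # no missing data: pooled fit equals the single fit exactly
  pooled <- impute_and_pool(d, y ~ v, w, "stratum", m = 5, seed = 2)
  expect_equal(pooled$coef, single$coef, tolerance = 1e-12)
  expect_equal(unname(pooled$vcov), unname(single$vcov), tolerance = 1e-12)
  # m = 1: pooled is that one imputation's fit
  d2 <- d
  d2$v[1:30] <- NA
  p1 <- impute_and_pool(d2, y ~ v, w, "stratum", m = 1, seed = 3)
  set.seed(3)
  completed <- impute_categorical(d2, "v", "y", "stratum", w)
  ref <- fit_weighted_logistic(y ~ v, completed, w)
  expect_equal(p1$coef, ref$coef, tolerance = 1e-12)
})

test_that("pooled variance is at least the mean within-imputation variance", {
  set.seed(61)
  n <- 500
  d <- data.frame(y = runif(n) < 0.5,
                  stratum = sample(c("s1", "s2"), n, TRUE),
                  v = sample(c("a", "b"), n, TRUE))
  d$v[sample(n, 100)] <- NA
  pooled <- impute_and_pool(d, y ~ v, stratum = "stratum", m = 8, seed = 4)
  expect_true(all(diag(pooled$vcov) >= diag(pooled$within) - 1e-12))
  expect_true(all(diag(pooled$between) >= 0))
})
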