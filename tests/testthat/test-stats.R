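test_that("the measurement table loads with its documented conventions", {
  d <- load_table4()
  expect_equal(nrow(d), 35)
  expect_equal(d$mbr[d$image == 1], -20.1)
  expect_equal(d$novice_t1[d$image == 28], 22.4)
  # "no scoliosis" rows carry angle 0 and the flag
  expect_equal(d$expert_t1[d$image == 15], 0)
  expect_equal(d$expert_no_scoliosis[d$image == 15], 1)
  expect_equal(sum(d$expert_no_scoliosis), 2)
})

test_that("descriptives use the population standard deviation", {
  d <- descriptive(c(-1, 1))
  expect_equal(d$mean, 0)
  expect_equal(d$sd, 1)     # n denominator
  expect_equal(descriptive(rep(4, 5))$sd, 0)
  expect_error(descriptive(3), "at least 2")
})

test_that("Pearson correlation handles exact linear relations", {
  x <- c(1, 3, 4, 8)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(2, 4)), "zero variance")
  expect_error(pearson_r(x, x[1:3]), "length mismatch")
})

test_that("Spearman follows the rank-difference formula", {
  expect_equal(spearman_rho(1:6, (1:6)^3), 1)   # monotone -> 1
  expect_equal(spearman_rho(1:6, -(1:6)), -1)
  # n = 3, ranks (1,2,3) vs (2,1,3): 1 - 6*2/(3*8) = 0.5
  expect_equal(spearman_rho(c(10, 20, 30), c(25, 15, 35)), 0.5)
  # with ties, equals Pearson-of-ranks, which matches stats::cor
  set.seed(6)
  x <- sample(1:5, 20, replace = TRUE)
  y <- x + sample(0:2, 20, replace = TRUE)
  expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"))
  # untied case also matches the reference implementation
  a <- stats::runif(15); b <- stats::runif(15)
  expect_equal(spearman_rho(a, b), stats::cor(a, b, method = "spearman"),
               tolerance = 1e-12)
})

test_that("one-way ANOVA matches its classical identities", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- one_way_anova(same)
  expect_equal(r$F, 0)
  # two groups: F equals the squared equal-variance t statistic
  set.seed(13)
  g1 <- stats::rnorm(12); g2 <- stats::rnorm(15, 0.5)
  r2 <- one_way_anova(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_error(one_way_anova(list(g1)), "at least 2 groups")
})

test_that("ICC behaves as an absolute-agreement coefficient", {
  set.seed(21)
  x <- stats::rnorm(30, 10, 3)
  expect_equal(icc(cbind(x, x)), 1)
  # large independent noise drives agreement towards zero
  noisy <- cbind(x, x + stats::rnorm(30, 0, 30))
  expect_lt(abs(icc(noisy)), 0.1 + 0.1)
  # invariant under adding a constant to both raters
  m <- cbind(x, x + stats::rnorm(30, 0, 1))
  expect_equal(icc(m), icc(m + 5), tolerance = 1e-12)
  # NOT invariant under scaling one rater (absolute agreement)
  ms <- cbind(x, 2 * x)
  expect_gt(abs(icc(ms) - icc(cbind(x, x))), 0.05)
  # consistency form tolerates a constant offset better
  off <- cbind(x, x + 10)
  expect_equal(icc(off, form = "ICC(3,1)"), 1, tolerance = 1e-9)
  expect_lt(icc(off, form = "ICC(2,1)"), 1)
  expect_error(icc(cbind(x[1:2], x[1:2])), "at least 3 subjects")
})

test_that("ICC bands follow the rating scale", {
  expect_equal(classify_icc(0.30), "poor")
  expect_equal(classify_icc(0.50), "fair")
  expect_equal(classify_icc(0.65), "good")
  expect_equal(classify_icc(0.80), "excellent")
  expect_error(classify_icc(1.2))
})

test_that("the agreement report assembles all statistics coherently", {
  d <- load_table4()
  rep1 <- agreement_report(d, session = 1)
  expect_equal(names(rep1$groups), c("expert", "novice", "mbr"))
  expect_equal(nrow(rep1$pairs), 3)
  expect_true(all(abs(rep1$pairs$pearson) <= 1))
  expect_true(all(rep1$pairs$icc_band == "excellent"))
  rep2 <- agreement_report(d, session = 2)
  expect_false(identical(rep1$groups$expert$mean,
                         rep2$groups$expert$mean))
})
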