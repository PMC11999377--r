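test_that("Spearman correlation reproduces hand-ranked cases", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  # d = (0,1,-1,0): rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(out <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Spearman correlation is invariant under strictly monotone transforms", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- x + rnorm(30, 0, 0.5)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r)
    expect_equal(spearman_rho(x, y^3), r)
    expect_equal(spearman_rho(-x, y), -r)
  }
})

test_that("g1 and g2 reproduce direct moment arithmetic", {
  # symmetric sample: zero skewness
  expect_equal(skewness_g1(c(-2, -1, 0, 1, 2)), 0)
  # {0,0,0,1}: m2 = 3/16, m3 = 3/32 -> g1 = 2/sqrt(3)
  expect_equal(skewness_g1(c(0, 0, 0, 1)), 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(skewness_g1(c(0, 0, 0, 1)), 1.1547, tolerance = 1e-4)
  # direct oracle on a random sample
  set.seed(42)
  x <- rexp(500)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3); m4 <- mean((x - mean(x))^4)
  expect_equal(skewness_g1(x), m3 / m2^1.5)
  expect_equal(kurtosis_g2(x), m4 / m2^2)
  expect_error(skewness_g1(rep(1, 10)), "variance")
  expect_error(kurtosis_g2(1:2), "at least 3")
})

test_that("g1 and g2 match the classic biased-moment definitions in e1071", {
  set.seed(43)
  x <- rgamma(200, 2)
  expect_equal(skewness_g1(x), e1071::skewness(x, type = 1))
  expect_equal(kurtosis_g2(x), e1071::kurtosis(x, type = 1) + 3)
})

test_that("g1 flips sign under negation; g2 is affine invariant and at least 1", {
  set.seed(44)
  for (i in 1:10) {
    x <- rlnorm(50)
    expect_equal(skewness_g1(-x), -skewness_g1(x))
    expect_equal(kurtosis_g2(3 - 2 * x), kurtosis_g2(x), tolerance = 1e-9)
    expect_gte(kurtosis_g2(x), 1)
  }
})

test_that("the Shapiro-Wilk wrapper enforces its n range and detects skew", {
  expect_error(normality_test(c(1, 2)), "between 3 and 5000")
  expect_error(normality_test(rnorm(5001)), "between 3 and 5000")
  # power against a right-skewed alternative: reject in >= 80% of runs
  rej <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    normality_test(rexp(100))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
  # approximate level under the null
  rej0 <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    normality_test(rnorm(80))$p < 0.05
  }, logical(1))
  expect_lte(mean(rej0), 0.10)
})

test_that("Kruskal-Wallis H matches the hand rank formula on toy groups", {
  vals <- c(1.2, 3.4, 2.1, 5.6, 7.1, 4.3)   # three groups of two, no ties
  grp <- c("FIM1-4", "FIM1-4", "FIM5-WC", "FIM5-WC", "FIM7", "FIM7")
  summ <- data.frame(subgroup = factor(grp, levels = subgroup_levels()),
                     daily_msda = vals)
  res <- subgroup_comparison(summ, "msda")
  r <- rank(vals)
  N <- 6
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  expect_equal(res$H, H, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj <= 1))
  expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p_raw * 3))
})

test_that("a large location shift is flagged after Bonferroni adjustment", {
  set.seed(46)
  summ <- data.frame(
    subgroup = factor(rep(c("FIM1-4", "FIM7"), each = 20),
                      levels = subgroup_levels()),
    daily_steps = c(rnorm(20, 0, 1), rnorm(20, 8, 1)))
  res <- subgroup_comparison(summ, "steps")
  expect_lt(res$pairwise$p_adj[1], 0.05)
  expect_lt(res$p, 0.05)
  expect_equal(unname(res$medians["FIM7"] > res$medians["FIM1-4"]), TRUE)
})

test_that("floor-effect metric counts exact zeros", {
  fe <- floor_effect(c(rep(0, 20), seq_len(177)))
  expect_equal(fe$n_zero, 20)
  expect_equal(fe$percent, 10.2)
  expect_equal(floor_effect(1:5)$percent, 0)
  expect_equal(floor_effect(rep(0, 8))$percent, 100)
  expect_equal(floor_effect(c(1e-12, 1))$n_zero, 0)  # no epsilon
})

test_that("build_report assembles correlations, diagnostics and comparisons", {
  set.seed(47)
  n_per <- c(10, 8, 8, 8, 8, 9)
  lvl <- subgroup_levels()
  rows <- do.call(rbind, lapply(seq_along(lvl), function(i) {
    act <- 0.004 + 0.002 * i + rnorm(n_per[i], 0, 0.001)
    steps <- pmax(1, round(400 * i + 300 * scale(act)[, 1] + rnorm(n_per[i], 0, 150)))
    data.frame(subgroup = lvl[i],
               mobility_mode = if (grepl("WC|1-4", lvl[i])) "wheelchair" else "walking",
               daily_msda = act, daily_steps = steps, retained = TRUE)
  }))
  rows$daily_steps[1:2] <- 0  # a floor in the weakest subgroup
  rep <- build_report(rows)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep$correlations), 3)
  expect_equal(rep$correlations$stratum, c("all", "walking", "wheelchair"))
  expect_equal(nrow(rep$comparisons$msda$pairwise), 15)
  expect_equal(nrow(rep$diagnostics), (6 + 3) * 2)
  expect_equal(rep$floor$n_zero, 2)
  expect_true(all(abs(rep$correlations$rho) <= 1, na.rm = TRUE))
  # excluded subjects are dropped before analysis
  rows2 <- rows
  rows2$retained[1] <- FALSE
  rep2 <- build_report(rows2)
  expect_equal(rep2$n, nrow(rows) - 1)
  expect_equal(rep2$n_excluded, 1)
})
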