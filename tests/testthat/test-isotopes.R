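test_that("delta notation behaves as arithmetic demands", {
  expect_equal(delta_value(0.0036765, 0.0036765), 0)
  expect_equal(delta_value(1.001 * 0.0112372, 0.0112372), 1.0, tolerance = 1e-9)
  expect_error(delta_value(0, 0.011), "positive")
})

test_that("reference discriminant functions assign the class means correctly", {
  s8 <- reference_discriminant_functions("S8")
  sc <- discriminant_scores(s8, ref_means$S8[, 1], ref_means$S8[, 2])
  # Central means score higher under the Central function, by +2.10
  expect_equal(sc[1, "CentralAtlantic"] - sc[1, "SouthAtlantic"], 2.10,
               tolerance = 1e-9)
  expect_gt(sc[2, "SouthAtlantic"], sc[2, "CentralAtlantic"])
  r6 <- reference_discriminant_functions("R6")
  sc6 <- discriminant_scores(r6, ref_means$R6[, 1], ref_means$R6[, 2])
  expect_gt(sc6[1, "CentralAtlantic"], sc6[1, "SouthAtlantic"])
  expect_equal(sc6[2, "CentralAtlantic"], 717.40, tolerance = 1e-9)
  expect_equal(sc6[2, "SouthAtlantic"], 721.24, tolerance = 1e-9)
})

test_that("fitted classification functions reproduce their algebraic form", {
  set.seed(1)
  n <- 60
  d <- data.frame(
    area = rep(c("A", "B"), each = n),
    d15N = c(rnorm(n, 13.1, 0.8), rnorm(n, 14.6, 1.3)),
    d13C = c(rnorm(n, -16.3, 0.3), rnorm(n, -16.8, 0.3)))
  m <- fit_lda(d, label_by = "area")
  # coefficient identity: a_g = S^-1 mu_g, c_g = -mu'S^-1mu/2 + log prior
  Sinv <- solve(m$pooled_cov)
  for (g in 1:2) {
    expect_equal(unname(m$coef[g, 1:2]), unname(drop(Sinv %*% m$means[g, ])),
                 tolerance = 1e-10)
    expect_equal(unname(m$coef[g, 3]),
                 -0.5 * drop(t(m$means[g, ]) %*% Sinv %*% m$means[g, ]) +
                   log(0.5), tolerance = 1e-10)
  }
  # assignments agree with the standard reference implementation
  ref <- MASS::lda(d[, c("d15N", "d13C")], grouping = factor(d$area),
                   prior = c(0.5, 0.5))
  expect_equal(predict(m, d),
               as.character(predict(ref, d[, c("d15N", "d13C")])$class))
})

test_that("equal-prior assignment is invariant to shifting both functions", {
  set.seed(2)
  d <- data.frame(area = rep(c("A", "B"), each = 20),
                  d15N = rnorm(40, rep(c(13, 15), each = 20), 1),
                  d13C = rnorm(40, rep(c(-16, -17), each = 20), 0.4))
  m <- fit_lda(d)
  m2 <- m
  m2$coef[, "constant"] <- m2$coef[, "constant"] + 123.45
  expect_identical(predict(m, d), predict(m2, d))
})

test_that("identical class means give tied scores and a warned tie-break", {
  d <- data.frame(area = rep(c("A", "B"), each = 5),
                  d15N = rep(c(1, 2, 3, 4, 5), 2),
                  d13C = rep(c(5, 2, 4, 1, 3), 2))
  m <- fit_lda(d)
  expect_warning(out <- predict(m, d[1, ]), "tie")
  expect_equal(out, "A")
})

test_that("fitted boundary agrees with the published S8 boundary on a grid", {
  # The published functions encode the study's pooled within-class
  # covariance: from a_C - a_S = S^-1 (mu_C - mu_S) with the published
  # coefficients and class means, S (hence the d15N-d13C correlation)
  # follows by linear algebra. Recover it as the generating covariance.
  ref <- reference_discriminant_functions("S8")
  a_diff <- ref["CentralAtlantic", 1:2] - ref["SouthAtlantic", 1:2]
  mu_diff <- ref_means$S8["CentralAtlantic", ] - ref_means$S8["SouthAtlantic", ]
  # S %*% a_diff = mu_diff, with pooled variances from the published SDs
  s11 <- (38 * 0.8^2 + 20 * 1.3^2) / 58
  s12 <- (mu_diff[1] - a_diff[1] * s11) / a_diff[2]
  s22 <- (mu_diff[2] - a_diff[1] * s12) / a_diff[2]
  S <- matrix(c(s11, s12, s12, s22), 2)
  expect_gt(s22, 0)
  expect_lt(s12, 0)  # the printed functions imply a negative correlation

  set.seed(3)
  n <- 2000
  d <- data.frame(
    area = rep(c("CentralAtlantic", "SouthAtlantic"), each = n),
    rbind(MASS::mvrnorm(n, ref_means$S8[1, ], S, empirical = TRUE),
          MASS::mvrnorm(n, ref_means$S8[2, ], S, empirical = TRUE)))
  names(d)[2:3] <- c("d15N", "d13C")
  m <- fit_lda(d)
  grid <- expand.grid(d15N = seq(11, 17, length.out = 40),
                      d13C = seq(-18, -15, length.out = 40))
  fit_lab <- predict(m, grid)
  sc <- discriminant_scores(ref, grid$d15N, grid$d13C)
  ref_lab <- colnames(sc)[max.col(sc, ties.method = "first")]
  expect_gte(mean(fit_lab == ref_lab), 0.90)

  # with the (unreported) correlation set to 0 the boundary tilts and grid
  # agreement drops a little below that level
  set.seed(3)
  d0 <- data.frame(
    area = rep(c("CentralAtlantic", "SouthAtlantic"), each = n),
    d15N = c(rnorm(n, 13.1, 0.8), rnorm(n, 14.6, 1.3)),
    d13C = c(rnorm(n, -16.3, 0.3), rnorm(n, -16.8, 0.3)))
  m0 <- fit_lda(d0)
  expect_gte(mean(predict(m0, grid) == ref_lab), 0.80)
})

test_that("the train/test split honours the per-bird and 30% rules", {
  # every bird tracked three years contributes exactly one training record
  # (the repeats already exceed the 30% testing share, so no rebalancing)
  d <- data.frame(bird_id = rep(sprintf("b%02d", 1:10), each = 3),
                  area = "A", d15N = rnorm(30), d13C = rnorm(30))
  d2 <- data.frame(bird_id = rep(sprintf("d%02d", 1:10), each = 3), area = "B",
                   d15N = rnorm(30), d13C = rnorm(30))
  sp <- split_train_test(rbind(d, d2), seed = 2)
  expect_true(all(table(sp$train$bird_id) == 1L))
  expect_equal(sum(sp$test$bird_id == "b01"), 2L)
  # 10 single-year birds per class -> 7 train / 3 test after rebalancing
  e <- data.frame(bird_id = sprintf("e%02d", 1:20),
                  area = rep(c("A", "B"), each = 10),
                  d15N = rnorm(20), d13C = rnorm(20))
  spe <- split_train_test(e, seed = 3)
  expect_equal(as.integer(table(spe$train$area)), c(7L, 7L))
  expect_equal(as.integer(table(spe$test$area)), c(3L, 3L))
  # a 9/1 class is topped up to at least 3 test records
  f <- data.frame(bird_id = c(rep("f01", 1), sprintf("f%02d", 2:10)),
                  area = "A", d15N = rnorm(10), d13C = rnorm(10))
  f$bird_id[10] <- "f09"  # one repeat -> initial test set of 1
  g <- data.frame(bird_id = sprintf("g%02d", 1:10), area = "B",
                  d15N = rnorm(10), d13C = rnorm(10))
  spf <- split_train_test(rbind(f, g), seed = 4)
  expect_gte(min(table(factor(spf$test$area, levels = c("A", "B")))), 3L)
  # pseudo-replication rule survives rebalancing: one record per bird in train
  expect_true(all(table(spf$train$bird_id) == 1L))
})

test_that("classification totals are sample-size-weighted class means", {
  rates <- data.frame(class = c("CentralAtlantic", "SouthAtlantic"),
                      n_train = c(38L, 21L), n_test = c(16L, 9L),
                      pct_train = c(51.3, 61.9), pct_test = c(47.1, 77.8))
  tot <- rbind_total(rates)
  expect_equal(tot$pct_train[tot$class == "Total"], 55.07, tolerance = 0.005)
})

test_that("classification rates are exact for a perfect and a random classifier", {
  set.seed(4)
  d <- data.frame(bird_id = sprintf("b%03d", 1:60),
                  area = rep(c("A", "B"), each = 30),
                  d15N = rep(c(0, 100), each = 30) + rnorm(60),
                  d13C = rep(c(0, -100), each = 30) + rnorm(60))
  sp <- split_train_test(d, seed = 1)
  m <- fit_lda(sp$train)
  cr <- classification_rates(m, sp$train, sp$test)
  expect_true(all(cr$pct_train == 100) && all(cr$pct_test == 100))

  # labels independent of the isotopes: accuracy near 50% for 2 classes
  set.seed(5)
  r <- data.frame(bird_id = sprintf("r%04d", 1:1000),
                  area = rep(c("A", "B"), 500),
                  d15N = rnorm(1000), d13C = rnorm(1000))
  spr <- split_train_test(r, seed = 2)
  mr <- fit_lda(spr$train)
  crr <- classification_rates(mr, spr$train, spr$test)
  expect_lt(abs(crr$pct_test[crr$class == "Total"] - 50), 5)
})

test_that("group comparisons select tests and letter the groups sensibly", {
  # all groups identical constants: no distinctions
  g <- rep(c("a", "b", "c"), each = 5)
  suppressWarnings(out <- group_comparison(rep(1, 15), g, test = "anova"))
  expect_equal(length(unique(out$letters)), 1L)

  set.seed(6)
  v <- c(rnorm(30), rnorm(30), rnorm(30, 5))
  g <- rep(c("g1", "g2", "g3"), each = 30)
  out <- group_comparison(v, g, test = "anova")
  expect_true(out$letters["g3"] != out$letters["g1"])
  expect_true(out$letters["g1"] == out$letters["g2"])
  expect_lt(out$p_value, 1e-6)
})

test_that("the ANOVA F statistic matches hand-computed sums of squares", {
  v <- c(3, 5, 4, 8, 9, 10)
  g <- rep(c("a", "b"), each = 3)
  out <- group_comparison(v, g, test = "anova")
  gm <- mean(v)
  ssb <- 3 * (mean(v[1:3]) - gm)^2 + 3 * (mean(v[4:6]) - gm)^2
  ssw <- sum((v[1:3] - mean(v[1:3]))^2) + sum((v[4:6] - mean(v[4:6]))^2)
  expect_equal(out$statistic, (ssb / 1) / (ssw / 4), tolerance = 1e-10)
  expect_equal(out$df, c(1, 4))
})

test_that("Kruskal-Wallis route applies the tie-corrected Dunn test", {
  set.seed(7)
  v <- c(rexp(20), rexp(20), rexp(20) + 3)
  g <- rep(c("a", "b", "c"), each = 20)
  out <- group_comparison(v, g, test = "kruskal")
  expect_equal(out$test, "kruskal")
  kw <- kruskal.test(v, factor(g))
  expect_equal(out$statistic, unname(kw$statistic))
  expect_true(out$letters["c"] != out$letters["a"])
  # Dunn z for two groups, no ties, against the closed form
  v2 <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g2 <- rep(c("x", "y"), each = 4)
  dn <- dunn_posthoc(v2, g2)
  N <- 8
  z_exp <- (mean(rank(v2)[1:4]) - mean(rank(v2)[5:8])) /
    sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 4))
  expect_equal(dn$z, z_exp, tolerance = 1e-12)
})

test_that("auto test selection screens normality per group", {
  set.seed(8)
  norm <- data.frame(v = rnorm(60), g = rep(c("a", "b"), each = 30))
  expect_equal(group_comparison(norm$v, norm$g, test = "auto")$test, "anova")
  skewed <- data.frame(v = c(rnorm(30), rexp(30)^3),
                       g = rep(c("a", "b"), each = 30))
  expect_equal(group_comparison(skewed$v, skewed$g, test = "auto")$test,
               "kruskal")
})

test_that("standard ellipse areas follow the eigenvalue formula", {
  X <- exact_cov_sample(40, S = diag(c(4, 1)))
  se <- standard_ellipse(X)
  expect_equal(se$SEA, 2 * pi, tolerance = 1e-10)
  expect_equal(se$SEAc, se$SEA * 39 / 38, tolerance = 1e-12)
  X10 <- exact_cov_sample(10, S = diag(c(4, 1)))
  se10 <- standard_ellipse(X10)
  expect_equal(se10$SEAc / se10$SEA, 9 / 8, tolerance = 1e-12)
  # isotropic unit covariance: SEA -> pi
  Xi <- exact_cov_sample(100, S = diag(2))
  expect_equal(standard_ellipse(Xi)$SEA, pi, tolerance = 1e-10)
  expect_error(standard_ellipse(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("the ellipse estimate is consistent and the posterior concentrates", {
  set.seed(9)
  S <- matrix(c(1.2, 0.3, 0.3, 0.5), 2)
  X <- MASS::mvrnorm(500, c(14, -16.5), S)
  se <- standard_ellipse(X, bayesian = TRUE, n_draws = 500, seed = 2)
  truth <- pi * sqrt(det(S))
  expect_lt(abs(se$SEA - truth) / truth, 0.10)
  expect_lt(abs(median(se$posterior_SEA) - se$SEA) / se$SEA, 0.10)
  expect_gt(min(se$posterior_SEA), 0)
})

test_that("feather variability screening flags multi-area feathers", {
  set.seed(10)
  colonies <- rep(c("Vila", "Raso"), each = 40)
  const <- data.frame(colony = colonies,
                      feather = rep(c("P1", "S8"), 40),
                      d15N = 12, d13C = -16.5)
  out <- feather_variability_summary(const)
  expect_false(any(out$flags$flagged))
  expect_equal(nrow(out$by_colony), 4L)  # feathers x colonies present

  # P1 from one common area; S8 an even mixture of the two area classes
  n <- 60
  mix <- data.frame(
    colony = rep(c("Vila", "Raso"), each = n),
    feather = rep(c("P1", "S8"), n),
    d15N = NA_real_, d13C = -16.5)
  p1 <- mix$feather == "P1"
  mix$d15N[p1] <- rnorm(sum(p1), 12.5, 0.6)
  mix$d15N[!p1] <- rnorm(sum(!p1), rep(c(13.1, 14.6), length.out = sum(!p1)),
                         rep(c(0.8, 1.3), length.out = sum(!p1)))
  out2 <- feather_variability_summary(mix)
  expect_true(out2$flags$flagged[out2$flags$feather == "S8"])
  expect_false(out2$flags$flagged[out2$flags$feather == "P1"])
})
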