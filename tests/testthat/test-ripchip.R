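make_rip <- function(m, group, sob = NULL) rip_dataset(m, group, sob)

test_that("QC masks low S/B spots and drops low-presence features", {
  m <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("F", 1:5),
                              paste0("a", 1:8)))
  group <- c(rep("IP", 3), rep("mock", 5))
  sob <- matrix(10, 5, 8, dimnames = dimnames(m))
  sob[1, 1:3] <- 1.0       # F1 left with 5 of 8 arrays: 62.5% > 60%
  sob[2, 1:4] <- 1.0       # F2 left with 4 of 8 arrays: 50%, dropped
  sob[3, 1] <- 1.8         # boundary: S/B = 1.8 exactly is masked
  ds <- qc_filter(make_rip(m, group, sob))
  expect_true("F1" %in% rownames(ds$log2_ratio))
  expect_false("F2" %in% rownames(ds$log2_ratio))
  expect_true(is.na(ds$log2_ratio["F3", 1]))
  rep <- attr(ds, "qc_report")
  expect_equal(rep$n_features_dropped, 1L)
  expect_equal(rep$dropped_features, "F2")
  expect_equal(rep$n_spots_masked, 3L + 4L + 1L)
})

test_that("the local SD prior follows the clamped-window worked case", {
  # 5 features whose mean expression sorts them as given, w = 3
  means <- 1:5
  sds <- c(1, 2, 3, 4, 5)
  expect_equal(local_sd_prior(means, sds, w = 3), c(2, 2, 3, 4, 4))
  # constant SDs give a constant prior
  expect_equal(local_sd_prior(rnorm(20), rep(0.7, 20), w = 7),
               rep(0.7, 20))
  # w = 1 degenerates to each feature's own SD
  s <- runif(10, 0.1, 2)
  expect_equal(local_sd_prior(rnorm(10), s, w = 1), s)
  # returned in original (unsorted) order
  expect_equal(local_sd_prior(c(3, 1, 2), c(30, 10, 20), w = 3),
               rep(20, 3))
})

test_that("the regularized t matches its closed-form oracle", {
  ip <- c(2.0, 2.1, 1.9)
  mock <- c(0.0, 0.1, -0.1, 0.05, -0.05)
  got <- regularized_t(ip, mock, 0.3, 0.3, nu0 = 10)
  want <- reg_t_oracle(ip, mock, 0.3, 0.3, 10)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, 3 + 5 - 2 + 2 * 10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # equal means give t = 0, p = 1
  sym <- regularized_t(c(1, 2, 3), c(3, 2, 1), 0.5, 0.5, nu0 = 5)
  expect_equal(sym$t, 0); expect_equal(sym$p, 1)
})

test_that("with nu0 = 0 the regularized t is the plain two-sample t", {
  set.seed(10)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n2 <- sample(2:8, 1)
    x1 <- rnorm(n1, sd = runif(1, 0.1, 2))
    x2 <- rnorm(n2, sd = runif(1, 0.1, 2))
    got <- regularized_t(x1, x2, nu0 = 0)
    want <- welch_style_t(x1, x2)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(regularized_t(c(1, 1), c(2, 2), nu0 = 0), "variance")
})

test_that("growing the prior weight shrinks t toward the prior-dominated value", {
  set.seed(4)
  x1 <- rnorm(3, 1, 1.5); x2 <- rnorm(5, 0, 1.5)
  s0 <- 0.4   # prior SD well below the sample SDs
  nus <- c(0.5, 1, 2, 5, 10, 50, 200, 1000)
  ts <- vapply(nus, function(nu)
    regularized_t(x1, x2, s0, s0, nu0 = nu)$t, numeric(1))
  # limit: variance fully replaced by the prior
  t_inf <- (mean(x1) - mean(x2)) / sqrt(s0^2 / 3 + s0^2 / 5)
  expect_true(all(diff(abs(ts - t_inf)) <= 1e-9))
  # p is continuous in nu0 (no jumps across a fine grid)
  ps <- vapply(seq(0.25, 20, by = 0.25), function(nu)
    regularized_t(x1, x2, s0, s0, nu0 = nu)$p, numeric(1))
  expect_lt(max(abs(diff(ps))), 0.05)
})

test_that("target calling combines fold and p-value thresholds", {
  # construct group means directly: IP mean 2.0 vs mock 0.2 is
  # 2^1.8 = 3.48-fold, above the 3-fold line
  expect_gte(2^(2.0 - 0.2), 3)
  set.seed(7)
  n <- 300
  ids <- sprintf("F%03d", 1:n)
  m <- matrix(rnorm(n * 8, 0, 0.3), n, 8,
              dimnames = list(ids, paste0("a", 1:8)))
  group <- c(rep("IP", 3), rep("mock", 5))
  m[1:10, 1:3] <- m[1:10, 1:3] + 2       # strong true enrichment
  m[11, 1:3] <- m[11, 1:3] + 1.0         # ~2-fold: below fold_min
  tc <- call_targets(make_rip(m, group), self_id = "F001")
  called <- tc$feature_id[tc$is_target]
  expect_setequal(called, ids[1:10])
  expect_false("F011" %in% called)       # fold below 3 despite tiny p
  expect_true(tc$is_self[tc$feature_id == "F001"])
  # sorted by descending fold change
  expect_false(is.unsorted(rev(tc$fold_change)))
  # invariant: every target satisfies both thresholds
  expect_true(all(tc$fold_change[tc$is_target] >= 3))
  expect_true(all(tc$p_value[tc$is_target] < 0.01))
})

test_that("features with fewer than two values per group are excluded", {
  m <- matrix(rnorm(16), 2, 8,
              dimnames = list(c("F1", "F2"), paste0("a", 1:8)))
  m[1, 1:2] <- NA                        # one IP value left
  group <- c(rep("IP", 3), rep("mock", 5))
  tc <- call_targets(make_rip(m, group))
  expect_equal(attr(tc, "excluded_features"), "F1")
  expect_equal(tc$feature_id, "F2")
})
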