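test_that("percentile ranks are tie-averaged, unit-topped and monotone-invariant", {
  expect_equal(percentile_rank(c(10, 20, 30)), c(1/3, 2/3, 1))
  expect_equal(percentile_rank(c(5, 5, 10)), c(0.5, 0.5, 1))
  x <- c(2, -1, 0.5, 7, NA, 3)
  r <- percentile_rank(x)
  expect_true(is.na(r[5]))
  expect_equal(r, percentile_rank(exp(x)))   # strictly increasing transform
  expect_error(percentile_rank(c(1, NA, NA)), "insufficient")
})

test_that("median-rank profiles follow the presence policy", {
  m <- matrix(runif(50), 10, 5,
              dimnames = list(paste0("F", 1:10), paste0("a", 1:5)))
  m[1, 1:3] <- NA                      # present in 2 of 5 < 50%
  prof <- median_rank_profile(m, screen_config(min_presence = 0.5))
  expect_false("F1" %in% names(prof$median_rank))
  expect_equal(attr(prof, "excluded_features"), "F1")
  # median over the available ranks
  m2 <- rbind(x = c(1, 2), y = c(2, 1), z = c(3, 3))
  colnames(m2) <- c("a", "b")
  prof2 <- median_rank_profile(m2)
  expect_equal(unname(prof2$median_rank["x"]), 0.5)  # ranks 1/3, 2/3
  # median of an explicit five-rank example
  expect_equal(median(c(0.95, 0.91, 0.99, 0.20, 0.97)), 0.95)
})

test_that("Z-score selection matches the closed form and its invariances", {
  tab <- matrix(c(1, 1, 1, 1, 11), ncol = 1,
                dimnames = list(paste0("F", 1:5), "a1"))
  sel <- suppressMessages(zscore_select(tab))
  # Z(11) = (11 - 1) / 4.472 = 2.236: below the 3.5 cutoff
  expect_equal(unname(sel$score["F5"]), 10 / sd(c(1, 1, 1, 1, 11)),
               tolerance = 1e-12)
  expect_equal(round(unname(sel$score["F5"]), 3), 2.236)
  expect_length(sel$selected, 0L)

  expect_error(suppressMessages(
    zscore_select(matrix(rep(3, 4), ncol = 1,
                         dimnames = list(paste0("F", 1:4), "a")))),
    "degenerate")

  # affine invariance with positive scale, replicate-all rule
  set.seed(1)
  m <- matrix(rnorm(300), 100, 3,
              dimnames = list(paste0("F", 1:100), paste0("a", 1:3)))
  m[1, ] <- m[1, ] + 8
  s1 <- suppressMessages(zscore_select(m))
  s2 <- suppressMessages(zscore_select(sweep(m * 3.7, 2, c(1, -2, 5), `+`)))
  expect_equal(s1$selected, s2$selected)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  expect_equal(s1$selected, "F1")

  # mean-of-replicates rule can rescue a feature missing one replicate hit
  cfg <- screen_config(require_all_replicates = FALSE)
  s3 <- suppressMessages(zscore_select(m, cfg))
  expect_true("F1" %in% s3$selected)
})

test_that("trough detection finds the valley of two-component mixtures", {
  set.seed(1)
  mix <- c(runif(3800, 0, 0.85), runif(200, 0.92, 1))
  cut <- find_trough_cutoff(mix)
  expect_gte(cut, 0.85); expect_lte(cut, 0.92)

  # the known valley midpoint is recovered within +/- 2 bins over seeds
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    mix <- c(runif(3800, 0, 0.85), runif(200, 0.92, 1))
    as.numeric(find_trough_cutoff(mix)) - 0.885
  }, numeric(1))
  expect_lte(max(abs(errs)), 2 * 0.01)

  # unimodal input refuses to invent a cutoff
  set.seed(2)
  expect_error(find_trough_cutoff(runif(4000)), "cutoff_override")
  # ... unless the analyst overrides
  cfg <- screen_config(cutoff_override = 0.9)
  expect_equal(suppressMessages(find_trough_cutoff(runif(4000), cfg)), 0.9)
  expect_error(find_trough_cutoff(runif(50)), "100")
})

test_that("binder selection is strictly above the cutoff", {
  prof <- structure(list(median_rank = c(A = 0.96, B = 0.91, C = 0.50)),
                    class = "rank_profile")
  expect_equal(select_binders(prof, 0.95)$selected, "A")
  expect_equal(select_binders(prof, 0.90)$selected, c("A", "B"))
  expect_length(select_binders(prof, 0.999)$selected, 0L)
  # boundary: equal to the cutoff is not selected
  expect_false("B" %in% select_binders(prof, 0.91)$selected)
})

test_that("rank-mode selection is invariant under per-array monotone transforms", {
  sim <- gen_protoarray(300, 4, 0.05, 0.93, 0.1, seed = 9)
  ft <- feature_table(sim$scans, "Cy5")
  warp <- ft
  warp[, 1] <- log1p(warp[, 1]); warp[, 2] <- warp[, 2]^3
  warp[, 3] <- warp[, 3] * 100; warp[, 4] <- sqrt(warp[, 4])
  p1 <- median_rank_profile(ft); p2 <- median_rank_profile(warp)
  expect_equal(p1$median_rank, p2$median_rank, tolerance = 1e-12)
})

test_that("overlap arithmetic reproduces the published set relations", {
  total_rna <- paste0("T", 1:67)
  shared <- 67 + 173 - 180                  # inclusion-exclusion: 60
  mrna <- c(total_rna[seq_len(shared)], paste0("M", 1:(173 - shared)))
  ov <- overlap_analysis(total_rna, mrna)
  expect_equal(ov$n_intersect, 60)
  expect_equal(ov$n_union, 180)
  expect_equal(ov$pct_A_in_B, 90)           # 90% of total-RNA binders shared
  expect_equal(ov$n_B_only, 113)            # mRNA-only binders
  expect_equal(ov$pct_B_only, 65)
  ov2 <- overlap_analysis("x", "y")
  expect_equal(ov2$n_intersect, 0); expect_equal(ov2$n_union, 2)
})
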