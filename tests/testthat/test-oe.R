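test_that("overexpression QC enforces both-channel S/B and correlation policy", {
  m <- matrix(rnorm(9), 3, 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  sob1 <- matrix(2.5, 3, 3); sob2 <- matrix(2.5, 3, 3)
  rc <- matrix(0.8, 3, 3)
  sob2[1, 1] <- 1.9        # one channel below 2.0 masks the spot
  rc[2, 1] <- 0.5
  ds <- oe_dataset(m, sob1, sob2, rc)

  out <- oe_qc_filter(ds)
  expect_true(is.na(out$log2_ratio[1, 1]))
  expect_true(is.na(out$log2_ratio[2, 1]))    # keep_above drops rc 0.5
  expect_false(is.na(out$log2_ratio[3, 1]))   # rc 0.8, S/B fine

  # the opposite reading of the correlation filter retains rc 0.5
  out2 <- oe_qc_filter(ds, oe_config(regcorr_direction = "keep_below"))
  expect_false(is.na(out2$log2_ratio[2, 1]))
  expect_true(is.na(out2$log2_ratio[3, 1]))
})

test_that("per-gene statistics match the closed-form one-sample t", {
  m <- rbind(up = c(0.5, 0.6, 0.7),
             flat = c(0, 0, 0),
             down = c(-0.8, -0.9, -1.0))
  st <- gene_stats(m)
  up <- st[st$gene_id == "up", ]
  expect_equal(up$mean_log2, 0.6)
  expect_equal(up$t_stat, 10.392, tolerance = 1e-3)
  # closed-form Student CDF for df = 2: F(t) = 1/2 + t / (2 sqrt(2 + t^2))
  p_exact <- 2 * (1 - (0.5 + up$t_stat / (2 * sqrt(2 + up$t_stat^2))))
  expect_equal(up$p_value, p_exact, tolerance = 1e-12)
  expect_equal(up$p_value, 0.0091, tolerance = 1e-2)

  flat <- st[st$gene_id == "flat", ]
  expect_equal(flat$fold_change, 1)
  expect_equal(flat$t_stat, 0)
  expect_false(flat$zero_variance)

  down <- st[st$gene_id == "down", ]
  expect_equal(down$fold_change, 2^-0.9, tolerance = 1e-12)
  expect_lt(down$fold_change, 1 / 1.5)

  # zero variance with nonzero mean is flagged, not silently p = 0
  st2 <- suppressMessages(gene_stats(rbind(const = c(0.4, 0.4, 0.4))))
  expect_true(st2$zero_variance)
  expect_true(is.na(st2$p_value))
})

test_that("changed-gene selection is reciprocal in fold and gated on p", {
  st <- data.frame(gene_id = c("a", "b", "c", "d"),
                   fold_change = c(1.6, 0.60, 1.6, 0.70),
                   p_value = c(0.01, 0.03, 0.2, 0.03),
                   stringsAsFactors = FALSE)
  ch <- changed_genes(st)
  expect_equal(ch$up, "a")
  expect_equal(ch$down, "b")          # 0.60 <= 1/1.5; 0.70 is not
  expect_false("c" %in% c(ch$up, ch$down))   # p too large
})

test_that("target-shift analysis reports both fold conventions and exact MW p", {
  st <- data.frame(gene_id = c("t1", "t2", "t3", "n1", "n2", "n3"),
                   mean_log2 = c(1, 2, 3, 4, 5, 6),
                   fold_change = 2^c(1, 2, 3, 4, 5, 6),
                   stringsAsFactors = FALSE)
  sh <- target_shift(st, c("t1", "t2", "t3"))
  expect_equal(sh$mw_p, 0.1)          # 2 / choose(6, 3) extreme labelings
  expect_equal(sh$mean_fc_targets, mean(2^(1:3)))
  expect_equal(sh$mean_fc_targets_geom, 2^2)
  expect_equal(sh$cdf$cdf_targets[sh$cdf$log2_ratio == 3], 1)
  expect_error(target_shift(st, character()), "non-empty|both")

  # MW p is invariant under strictly monotone transforms
  st2 <- st; st2$mean_log2 <- exp(st$mean_log2)
  expect_equal(target_shift(st2, c("t1", "t2", "t3"))$mw_p, sh$mw_p)
})

test_that("Fisher over-representation matches full enumeration", {
  ids <- sprintf("g%02d", 1:8)
  # table [[3,1],[1,3]]: targets a-d, changed a-c + e
  ov <- overrep_fisher(changed = ids[c(1:3, 5)], targets = ids[1:4],
                       universe = ids)
  expect_equal(unname(ov$table), matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(ov$p, 34 / 70, tolerance = 1e-12)
  expect_equal(ov$p, fisher_enum(ov$table), tolerance = 1e-12)

  # no association: [[1,1],[1,1]] gives p = 1
  ov2 <- overrep_fisher(changed = c("g1", "g3"), targets = c("g1", "g2"),
                        universe = c("g1", "g2", "g3", "g4"))
  expect_equal(unname(ov2$table), matrix(c(1, 1, 1, 1), 2))
  expect_equal(ov2$p, 1)

  # random tables with margins <= 30 against the enumeration oracle,
  # and target/changed role symmetry (table transpose)
  set.seed(21)
  for (i in 1:100) {
    cells <- sample(0:15, 4, TRUE)
    if (sum(cells) == 0) next
    universe <- sprintf("u%02d", seq_len(sum(cells)))
    targets <- universe[seq_len(cells[1] + cells[2])]
    changed <- c(universe[seq_len(cells[1])],
                 setdiff(universe, targets)[seq_len(cells[3])])
    ov3 <- overrep_fisher(changed, targets, universe)
    expect_equal(ov3$p, fisher_enum(ov3$table), tolerance = 1e-12)
    expect_equal(ov3$p, overrep_fisher(targets, changed, universe)$p,
                 tolerance = 1e-12)
  }
})

test_that("the target-shift null and the driver-recovery property hold", {
  # under no shift the MW p is approximately uniform
  ps <- vapply(1:60, function(s) {
    sim <- gen_overexpression(600, 60, 1.0, "MAP1", 1.0, 3, 0.2, seed = s)
    target_shift(gene_stats(sim$log2_ratio), sim$truth$true_targets)$mw_p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  expect_lte(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)))

  # a 4.2-fold driver tops the changed list essentially always
  tops <- vapply(1:40, function(s) {
    sim <- gen_overexpression(800, 40, 0.925, "MAP1", 4.2, 3, 0.2, seed = s)
    st <- gene_stats(sim$log2_ratio)
    st$gene_id[which.max(abs(st$mean_log2))] == "MAP1"
  }, logical(1))
  expect_gte(mean(tops), 0.95)
})
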