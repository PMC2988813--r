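#' Construct an overexpression profiling dataset
#'
#' Replicate log2 ratios (overexpression/control) with optional
#' per-spot QC fields from the two-color scan.
#'
#' @param log2_ratio Numeric matrix, genes x replicates.
#' @param sob1,sob2 Optional matrices of signal over background for the
#'   two channels, same shape as `log2_ratio`.
#' @param regcorr Optional matrix of per-spot regression correlations.
#' @return An object of class `"oe_dataset"`.
#' @export
oe_dataset <- function(log2_ratio, sob1 = NULL, sob2 = NULL,
                       regcorr = NULL) {
  stopifnot(is.matrix(log2_ratio))
  for (q in list(sob1, sob2, regcorr))
    if (!is.null(q)) stopifnot(identical(dim(q), dim(log2_ratio)))
  structure(list(log2_ratio = log2_ratio, sob1 = sob1, sob2 = sob2,
                 regcorr = regcorr),
            class = "oe_dataset")
}

#' Quality-filter overexpression profiles
#'
#' Masks spots failing the signal-over-background threshold in either
#' channel (retention requires S/B strictly above `sob_min` in both)
#' or the regression-correlation criterion. The correlation direction
#' is configurable: `"keep_above"` (the default, the usual QC reading
#' that well-measured two-color spots have high channel correlation)
#' retains spots with correlation >= the threshold, `"keep_below"`
#' retains the complement. Genes left with fewer than 2 replicate
#' values are excluded from testing downstream.
#'
#' @param ds An `"oe_dataset"`.
#' @param cfg An [oe_config()].
#' @return The filtered `"oe_dataset"`, with a `"qc_report"` attribute.
#' @export
oe_qc_filter <- function(ds, cfg = oe_config()) {
  stopifnot(inherits(ds, "oe_dataset"))
  m <- ds$log2_ratio
  fail <- matrix(FALSE, nrow(m), ncol(m))
  for (sob in list(ds$sob1, ds$sob2))
    if (!is.null(sob)) fail <- fail | (!is.na(sob) & sob <= cfg$sob_min)
  if (!is.null(ds$regcorr)) {
    rc_fail <- if (cfg$regcorr_direction == "keep_above")
      ds$regcorr < cfg$regcorr_threshold
    else ds$regcorr >= cfg$regcorr_threshold
    fail <- fail | (!is.na(ds$regcorr) & rc_fail)
  }
  n_masked <- sum(fail & !is.na(m))
  m[fail] <- NA_real_
  out <- oe_dataset(m, ds$sob1, ds$sob2, ds$regcorr)
  attr(out, "qc_report") <- list(n_spots_masked = n_masked,
                                 n_genes_testable = sum(rowSums(!is.na(m)) >= 2),
                                 sob_min = cfg$sob_min,
                                 regcorr_threshold = cfg$regcorr_threshold,
                                 regcorr_direction = cfg$regcorr_direction)
  out
}

#' Per-gene averaging and one-sample testing of replicate log2 ratios
#'
#' For each gene with at least 2 finite replicate values: the mean
#' log2 ratio, the fold change `2^mean` (values below 1 are
#' down-regulation under the two-color convention), and the two-sided
#' one-sample t-test of H0: mean log2 ratio = 0 with `n - 1` degrees
#' of freedom. Genes whose replicates are identical but nonzero have
#' no defined t-statistic; they are flagged `zero_variance` and their
#' p is `NA` rather than a silent 0.
#'
#' @param ds An `"oe_dataset"` (normally after [oe_qc_filter()]), or a
#'   plain genes x replicates matrix of log2 ratios.
#' @return A data frame with columns `gene_id`, `n`, `mean_log2`,
#'   `fold_change`, `sd`, `t_stat`, `p_value`, `zero_variance`. Genes
#'   with fewer than 2 values are omitted and listed in the
#'   `"excluded_genes"` attribute.
#' @export
gene_stats <- function(ds) {
  m <- if (inherits(ds, "oe_dataset")) ds$log2_ratio else ds
  stopifnot(is.matrix(m))
  n <- rowSums(is.finite(m))
  keep <- n >= 2
  mm <- m[keep, , drop = FALSE]
  mean_log2 <- rowMeans(mm, na.rm = TRUE)
  sds <- apply(mm, 1, sd, na.rm = TRUE)
  nn <- n[keep]
  se <- sds / sqrt(nn)
  t_stat <- ifelse(sds > 0, mean_log2 / se, ifelse(mean_log2 == 0, 0, NA))
  zero_var <- sds == 0 & mean_log2 != 0
  if (any(zero_var))
    message(sum(zero_var), " gene(s) with zero replicate variance and ",
            "nonzero mean: t undefined, flagged")
  p <- ifelse(is.na(t_stat), NA, 2 * pt(-abs(t_stat), nn - 1))
  res <- data.frame(gene_id = rownames(mm), n = nn,
                    mean_log2 = mean_log2, fold_change = 2^mean_log2,
                    sd = sds, t_stat = t_stat, p_value = p,
                    zero_variance = zero_var, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded_genes") <- rownames(m)[!keep]
  res
}

#' Select significantly changed genes
#'
#' A gene is "up" when its fold change is at least `fold_min` and
#' "down" when it is at most `1 / fold_min` (reciprocal symmetry: "at
#' least 1.5-fold changed" in either direction), in both cases with
#' one-sample p below `alpha_gene`.
#'
#' @param stats Data frame from [gene_stats()].
#' @param cfg An [oe_config()].
#' @return A list with character vectors `up` and `down`.
#' @export
changed_genes <- function(stats, cfg = oe_config()) {
  sig <- !is.na(stats$p_value) & stats$p_value < cfg$alpha_gene
  list(up = stats$gene_id[sig & stats$fold_change >= cfg$fold_min],
       down = stats$gene_id[sig & stats$fold_change <= 1 / cfg$fold_min])
}

#' Distribution shift of a target set in an overexpression profile
#'
#' Compares the expression response of a defined target set against
#' all other profiled genes: the mean fold change over targets (both
#' the arithmetic mean of per-gene linear fold changes and the
#' back-transformed mean log2 ratio, since the two conventions differ
#' slightly), a two-sided Mann-Whitney U test on the per-gene mean
#' log2 ratios, and the cumulative-distribution tables of both groups
#' for plotting.
#'
#' @param stats Data frame from [gene_stats()].
#' @param targets Character vector of target gene IDs.
#' @return A list of class `"shift_result"`: `mean_fc_targets`,
#'   `mean_fc_targets_geom`, `mean_fc_nontargets`, `n_targets`,
#'   `n_nontargets`, `mw_p`, and `cdf` (a data frame with columns
#'   `log2_ratio`, `cdf_targets`, `cdf_nontargets`).
#' @export
target_shift <- function(stats, targets) {
  is_t <- stats$gene_id %in% targets
  if (sum(is_t) == 0 || sum(!is_t) == 0)
    stop("both targets and non-targets must be present among tested genes")
  lt <- stats$mean_log2[is_t]
  ln <- stats$mean_log2[!is_t]
  # exact p for small untied samples (wilcox.test default), normal
  # approximation otherwise
  mw <- suppressWarnings(wilcox.test(lt, ln, alternative = "two.sided"))
  grid <- sort(unique(stats$mean_log2))
  cdf <- data.frame(log2_ratio = grid,
                    cdf_targets = ecdf(lt)(grid),
                    cdf_nontargets = ecdf(ln)(grid))
  structure(list(mean_fc_targets = mean(stats$fold_change[is_t]),
                 mean_fc_targets_geom = 2^mean(lt),
                 mean_fc_nontargets = mean(stats$fold_change[!is_t]),
                 n_targets = sum(is_t), n_nontargets = sum(!is_t),
                 mw_p = mw$p.value, cdf = cdf),
            class = "shift_result")
}

#' Fisher's exact test for target over-representation among changed genes
#'
#' Builds the 2x2 table (target / non-target) x (changed / unchanged)
#' over the tested universe and computes the two-sided exact p-value
#' by the probability-mass method (summing all tables at the observed
#' margins whose point probability does not exceed the observed
#' table's).
#'
#' @param changed Character vector of changed gene IDs (e.g. the
#'   down-regulated set).
#' @param targets Character vector of target gene IDs.
#' @param universe Character vector of all tested gene IDs.
#' @return A list with `table` (2x2 integer matrix) and `p`.
#' @export
overrep_fisher <- function(changed, targets, universe) {
  universe <- unique(universe)
  stopifnot(all(changed %in% universe), all(targets %in% universe))
  is_t <- universe %in% targets
  is_c <- universe %in% changed
  tab <- matrix(c(sum(is_t & is_c), sum(is_t & !is_c),
                  sum(!is_t & is_c), sum(!is_t & !is_c)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "non_target"),
                                c("changed", "unchanged")))
  list(table = tab, p = fisher.test(tab, alternative = "two.sided")$p.value)
}

#' @importFrom stats ecdf
NULL
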