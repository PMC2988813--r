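#' Configuration objects for the screening pipeline
#'
#' Constructors for the per-stage configuration lists. Each constructor
#' validates its thresholds and fills in the pipeline defaults, which
#' correspond to the published screening procedure: Z > 3.5 for
#' single-RNA probings, signal-over-background > 1.8 and presence in
#' more than 60% of arrays for RIP-Chip, 3-fold enrichment at p < 0.01
#' for target calling, and so on.
#'
#' @param z_threshold Z-score cutoff for binder selection (default 3.5).
#' @param center Centering statistic for Z-scores, `"median"` or
#'   `"mean"`. The default is the median.
#' @param require_all_replicates If `TRUE` (default) a feature must
#'   exceed `z_threshold` in every replicate; otherwise the
#'   replicate-mean Z is thresholded.
#' @param hist_bin_width Histogram bin width for trough detection
#'   (default 0.01, must lie in (0, 0.1)).
#' @param trough_search_interval Numeric length-2 vector, the median-rank
#'   interval searched for the bimodal trough (default `c(0.5, 1)`).
#' @param cutoff_override Optional manual rank cutoff; when set,
#'   automatic trough detection is bypassed.
#' @param min_presence Minimum fraction of replicate arrays with data
#'   for a feature to receive a median rank (default 0.5).
#'
#' @return A named list with class `"screen_config"`, `"rip_config"`,
#'   `"oe_config"` or `"enrich_config"`.
#' @export
screen_config <- function(z_threshold = 3.5,
                          center = c("median", "mean"),
                          require_all_replicates = TRUE,
                          hist_bin_width = 0.01,
                          trough_search_interval = c(0.5, 1),
                          cutoff_override = NULL,
                          min_presence = 0.5) {
  center <- match.arg(center)
  stopifnot(z_threshold > 0,
            hist_bin_width > 0, hist_bin_width < 0.1,
            length(trough_search_interval) == 2,
            trough_search_interval[1] < trough_search_interval[2],
            trough_search_interval[1] >= 0, trough_search_interval[2] <= 1,
            min_presence > 0, min_presence <= 1)
  if (!is.null(cutoff_override))
    stopifnot(cutoff_override > 0, cutoff_override < 1)
  structure(list(z_threshold = z_threshold, center = center,
                 require_all_replicates = require_all_replicates,
                 hist_bin_width = hist_bin_width,
                 trough_search_interval = trough_search_interval,
                 cutoff_override = cutoff_override,
                 min_presence = min_presence),
            class = "screen_config")
}

#' @rdname screen_config
#' @param sob_min Minimum signal-over-background; spots at or below the
#'   threshold are masked (strict `>` retains). Default 1.8 for RIP-Chip,
#'   2.0 (both channels) for overexpression profiles.
#' @param presence_min Minimum fraction of arrays with data for a feature
#'   to be tested; the comparison is strict (default 0.6, i.e. "more
#'   than 60% of the arrays").
#' @param fold_min Minimum fold change for a call (default 3 for RIP-Chip
#'   targets, 1.5 for overexpression-changed genes).
#' @param p_max Maximum p-value for a RIP-Chip target call (default 0.01).
#' @param prior_df Prior degrees of freedom `nu0` of the Bayesian
#'   variance estimate (default 10).
#' @param window_size Odd window width, in features sorted by mean
#'   expression, over which the prior standard deviation is averaged
#'   (default 101).
#' @param df_augmented If `TRUE` (default) the test degrees of freedom
#'   are augmented by `2 * prior_df`; otherwise plain `n1 + n2 - 2`.
#' @export
rip_config <- function(sob_min = 1.8, presence_min = 0.6, fold_min = 3,
                       p_max = 0.01, prior_df = 10, window_size = 101,
                       df_augmented = TRUE) {
  stopifnot(sob_min > 0, presence_min > 0, presence_min < 1,
            fold_min > 1, p_max > 0, p_max < 1,
            prior_df >= 0, window_size >= 1, window_size %% 2 == 1)
  structure(list(sob_min = sob_min, presence_min = presence_min,
                 fold_min = fold_min, p_max = p_max, prior_df = prior_df,
                 window_size = window_size, df_augmented = df_augmented),
            class = "rip_config")
}

#' @rdname screen_config
#' @param regcorr_threshold Regression-correlation QC threshold for
#'   two-color spots (default 0.6).
#' @param regcorr_direction `"keep_above"` (default) retains spots whose
#'   regression correlation is at least the threshold, the usual QC
#'   direction; `"keep_below"` retains the complement.
#' @param alpha_gene Per-gene significance level for the one-sample
#'   t-test on replicate log2 ratios (default 0.05).
#' @export
oe_config <- function(sob_min = 2.0, regcorr_threshold = 0.6,
                      regcorr_direction = c("keep_above", "keep_below"),
                      fold_min = 1.5, alpha_gene = 0.05) {
  regcorr_direction <- match.arg(regcorr_direction)
  stopifnot(sob_min > 0, fold_min > 1, alpha_gene > 0, alpha_gene < 1)
  structure(list(sob_min = sob_min, regcorr_threshold = regcorr_threshold,
                 regcorr_direction = regcorr_direction,
                 fold_min = fold_min, alpha_gene = alpha_gene),
            class = "oe_config")
}

#' @rdname screen_config
#' @param alpha Significance level on the corrected p-value (default 0.01).
#' @param correction Multiple-testing correction, `"bonferroni"`
#'   (default) or `"none"`.
#' @export
enrich_config <- function(alpha = 0.01,
                          correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, correction = correction),
            class = "enrich_config")
}

#' @rdname screen_config
#' @param screen,rip,oe,enrich Stage configurations.
#' @param seed Integer seed from which all simulation sub-seeds derive.
#' @export
pipeline_config <- function(screen = screen_config(), rip = rip_config(),
                            oe = oe_config(), enrich = enrich_config(),
                            seed = 1L) {
  stopifnot(inherits(screen, "screen_config"), inherits(rip, "rip_config"),
            inherits(oe, "oe_config"), inherits(enrich, "enrich_config"))
  structure(list(screen = screen, rip = rip, oe = oe, enrich = enrich,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}
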