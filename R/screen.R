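#' Percentile ranks within one array
#'
#' Converts one array's signals to ascending percentile ranks in
#' (0, 1]: tie-averaged ranks divided by the number of finite values,
#' so the (untied) maximum maps to exactly 1. Missing values stay
#' missing. Ranks are invariant under any strictly increasing
#' transform of the signals, which is what makes them robust to
#' array-to-array differences in signal magnitude and scale.
#'
#' @param values Numeric vector of one array's signals.
#' @return Numeric vector of the same length with percentile ranks in
#'   (0, 1] and `NA` where the input was missing.
#' @export
percentile_rank <- function(values) {
  n_finite <- sum(is.finite(values))
  if (n_finite < 2)
    stop("insufficient data: need at least 2 finite values, got ", n_finite)
  v <- values
  v[!is.finite(v)] <- NA
  rank(v, ties.method = "average", na.last = "keep") / n_finite
}

#' Median percentile-rank profile across replicate arrays
#'
#' Ranks each array with [percentile_rank()] and takes, per feature,
#' the median rank over arrays with data. Features with data in fewer
#' than `min_presence` of the arrays are excluded and reported in the
#' `"excluded_features"` attribute.
#'
#' @param table Numeric matrix, features x arrays (one channel).
#' @param cfg A [screen_config()].
#' @return A list of class `"rank_profile"` with elements `ranks`
#'   (features x arrays matrix of percentile ranks) and `median_rank`
#'   (named vector over retained features).
#' @export
median_rank_profile <- function(table, cfg = screen_config()) {
  stopifnot(is.matrix(table), ncol(table) >= 2)
  ranks <- apply(table, 2, percentile_rank)
  dimnames(ranks) <- dimnames(table)
  presence <- rowMeans(!is.na(ranks))
  keep <- presence >= cfg$min_presence
  med <- apply(ranks[keep, , drop = FALSE], 1, median, na.rm = TRUE)
  structure(list(ranks = ranks, median_rank = med),
            class = "rank_profile",
            excluded_features = rownames(table)[!keep])
}

#' Detect the trough of a bimodal median-rank distribution
#'
#' Histograms the median percentile ranks at `hist_bin_width` inside
#' the search interval, lightly smooths the counts with a centred
#' moving average of `smooth_bins` bins (raw 0.01-wide bins carry
#' enough Poisson noise to fake local maxima), identifies the two
#' highest local maxima of the smoothed histogram, and returns the
#' midpoint of the lowest-count bin strictly between them (for ties,
#' the centre bin of the minimal run). When features are
#' consistently highly ranked across replicates the median-rank
#' distribution is bimodal -- a broad non-binder mode and a high-rank
#' binder mode -- and the trough between the modes is a conservative
#' binder cutoff. If `cutoff_override` is set in the config it is
#' returned directly and auto-detection is bypassed.
#'
#' @param median_ranks Numeric vector of per-feature median ranks.
#' @param cfg A [screen_config()].
#' @param smooth_bins Width (in bins, odd) of the moving-average
#'   smoother applied before peak detection (default 5).
#' @param min_rel_depth Minimum relative depth of the valley (drop
#'   from the lower mode to the valley floor, as a fraction of the
#'   lower mode's height) for the histogram to count as bimodal
#'   (default 0.35); below it a no-trough error is raised.
#' @return The cutoff (a single number). The attributes `"histogram"`
#'   (data frame of bin midpoints, raw and smoothed counts) and
#'   `"modes"` (the two mode midpoints) document the detection.
#' @export
find_trough_cutoff <- function(median_ranks, cfg = screen_config(),
                               smooth_bins = 5, min_rel_depth = 0.35) {
  if (!is.null(cfg$cutoff_override)) {
    message("trough auto-detection bypassed; using cutoff_override = ",
            cfg$cutoff_override)
    return(cfg$cutoff_override)
  }
  x <- median_ranks[is.finite(median_ranks)]
  if (length(x) < 100)
    stop("need >= 100 median ranks for trough detection ",
         "(or set cutoff_override)")
  lo <- cfg$trough_search_interval[1]
  hi <- cfg$trough_search_interval[2]
  bw <- cfg$hist_bin_width
  breaks <- seq(lo, hi + bw / 2, by = bw)
  mids <- head(breaks, -1) + bw / 2
  counts <- tabulate(findInterval(x[x >= lo & x <= hi], breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(mids))
  nb <- length(counts)
  stopifnot(smooth_bins >= 1, smooth_bins %% 2 == 1)
  h <- (smooth_bins - 1) %/% 2
  smoothed <- vapply(seq_len(nb), function(i)
    mean(counts[max(1, i - h):min(nb, i + h)]), numeric(1))

  # local maxima of the smoothed histogram: at least as high as both
  # neighbours and strictly higher than at least one (plateaus
  # contribute their first bin)
  left <- c(-Inf, smoothed[-nb])
  right <- c(smoothed[-1], -Inf)
  is_max <- smoothed >= left & smoothed >= right &
    (smoothed > left | smoothed > right)
  peaks <- which(is_max)
  # the two modes are the pair of local maxima enclosing the most
  # prominent valley: the drop from the lower mode to the minimum
  # between them, relative to the lower mode. Poisson bumps on one
  # mode's flank leave shallow relative dips; a genuine between-mode
  # valley loses most of the lower mode's height.
  top2 <- NULL; best_depth <- min_rel_depth
  if (length(peaks) >= 2) {
    for (a in seq_len(length(peaks) - 1)) for (b in (a + 1):length(peaks)) {
      i <- peaks[a]; j <- peaks[b]
      if (j - i < 2) next
      low_mode <- min(smoothed[i], smoothed[j])
      depth <- (low_mode - min(smoothed[(i + 1):(j - 1)])) / low_mode
      if (depth > best_depth) {
        best_depth <- depth
        top2 <- c(i, j)
      }
    }
  }
  if (is.null(top2))
    stop("no trough found: median-rank histogram is unimodal in [",
         lo, ", ", hi, "]; supply cutoff_override")
  between <- (top2[1] + 1):(top2[2] - 1)
  run <- between[smoothed[between] == min(smoothed[between])]
  trough_bin <- run[ceiling(length(run) / 2)]
  cutoff <- mids[trough_bin]
  structure(cutoff,
            histogram = data.frame(mid = mids, count = counts,
                                   smoothed = smoothed),
            modes = mids[top2])
}

#' Select binders above a median-rank cutoff
#'
#' Features whose median percentile rank is strictly greater than the
#' cutoff are selected as binders.
#'
#' @param profile A `"rank_profile"` from [median_rank_profile()].
#' @param cutoff Rank cutoff in (0, 1), e.g. from [find_trough_cutoff()].
#' @return A list of class `"binder_selection"`: `selected` (character
#'   vector of feature IDs), `cutoff_used`, `score` (named median
#'   ranks) and `mode = "rank"`.
#' @export
select_binders <- function(profile, cutoff) {
  stopifnot(inherits(profile, "rank_profile"),
            cutoff > 0, cutoff < 1)
  score <- profile$median_rank
  structure(list(selected = names(score)[score > cutoff],
                 cutoff_used = as.numeric(cutoff),
                 score = score, mode = "rank"),
            class = "binder_selection")
}

#' Z-score binder selection from replicate arrays
#'
#' For each array, features are scored as
#' `Z = (x - center(array)) / SD(array)` with the sample standard
#' deviation over all finite values; a feature is selected when its Z
#' exceeds `z_threshold` in every replicate
#' (`require_all_replicates = TRUE`, the default) or when its
#' replicate-mean Z exceeds the threshold. Intended for probings with
#' a single defined RNA, where replicate signals are reproducible
#' enough for absolute scores; for complex RNA pools use the rank mode.
#'
#' The centering statistic defaults to the median, which is robust to
#' the handful of true binders in the upper tail; mean-centering is
#' available for compatibility and a note is emitted because the two
#' conventions give slightly different scores.
#'
#' @param table Numeric matrix, features x arrays (one channel).
#' @param cfg A [screen_config()].
#' @return A `"binder_selection"`: `selected`, `cutoff_used`
#'   (`z_threshold`), `score` (replicate-mean Z per feature),
#'   `z` (features x arrays matrix), `mode = "zscore"`.
#' @export
zscore_select <- function(table, cfg = screen_config()) {
  stopifnot(is.matrix(table), ncol(table) >= 1)
  message("Z-score mode: centering on the ", cfg$center,
          " of each array's averaged signals")
  z <- apply(table, 2, function(x) {
    fin <- is.finite(x)
    if (sum(fin) < 3)
      stop("need >= 3 finite values per array for Z-scores")
    s <- sd(x[fin])
    if (s == 0)
      stop("degenerate array: zero standard deviation")
    ctr <- if (cfg$center == "median") median(x[fin]) else mean(x[fin])
    (x - ctr) / s
  })
  dimnames(z) <- dimnames(table)
  mean_z <- rowMeans(z, na.rm = TRUE)
  hit <- if (cfg$require_all_replicates)
    apply(z > cfg$z_threshold, 1, function(r) all(r[!is.na(r)]) && any(!is.na(r)))
  else mean_z > cfg$z_threshold
  structure(list(selected = rownames(table)[which(hit)],
                 cutoff_used = cfg$z_threshold,
                 score = mean_z, z = z, mode = "zscore"),
            class = "binder_selection")
}

#' Overlap arithmetic for two binder sets
#'
#' Exact set arithmetic between two feature sets (e.g. total-RNA vs
#' mRNA binders), with the percentages used in reporting (rounded to
#' the nearest integer).
#'
#' @param setA,setB Character vectors of feature IDs.
#' @return A list with `n_A`, `n_B`, `n_intersect`, `n_union`,
#'   `n_A_only`, `n_B_only`, and percentages `pct_A_in_B`
#'   (shared features as a percentage of A), `pct_B_in_A`,
#'   `pct_A_only` (of A), `pct_B_only` (of B).
#' @export
overlap_analysis <- function(setA, setB) {
  A <- unique(setA); B <- unique(setB)
  both <- intersect(A, B)
  pct <- function(k, n) if (n == 0) NA_real_ else round(100 * k / n)
  list(n_A = length(A), n_B = length(B),
       n_intersect = length(both), n_union = length(union(A, B)),
       n_A_only = length(setdiff(A, B)), n_B_only = length(setdiff(B, A)),
       pct_A_in_B = pct(length(both), length(A)),
       pct_B_in_A = pct(length(both), length(B)),
       pct_A_only = pct(length(setdiff(A, B)), length(A)),
       pct_B_only = pct(length(setdiff(B, A)), length(B)))
}
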