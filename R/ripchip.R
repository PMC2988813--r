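#' Construct a RIP-Chip dataset
#'
#' Bundles the log2 IP(or mock)/input ratios with group labels and the
#' per-spot signal-over-background of the input channel, the quantity
#' used for quality filtering.
#'
#' @param log2_ratio Numeric matrix, features x arrays.
#' @param group Character vector over arrays, values `"IP"` or `"mock"`.
#' @param signal_over_background Numeric matrix of the same shape as
#'   `log2_ratio`, or `NULL` if no S/B filtering is to be applied.
#' @return An object of class `"rip_dataset"`.
#' @export
rip_dataset <- function(log2_ratio, group, signal_over_background = NULL) {
  stopifnot(is.matrix(log2_ratio), length(group) == ncol(log2_ratio),
            all(group %in% c("IP", "mock")))
  if (!is.null(signal_over_background))
    stopifnot(identical(dim(signal_over_background), dim(log2_ratio)))
  structure(list(log2_ratio = log2_ratio, group = group,
                 signal_over_background = signal_over_background,
                 n_ip = sum(group == "IP"), n_mock = sum(group == "mock")),
            class = "rip_dataset")
}

#' Quality-filter a RIP-Chip dataset
#'
#' Masks to missing every spot whose input-channel signal over
#' background is at or below `sob_min` (the comparison for retention is
#' strict: S/B must exceed the threshold), then drops features with
#' data in no more than `presence_min` of the arrays ("more than 60%"
#' retained under the defaults). Masked and dropped counts are in the
#' `"qc_report"` attribute.
#'
#' @param ds A `"rip_dataset"`.
#' @param cfg A [rip_config()].
#' @return The filtered `"rip_dataset"`.
#' @export
qc_filter <- function(ds, cfg = rip_config()) {
  stopifnot(inherits(ds, "rip_dataset"))
  m <- ds$log2_ratio
  n_masked <- 0L
  if (!is.null(ds$signal_over_background)) {
    fail <- !is.na(ds$signal_over_background) &
      ds$signal_over_background <= cfg$sob_min
    n_masked <- sum(fail & !is.na(m))
    m[fail] <- NA_real_
  }
  presence <- rowMeans(!is.na(m))
  keep <- presence > cfg$presence_min
  out <- rip_dataset(m[keep, , drop = FALSE], ds$group,
                     if (is.null(ds$signal_over_background)) NULL
                     else ds$signal_over_background[keep, , drop = FALSE])
  attr(out, "qc_report") <- list(n_features_in = nrow(ds$log2_ratio),
                                 n_spots_masked = n_masked,
                                 n_features_dropped = sum(!keep),
                                 dropped_features = rownames(m)[!keep],
                                 sob_min = cfg$sob_min,
                                 presence_min = cfg$presence_min)
  out
}

#' Local prior standard deviation from expression neighbours
#'
#' Estimates, for each feature, a prior standard deviation as the mean
#' of the sample SDs of the `w` features closest in mean expression:
#' features are sorted by mean, a sliding window of width `w` is
#' clamped (not reflected) at the ends so every window holds exactly
#' `w` features (or all features when fewer than `w` have a defined
#' SD), and the window mean of SDs is returned in the original feature
#' order. This is the "Bayesian estimate of the variance among gene
#' measurements within an experiment" used to regularize low-replicate
#' t-tests: features measured at similar intensity share similar
#' measurement variance.
#'
#' @param means Per-feature mean expression (sorting key).
#' @param sds Per-feature sample standard deviation.
#' @param w Window width in features (odd).
#' @return Numeric vector of prior SDs, aligned with the input order;
#'   `NA` where `sds` was `NA`.
#' @export
local_sd_prior <- function(means, sds, w = 101) {
  stopifnot(length(means) == length(sds), w >= 1)
  ok <- which(!is.na(sds) & !is.na(means))
  out <- rep(NA_real_, length(sds))
  n <- length(ok)
  if (n == 0) return(out)
  w_eff <- min(w, n)
  ord <- ok[order(means[ok])]
  s_sorted <- sds[ord]
  h <- (w_eff - 1) %/% 2
  # clamped window starts: full width w_eff everywhere
  starts <- pmin(pmax(seq_len(n) - h, 1L), n - w_eff + 1L)
  cs <- c(0, cumsum(s_sorted))
  sigma0_sorted <- (cs[starts + w_eff] - cs[starts]) / w_eff
  out[ord] <- sigma0_sorted
  out
}

#' Regularized two-sample t-test (Bayesian variance shrinkage)
#'
#' Per group, the posterior variance blends the observed sample
#' variance with a prior variance from expression neighbours:
#' \deqn{\hat\sigma^2 = \frac{\nu_0 \sigma_0^2 + (n-1) s^2}{\nu_0 + n - 2}}
#' and the statistic is
#' \deqn{t = \frac{\bar x_1 - \bar x_2}
#'   {\sqrt{\hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2}}}
#' with `df = n1 + n2 - 2 + 2 * nu0` degrees of freedom (the prior
#' contributes pseudo-observations; set `df_augmented = FALSE` in the
#' config for plain `n1 + n2 - 2`). With `nu0 = 0` this reduces
#' exactly to the ordinary two-sample t with per-group variances.
#'
#' @param x1,x2 Numeric vectors (finite values; at least 2 per group).
#' @param sigma0_1,sigma0_2 Prior SDs for each group, e.g. from
#'   [local_sd_prior()]. Ignored when `nu0 = 0`.
#' @param nu0 Prior degrees of freedom (>= 0).
#' @param df_augmented Augment df by `2 * nu0` (default `TRUE`).
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
regularized_t <- function(x1, x2, sigma0_1 = NA, sigma0_2 = NA, nu0 = 10,
                          df_augmented = TRUE) {
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(n1 >= 2, n2 >= 2, nu0 >= 0)
  s1 <- var(x1); s2 <- var(x2)
  if (nu0 == 0) {
    if (s1 == 0 && s2 == 0)
      stop("undefined variance: both groups constant and nu0 = 0")
    v1 <- s1; v2 <- s2
  } else {
    stopifnot(is.finite(sigma0_1), is.finite(sigma0_2))
    v1 <- (nu0 * sigma0_1^2 + (n1 - 1) * s1) / (nu0 + n1 - 2)
    v2 <- (nu0 * sigma0_2^2 + (n2 - 1) * s2) / (nu0 + n2 - 2)
  }
  t <- (mean(x1) - mean(x2)) / sqrt(v1 / n1 + v2 / n2)
  df <- n1 + n2 - 2 + if (df_augmented) 2 * nu0 else 0
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Call RIP-Chip targets against mock controls
#'
#' For every feature retained by [qc_filter()], computes the group
#' means of the log2 ratios, the fold change
#' `2^(mean_IP - mean_mock)`, and a regularized-t p-value with the
#' prior SD taken from expression neighbours within each group
#' ([local_sd_prior()] on the group means). A feature is a target when
#' `fold_change >= fold_min` and `p < p_max` (defaults: at least
#' 3-fold enrichment at p < 0.01). Features with fewer than 2 values
#' in either group are excluded from testing and reported.
#'
#' @param ds A `"rip_dataset"`, already quality-filtered.
#' @param cfg A [rip_config()].
#' @param self_id Optional feature ID of the immunopurified protein's
#'   own transcript; its target row is flagged `is_self`
#'   (self-association, the substrate of autoregulatory feedback).
#' @return A data frame sorted by descending fold change with columns
#'   `feature_id`, `n_ip`, `n_mock`, `mean_log2_ip`, `mean_log2_mock`,
#'   `fold_change`, `t_stat`, `df`, `p_value`, `is_target`, `is_self`.
#'   The `"excluded_features"` attribute lists untestable features.
#' @export
call_targets <- function(ds, cfg = rip_config(), self_id = NULL) {
  stopifnot(inherits(ds, "rip_dataset"))
  m <- ds$log2_ratio
  ip <- m[, ds$group == "IP", drop = FALSE]
  mock <- m[, ds$group == "mock", drop = FALSE]
  n_ip <- rowSums(!is.na(ip))
  n_mock <- rowSums(!is.na(mock))
  testable <- n_ip >= 2 & n_mock >= 2
  excluded <- rownames(m)[!testable]

  ip <- ip[testable, , drop = FALSE]
  mock <- mock[testable, , drop = FALSE]
  mean_ip <- rowMeans(ip, na.rm = TRUE)
  mean_mock <- rowMeans(mock, na.rm = TRUE)
  sd_ip <- apply(ip, 1, sd, na.rm = TRUE)
  sd_mock <- apply(mock, 1, sd, na.rm = TRUE)
  sigma0_ip <- local_sd_prior(mean_ip, sd_ip, cfg$window_size)
  sigma0_mock <- local_sd_prior(mean_mock, sd_mock, cfg$window_size)

  n <- sum(testable)
  t_stat <- df <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- regularized_t(ip[i, ], mock[i, ], sigma0_ip[i], sigma0_mock[i],
                       nu0 = cfg$prior_df, df_augmented = cfg$df_augmented)
    t_stat[i] <- r$t; df[i] <- r$df; p[i] <- r$p
  }
  fold <- 2^(mean_ip - mean_mock)
  res <- data.frame(feature_id = rownames(ip),
                    n_ip = rowSums(!is.na(ip)),
                    n_mock = rowSums(!is.na(mock)),
                    mean_log2_ip = mean_ip, mean_log2_mock = mean_mock,
                    fold_change = fold, t_stat = t_stat, df = df,
                    p_value = p,
                    is_target = fold >= cfg$fold_min & p < cfg$p_max,
                    stringsAsFactors = FALSE)
  res$is_self <- if (is.null(self_id)) FALSE else res$feature_id == self_id
  res <- res[order(-res$fold_change), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded_features") <- excluded
  res
}

#' @importFrom stats var
NULL
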