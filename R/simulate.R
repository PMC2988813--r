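# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Ground truth of a simulated dataset
#'
#' @param true_binders,true_targets Character vectors of spiked-in
#'   feature IDs.
#' @param true_shift Multiplicative mean fold change applied to targets.
#' @param cluster_assignment Named integer vector, gene -> cluster.
#' @param seed The seed that produced the dataset.
#' @return A list of class `"sim_truth"`.
#' @export
sim_truth <- function(true_binders = character(), true_targets = character(),
                      true_shift = NA_real_, cluster_assignment = NULL,
                      seed = NA_integer_) {
  structure(list(true_binders = true_binders, true_targets = true_targets,
                 true_shift = true_shift,
                 cluster_assignment = cluster_assignment,
                 seed = seed),
            class = "sim_truth")
}

#' Simulate replicate protein-microarray probings
#'
#' Generates `n_replicates` two-channel protein arrays with duplicate
#' spots. Non-binder fluorescence is i.i.d. log-normal per replicate
#' (strictly positive, right-skewed, the standard intensity noise
#' model). Binders are constructed by rank injection: each binder's
#' per-replicate signal is the background distribution's quantile at
#' a level drawn uniformly from `(binder_rank_floor, 1)`, times
#' multiplicative log-normal noise, so binders sit above the
#' `binder_rank_floor` quantile of the background in every replicate
#' and the median-rank histogram is bimodal. The same binder set is
#' used in both channels when `shared_binders = TRUE` (default);
#' otherwise each channel gets an independent binder set.
#'
#' @param n_proteins Number of proteins (>= 10).
#' @param n_replicates Number of replicate arrays (>= 2).
#' @param binder_fraction Fraction of proteins that are true binders.
#' @param binder_rank_floor Background quantile above which binder
#'   signals are injected, in (0, 1).
#' @param noise_sd SD of multiplicative log-normal noise applied to
#'   binder levels and duplicate spots.
#' @param seed Integer seed; identical calls are byte-identical.
#' @param n_spots Duplicate spots per protein (default 2).
#' @param shared_binders One binder set for both channels (default).
#' @param meanlog,sdlog Log-normal background parameters.
#' @return A list with `scans` (list of `"array_scan"`) and `truth`
#'   (a `"sim_truth"` with `true_binders`).
#' @export
gen_protoarray <- function(n_proteins, n_replicates,
                           binder_fraction = 0.05,
                           binder_rank_floor = 0.92,
                           noise_sd = 0.1, seed = 1L,
                           n_spots = 2, shared_binders = TRUE,
                           meanlog = log(500), sdlog = 1) {
  stopifnot(n_proteins >= 10, n_replicates >= 2,
            binder_rank_floor > 0, binder_rank_floor < 1)
  n_binders <- round(n_proteins * binder_fraction)
  if (n_binders < 1)
    stop("binder_fraction produces no binders at n_proteins = ", n_proteins)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  channels <- c("Cy3", "Cy5")
  .with_seed(seed, {
    binder_sets <- if (shared_binders) {
      b <- sample(ids, n_binders)
      list(Cy3 = b, Cy5 = b)
    } else list(Cy3 = sample(ids, n_binders), Cy5 = sample(ids, n_binders))
    scans <- lapply(seq_len(n_replicates), function(r) {
      feat <- data.frame(
        feature_id = rep(ids, each = n_spots),
        spot_index = rep(seq_len(n_spots), times = n_proteins),
        flag = 0L, stringsAsFactors = FALSE)
      for (ch in channels) {
        level <- rlnorm(n_proteins, meanlog, sdlog)
        is_b <- ids %in% binder_sets[[ch]]
        u <- runif(sum(is_b), binder_rank_floor, 1)
        level[is_b] <- qlnorm(u, meanlog, sdlog) *
          exp(rnorm(sum(is_b), 0, noise_sd))
        spot <- rep(level, each = n_spots) *
          exp(rnorm(n_proteins * n_spots, 0, noise_sd))
        feat[[paste0("net.", ch)]] <- spot
      }
      structure(list(array_id = sprintf("array%02d", r), features = feat,
                     channel_names = channels),
                class = "array_scan")
    })
    truth <- sim_truth(true_binders = sort(binder_sets$Cy5), seed = seed)
    truth$binder_sets <- lapply(binder_sets, sort)
    list(scans = scans, truth = truth)
  })
}

#' Simulate a RIP-Chip experiment with mock controls
#'
#' Non-target log2 ratios are Normal(0, `noise_sd`) in IP and mock
#' arrays alike; target ratios in the IP arrays are shifted up by
#' `log2_enrichment`. A fraction `sob_low_fraction` of spots per array
#' is assigned input-channel signal over background below the QC
#' threshold (uniform in (0.5, 1.8]) to exercise the filter; remaining
#' spots get S/B uniform in (2, 30).
#'
#' @param n_features Number of array features.
#' @param n_targets Number of spiked-in targets (0 gives a pure null).
#' @param log2_enrichment IP-vs-mock shift of targets on the log2
#'   scale (2 corresponds to 4-fold enrichment).
#' @param n_ip,n_mock Numbers of IP and mock arrays (>= 2 each).
#' @param noise_sd SD of the log2-ratio noise.
#' @param sob_low_fraction Fraction of low-quality spots per array.
#' @param seed Integer seed.
#' @return A list with `dataset` (a `"rip_dataset"`) and `truth`.
#' @export
gen_ripchip <- function(n_features, n_targets, log2_enrichment = 2,
                        n_ip = 3, n_mock = 5, noise_sd = 0.4,
                        sob_low_fraction = 0.02, seed = 1L) {
  stopifnot(n_ip >= 2, n_mock >= 2, n_targets >= 0,
            n_targets <= n_features,
            sob_low_fraction >= 0, sob_low_fraction < 1)
  ids <- sprintf("F%05d", seq_len(n_features))
  n_arr <- n_ip + n_mock
  group <- c(rep("IP", n_ip), rep("mock", n_mock))
  .with_seed(seed, {
    targets <- if (n_targets > 0) sample(ids, n_targets) else character()
    m <- matrix(rnorm(n_features * n_arr, 0, noise_sd), n_features, n_arr,
                dimnames = list(ids, paste0(tolower(group),
                                            seq_len(n_arr))))
    m[ids %in% targets, group == "IP"] <-
      m[ids %in% targets, group == "IP"] + log2_enrichment
    sob <- matrix(runif(n_features * n_arr, 2, 30), n_features, n_arr,
                  dimnames = dimnames(m))
    if (sob_low_fraction > 0) {
      n_low <- round(sob_low_fraction * n_features)
      for (j in seq_len(n_arr))
        sob[sample.int(n_features, n_low), j] <- runif(n_low, 0.5, 1.8)
    }
    list(dataset = rip_dataset(m, group, sob),
         truth = sim_truth(true_targets = sort(targets), seed = seed))
  })
}

#' Simulate replicate overexpression profiles
#'
#' Generates a genes x replicates matrix of log2 ratios
#' (overexpression/control): non-targets centred at 0, a target set
#' centred at `log2(target_mean_fc)`, and the overexpressed driver
#' gene centred at `log2(driver_fc)`, all with i.i.d. Normal noise.
#'
#' @param n_genes Number of profiled genes (driver included).
#' @param targets Either a count of target genes to spike or a
#'   character vector of gene IDs (must not contain `driver_id`).
#' @param target_mean_fc Mean fold change applied to targets (e.g.
#'   0.925 for a slight coordinated down-shift).
#' @param driver_id Gene ID of the overexpressed driver.
#' @param driver_fc Fold change of the driver itself (e.g. 4.2).
#' @param n_reps Replicate columns (>= 2).
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param seed Integer seed.
#' @return A list with `log2_ratio` (matrix with gene IDs as row
#'   names) and `truth` (with `true_targets` and `true_shift`).
#' @export
gen_overexpression <- function(n_genes, targets, target_mean_fc = 0.925,
                               driver_id = "MAP1", driver_fc = 4.2,
                               n_reps = 3, noise_sd = 0.2, seed = 1L) {
  stopifnot(n_genes >= 3, n_reps >= 2, target_mean_fc > 0, driver_fc > 0)
  ids <- c(driver_id, sprintf("G%05d", seq_len(n_genes - 1)))
  .with_seed(seed, {
    target_ids <- if (is.character(targets)) targets
    else sample(setdiff(ids, driver_id), targets)
    if (driver_id %in% target_ids)
      stop("driver_id must not be among the targets")
    stopifnot(all(target_ids %in% ids))
    mu <- rep(0, n_genes)
    mu[ids %in% target_ids] <- log2(target_mean_fc)
    mu[ids == driver_id] <- log2(driver_fc)
    m <- matrix(mu + rnorm(n_genes * n_reps, 0, noise_sd),
                n_genes, n_reps,
                dimnames = list(ids, paste0("rep", seq_len(n_reps))))
    list(log2_ratio = m,
         truth = sim_truth(true_targets = sort(target_ids),
                           true_shift = target_mean_fc, seed = seed))
  })
}

#' Simulate a block-structured expression compendium
#'
#' Partitions genes into `n_clusters` blocks of near-equal size; each
#' block gets a distinct condition-profile mean (centroid coordinates
#' drawn Normal(0, `separation`) around a common baseline) and genes
#' get Gaussian noise around their block centroid. With
#' `separation = 0` all blocks coincide and clustering recovery is at
#' chance.
#'
#' @param n_genes,n_conditions Matrix dimensions.
#' @param n_clusters Number of blocks (<= `n_genes`).
#' @param separation SD of centroid coordinates around the baseline.
#' @param seed Integer seed.
#' @param noise_sd Within-block noise SD (default 1).
#' @param baseline Common expression baseline on the RMA-like log
#'   scale (default 8).
#' @return A list with `matrix` (genes x conditions) and `truth`
#'   (with `cluster_assignment`).
#' @export
gen_compendium <- function(n_genes, n_conditions, n_clusters,
                           separation = 3, seed = 1L, noise_sd = 1,
                           baseline = 8) {
  stopifnot(n_clusters >= 1, n_clusters <= n_genes, n_conditions >= 1,
            separation >= 0)
  ids <- sprintf("G%04d", seq_len(n_genes))
  conds <- sprintf("cond%03d", seq_len(n_conditions))
  .with_seed(seed, {
    assign <- sort(rep_len(seq_len(n_clusters), n_genes))
    centroids <- matrix(baseline + rnorm(n_clusters * n_conditions,
                                         0, separation),
                        n_clusters, n_conditions)
    m <- centroids[assign, , drop = FALSE] +
      matrix(rnorm(n_genes * n_conditions, 0, noise_sd),
             n_genes, n_conditions)
    dimnames(m) <- list(ids, conds)
    list(matrix = m,
         truth = sim_truth(cluster_assignment = setNames(assign, ids),
                           seed = seed))
  })
}
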