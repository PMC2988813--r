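#' K-means clustering of expression profiles across conditions
#'
#' Clusters genes by their condition profiles (rows of the expression
#' matrix) with Lloyd's algorithm under the Euclidean metric,
#' k-means++-style seeding, and multiple restarts keeping the solution
#' with the lowest within-cluster sum of squares. A cluster emptied
#' during an iteration is re-seeded with the point farthest from its
#' assigned centroid. Genes with missing values are dropped before
#' clustering and reported.
#'
#' @param m Numeric matrix, genes x conditions (e.g. RMA-scale log
#'   expression).
#' @param k Number of clusters (default 10).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param nstart Number of random restarts (default 25).
#' @param iter_max Maximum Lloyd iterations per restart (default 100).
#' @return A list of class `"kmeans_profiles"` with `cluster` (named
#'   integer vector over genes), `centers` (k x conditions matrix),
#'   `withinss` (per-cluster), `tot_withinss`, and `sizes`. Dropped
#'   genes are in the `"dropped_genes"` attribute.
#' @export
kmeans_profiles <- function(m, k = 10, seed = 1L, nstart = 25,
                            iter_max = 100) {
  stopifnot(is.matrix(m))
  complete <- rowSums(!is.finite(m)) == 0
  dropped <- rownames(m)[!complete]
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " gene(s) with missing profiles")
  m <- m[complete, , drop = FALSE]
  if (k > nrow(m)) stop("k (", k, ") exceeds number of genes (", nrow(m), ")")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- .lloyd_once(m, k, iter_max)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  best$cluster <- setNames(best$cluster, rownames(m))
  best$sizes <- tabulate(best$cluster, nbins = k)
  structure(best, class = "kmeans_profiles", dropped_genes = dropped)
}

# one restart: k-means++ seeding then Lloyd iterations
.lloyd_once <- function(m, k, iter_max) {
  n <- nrow(m)
  # k-means++ seeding
  centers <- matrix(NA_real_, k, ncol(m))
  idx <- sample.int(n, 1)
  centers[1, ] <- m[idx, ]
  d2 <- .sqdist_to(m, centers[1, ])
  if (k > 1) for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers[j, ] <- m[idx, ]
    d2 <- pmin(d2, .sqdist_to(m, centers[j, ]))
  }
  assign <- integer(n)
  for (it in seq_len(iter_max)) {
    d <- .sqdist_all(m, centers)
    new_assign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    repeat {
      empty <- which(tabulate(new_assign, nbins = k) == 0)
      if (length(empty) == 0) break
      far <- which.max(d[cbind(seq_len(n), new_assign)])
      centers[empty[1], ] <- m[far, ]
      d <- .sqdist_all(m, centers)
      new_assign <- max.col(-d, ties.method = "first")
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(m[new_assign == j, , drop = FALSE])
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  d <- .sqdist_all(m, centers)
  wss <- vapply(seq_len(k),
                function(j) sum(d[assign == j, j]), numeric(1))
  list(cluster = assign, centers = centers, withinss = wss,
       tot_withinss = sum(wss), iterations = it)
}

.sqdist_to <- function(m, center) {
  rowSums(sweep(m, 2, center)^2)
}

.sqdist_all <- function(m, centers) {
  # n x k matrix of squared Euclidean distances
  cross <- m %*% t(centers)
  sweep(sweep(-2 * cross, 2, rowSums(centers^2), `+`),
        1, rowSums(m^2), `+`)
}

#' Compare expression levels between two gene classes
#'
#' Summarizes each gene by its median expression across conditions and
#' compares the two classes of per-gene medians with a two-sided
#' Wilcoxon rank-sum (Mann-Whitney U) test. Classes must be disjoint.
#'
#' @param m Numeric matrix, genes x conditions.
#' @param classA,classB Character vectors of gene IDs present in `m`.
#' @return A list with `median_A`, `median_B` (median of the per-gene
#'   medians in each class), `n_A`, `n_B` and `p` (two-sided rank-sum
#'   p-value).
#' @export
class_expression_test <- function(m, classA, classB) {
  stopifnot(is.matrix(m))
  if (length(intersect(classA, classB)) > 0)
    stop("classes must be disjoint")
  a <- intersect(classA, rownames(m))
  b <- intersect(classB, rownames(m))
  if (length(a) == 0 || length(b) == 0)
    stop("both classes must be non-empty in the matrix")
  med <- apply(m, 1, median, na.rm = TRUE)
  w <- suppressWarnings(wilcox.test(med[a], med[b],
                                    alternative = "two.sided"))
  list(median_A = median(med[a]), median_B = median(med[b]),
       n_A = length(a), n_B = length(b), p = w$p.value)
}
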