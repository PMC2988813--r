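#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing `k` or more annotated genes in a
#' sample of `n` drawn without replacement from a universe of `N`
#' genes of which `K` carry the annotation. Computed in log space via
#' [stats::phyper()], numerically stable for universes well beyond
#' 10^4 genes.
#'
#' @param N Universe size.
#' @param K Annotated genes in the universe.
#' @param n Sample size.
#' @param k Annotated genes in the sample.
#' @return `P(X >= k)`, a single number in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1,
            k >= 0, k <= n, n <= N, K <= N, K >= 0)
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build an annotation map
#'
#' Indexes a gene-to-term annotation table (one row per gene/term
#' pair) into forward (gene -> terms) and inverse (term -> genes) maps
#' for one namespace.
#'
#' @param annotation Data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name` and `namespace` (see
#'   [read_annotation_table()]).
#' @param namespace Optional namespace to restrict to before indexing.
#' @return An object of class `"annotation_map"` with elements
#'   `gene2terms`, `term2genes`, `term_names` and `namespace`.
#' @export
annotation_map <- function(annotation, namespace = NULL) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  if (!is.null(namespace)) {
    stopifnot("namespace" %in% names(annotation))
    annotation <- annotation[annotation$namespace == namespace, , drop = FALSE]
  }
  annotation <- unique(annotation[, intersect(
    c("gene_id", "term_id", "term_name"), names(annotation)), drop = FALSE])
  term_names <- if ("term_name" %in% names(annotation))
    vapply(split(annotation$term_name, annotation$term_id),
           function(x) x[1], character(1))
  else setNames(unique(annotation$term_id), unique(annotation$term_id))
  structure(list(gene2terms = split(annotation$term_id, annotation$gene_id),
                 term2genes = split(annotation$gene_id, annotation$term_id),
                 term_names = term_names,
                 namespace = namespace),
            class = "annotation_map")
}

#' Hypergeometric term over-representation with Bonferroni correction
#'
#' Tests every annotation term with at least one hit in the sample for
#' over-representation against an explicit universe, using the exact
#' upper-tail hypergeometric probability. The Bonferroni multiplier is
#' the number of terms actually tested (those with >= 1 sample hit);
#' both the multiplier and the universe are logged so the convention
#' is always explicit.
#'
#' @param sample Character vector of gene IDs (must be a subset of
#'   `universe`).
#' @param annotation An `"annotation_map"` (or a data frame passed to
#'   [annotation_map()]).
#' @param cfg An [enrich_config()].
#' @param universe Character vector of gene IDs defining the
#'   background, e.g. all proteins on the array for Pfam-domain tests
#'   or all features with microarray data for GO tests over RIP-Chip
#'   targets.
#' @return A data frame sorted by raw p-value with columns `term_id`,
#'   `term_name`, `k` (hits in sample), `n` (sample size), `K` (hits
#'   in universe), `N` (universe size), `p_raw`, `p_corrected`,
#'   `significant`.
#' @export
enrich_terms <- function(sample, annotation, cfg = enrich_config(),
                         universe) {
  if (!inherits(annotation, "annotation_map"))
    annotation <- annotation_map(annotation)
  sample <- unique(sample); universe <- unique(universe)
  if (length(sample) == 0 || length(universe) == 0)
    stop("sample and universe must be non-empty")
  if (!all(sample %in% universe))
    stop("sample must be a subset of the universe (",
         sum(!sample %in% universe), " gene(s) outside)")
  N <- length(universe); n <- length(sample)
  term_genes_u <- lapply(annotation$term2genes, intersect, universe)
  k <- vapply(term_genes_u, function(g) sum(sample %in% g), integer(1))
  K <- lengths(term_genes_u)
  tested <- k >= 1 & K >= 1
  n_tested <- sum(tested)
  message("enrich_terms: N = ", N, ", n = ", n, ", terms tested = ",
          n_tested, " (Bonferroni multiplier)")
  p_raw <- mapply(function(K, k) hypergeom_upper_tail(N, K, n, k),
                  K[tested], k[tested])
  mult <- if (cfg$correction == "bonferroni") n_tested else 1
  res <- data.frame(term_id = names(term_genes_u)[tested],
                    term_name = unname(
                      annotation$term_names[names(term_genes_u)[tested]]),
                    k = unname(k[tested]), n = n, K = unname(K[tested]), N = N,
                    p_raw = unname(p_raw),
                    stringsAsFactors = FALSE)
  res$p_corrected <- pmin(1, res$p_raw * mult)
  res$significant <- res$p_corrected < cfg$alpha
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_terms_tested") <- n_tested
  res
}
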