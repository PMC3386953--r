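# Gene-set statistics: hypergeometric upper tail (computed in log space),
# splicing-factor "footprint" overlap testing, GO-style over-representation
# with a minimum-set-size filter and Benjamini-Hochberg correction, and the
# process-by-condition cross-tabulation.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` marked items. Terms are accumulated in
#' log space for numerical stability.
#'
#' @param N universe size.
#' @param K marked (target) items in the universe.
#' @param n items drawn (query size).
#' @param k observed overlap; must satisfy `0 <= k <= min(K, n)`.
#' @return The upper-tail probability; exactly 1 when `k = 0`.
#' @export
hypergeometric_upper_tail <- function(N, K, n, k) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L || length(k) != 1L)
    stop_config("hypergeometric_upper_tail takes scalar arguments")
  if (N < 0 || K < 0 || n < 0 || K > N || n > N)
    stop_config("need 0 <= K <= N and 0 <= n <= N (got N=%g K=%g n=%g)", N, K, n)
  if (k < 0 || k > min(K, n))
    stop_config("need 0 <= k <= min(K, n) (got k=%g)", k)
  if (k == 0) return(1)
  i <- seq.int(k, min(K, n))
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx) * sum(exp(lt - mx)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min over j >= i of min(1, p(j) * m / j)` after sorting
#' ascending; the original order is restored and ties are handled stably.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_config("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq.int(m, 1L)))
  q[order(o)]
}

#' Splicing-factor footprint overlap test
#'
#' Tests whether a splicing factor's known target genes are over-represented
#' among the query genes (typically the genes called alternatively spliced)
#' using the hypergeometric upper tail. Query and target sets are first
#' intersected with the stated gene universe; members outside the universe
#' are dropped and reported.
#'
#' @param query_genes character vector (e.g. AS-called genes).
#' @param target_set character vector of the factor's target genes.
#' @param universe_genes the gene universe (e.g. genes present in either
#'   compared condition). Must be supplied explicitly — the p-value is
#'   meaningless without a stated universe.
#' @return An `overlap_result` list: universe size `N`, in-universe target
#'   size `K`, query size `n`, overlap `k`, `expected` = `K*n/N`, `p`
#'   (upper tail), the overlapping `overlap_genes`, and counts of members
#'   dropped as outside the universe.
#' @export
footprint_overlap_test <- function(query_genes, target_set, universe_genes) {
  universe <- unique(as.character(universe_genes))
  if (!length(universe)) stop_data("empty gene universe")
  query <- unique(as.character(query_genes))
  target <- unique(as.character(target_set))
  dropped_query <- setdiff(query, universe)
  dropped_target <- setdiff(target, universe)
  if (length(dropped_query) || length(dropped_target))
    message(sprintf("footprint_overlap_test: dropped %d query / %d target gene(s) outside the universe",
                    length(dropped_query), length(dropped_target)))
  query <- intersect(query, universe)
  target <- intersect(target, universe)
  if (!length(query)) stop_data("query empty after universe intersection")
  if (!length(target)) stop_data("target set empty after universe intersection")
  overlap <- intersect(query, target)
  N <- length(universe); K <- length(target); n <- length(query)
  k <- length(overlap)
  structure(list(N = N, K = K, n = n, k = k,
                 expected = K * n / N,
                 p = hypergeometric_upper_tail(N, K, n, k),
                 overlap_genes = overlap,
                 dropped_query = dropped_query,
                 dropped_target = dropped_target),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: k = %d of K = %d targets in a query of n = %d (universe N = %d)\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("  expected %.2f, hypergeometric upper-tail p = %.4g\n",
              x$expected, x$p))
  if (length(x$overlap_genes))
    cat("  overlap:", paste(x$overlap_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Gene-set over-representation analysis
#'
#' One hypergeometric upper-tail test per gene set against the query, with
#' sets restricted to the universe first. Only sets with at least
#' `min_genes` members inside the universe are tested (the size filter
#' applies to the in-universe size, not the raw set size). Adjusted
#' p-values (BH by default) are computed across the surviving sets and rows
#' are sorted by adjusted p, then name.
#'
#' @param query_genes character vector; must be a subset of the universe.
#' @param sets a [gene_set_collection()].
#' @param universe_genes the gene universe.
#' @param min_genes minimum in-universe set size (default 10).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return An `enrichment_table` data.frame: `set_name`, `set_size`
#'   (in-universe), `hits`, `expected`, `p`, `adj_p`, `hit_genes`
#'   (comma-separated). Empty (with a warning) when no set survives the
#'   size filter.
#' @export
annotation_enrichment <- function(query_genes, sets, universe_genes,
                                  min_genes = 10L, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  universe <- unique(as.character(universe_genes))
  query <- unique(as.character(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_data("query gene(s) outside the universe: %s",
              paste(utils::head(outside, 5L), collapse = ", "))
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]]$genes, universe)
    if (length(members) < min_genes) next
    hits <- intersect(query, members)
    rows[[nm]] <- data.frame(
      set_name = nm,
      set_size = length(members),
      hits = length(hits),
      expected = length(members) * length(query) / length(universe),
      p = hypergeometric_upper_tail(length(universe), length(members),
                                    length(query), length(hits)),
      hit_genes = paste(sort(hits), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning(sprintf("no gene set has >= %d members in the universe", min_genes))
    out <- data.frame(set_name = character(0), set_size = integer(0),
                      hits = integer(0), expected = numeric(0),
                      p = numeric(0), adj_p = numeric(0),
                      hit_genes = character(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$adj_p <- if (adjust == "BH") bh_adjust(out$p) else pmin(1, out$p * nrow(out))
  out <- out[order(out$adj_p, out$set_name),
             c("set_name", "set_size", "hits", "expected", "p", "adj_p",
               "hit_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Cross-tabulate enrichment results across analyses
#'
#' Given enrichment tables from several labelled analyses (e.g. AS-called
#' vs transcription-called genes under two activation conditions), builds a
#' process-by-analysis matrix of adjusted p-values and flags the processes
#' appearing in exactly one analysis.
#'
#' @param enrichment_tables named list (>= 2) of `enrichment_table`s.
#' @param sentinel value used where a set did not survive in an analysis
#'   (default `NA`).
#' @return A data.frame with one row per set name in the union: one
#'   adjusted-p column per label, `n_analyses` and `unique_to` (the label,
#'   or `NA` when present in several).
#' @export
process_condition_matrix <- function(enrichment_tables, sentinel = NA_real_) {
  if (!is.list(enrichment_tables) || length(enrichment_tables) < 2L ||
      is.null(names(enrichment_tables)))
    stop_config("process_condition_matrix needs >= 2 labelled tables")
  labels <- names(enrichment_tables)
  all_sets <- sort(unique(unlist(lapply(enrichment_tables,
                                        function(t) t$set_name))))
  mat <- matrix(sentinel, length(all_sets), length(labels),
                dimnames = list(all_sets, labels))
  surviving <- matrix(FALSE, length(all_sets), length(labels),
                      dimnames = dimnames(mat))
  for (lab in labels) {
    t <- enrichment_tables[[lab]]
    mat[t$set_name, lab] <- t$adj_p
    surviving[t$set_name, lab] <- TRUE
  }
  n_analyses <- rowSums(surviving)
  unique_to <- ifelse(n_analyses == 1L,
                      labels[apply(surviving, 1L, which.max)],
                      NA_character_)
  data.frame(set_name = all_sets, mat, n_analyses = n_analyses,
             unique_to = unique_to, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}
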