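# Over-representation analysis of a gene list against a gene-set collection,
# with multiple-testing adjustment, top-k selection, and mapping onto a
# disease-associated pathway list.

#' Over-representation tail probability
#'
#' For an overlap of `k` genes between a query of size `n` and a gene set of
#' size `K` drawn from a universe of size `N`:
#' * `"hypergeometric"` — `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`;
#' * `"ease"` — the same upper tail evaluated at `max(k - 1, 0)`, the
#'   conservative one-removed variant of Fisher's exact test popularized by
#'   the DAVID annotation server (default, since the workflow this package
#'   re-implements relies on DAVID-style scores).
#'
#' `k = 0` gives exactly 1 under both methods.
#'
#' @param k overlap size.
#' @param K gene-set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @param method `"ease"` (default) or `"hypergeometric"`.
#' @return the tail probability in `(0, 1]`. Vectorized over `k`, `K`, `n`.
#' @export
#' @examples
#' overrep_pvalue(5, 5, 5, 20, method = "hypergeometric")  # 1/choose(20, 5)
#' overrep_pvalue(5, 5, 5, 20, method = "ease")
overrep_pvalue <- function(k, K, n, N, method = c("ease", "hypergeometric")) {
  method <- match.arg(method)
  stopifnot(length(N) == 1L, N >= 1)
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("require 0 <= k <= min(K, n), K <= N, n <= N", call. = FALSE)
  keff <- if (method == "ease") pmax(k - 1, 0) else k
  # P(X >= keff) = P(X > keff - 1)
  stats::phyper(keff - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' Tests the query gene list against every set in the collection. Query genes
#' outside the universe are dropped (count reported); only sets with at least
#' one overlapping gene are scored. Benjamini-Hochberg adjustment (if
#' requested) is applied across all scored sets. Results are sorted by
#' adjusted p, then raw p, then fold enrichment (descending), then set name,
#' so output order is deterministic.
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param universe_mode `"annotation"` (default; the union of all annotated
#'   genes in the collection) or `"custom"` (use `custom_universe`).
#' @param custom_universe explicit background gene list for
#'   `universe_mode = "custom"`.
#' @param method passed to [overrep_pvalue()].
#' @param adjust `"BH"` (default) or `"none"`.
#' @return a `data.frame` with columns `set_name`, `description`, `k`, `K`,
#'   `n`, `N`, `p_raw`, `p_adj`, `fold_enrichment`, `genes` (overlap,
#'   comma-separated).
#' @export
enrich <- function(query, collection,
                   universe_mode = c("annotation", "custom"),
                   custom_universe = NULL,
                   method = c("ease", "hypergeometric"),
                   adjust = c("BH", "none")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe_mode <- match.arg(universe_mode)
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  universe <- if (universe_mode == "annotation") collection$universe else {
    if (is.null(custom_universe))
      stop("custom_universe required when universe_mode = 'custom'",
           call. = FALSE)
    sort(unique(normalize_genes(custom_universe)))
  }
  query <- unique(normalize_genes(query))
  eff <- intersect(query, universe)
  dropped <- length(query) - length(eff)
  if (dropped > 0L)
    message(sprintf("enrich: %d query gene(s) outside the universe dropped",
                    dropped))
  if (!length(eff))
    stop("no query genes remain after intersecting with the universe",
         call. = FALSE)
  N <- length(universe)
  n <- length(eff)
  rows <- lapply(collection$sets, function(s) {
    members <- intersect(s$members, universe)
    hits <- intersect(eff, members)
    if (!length(hits)) return(NULL)
    k <- length(hits)
    K <- length(members)
    data.frame(set_name = s$name, description = s$description,
               k = k, K = K, n = n, N = N,
               p_raw = overrep_pvalue(k, K, n, N, method = method),
               fold_enrichment = (k / n) / (K / N),
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set_name = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      fold_enrichment = numeric(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- if (adjust == "BH")
    stats::p.adjust(res$p_raw, method = "BH") else res$p_raw
  res <- res[order(res$p_adj, res$p_raw, -res$fold_enrichment, res$set_name), ]
  rownames(res) <- NULL
  res[, c("set_name", "description", "k", "K", "n", "N", "p_raw", "p_adj",
          "fold_enrichment", "genes")]
}

#' Top significant pathways
#'
#' Filters enrichment results to those with p strictly below `alpha`
#' (adjusted p if `use_adjusted`) and returns the first `k` in the result's
#' sort order.
#'
#' @param results an [enrich()] result.
#' @param k maximum number of pathways (default 15).
#' @param alpha significance threshold, strict (default 0.05).
#' @param use_adjusted filter on `p_adj` (default) or `p_raw`.
#' @return the filtered, truncated `data.frame`.
#' @export
top_pathways <- function(results, k = 15L, alpha = 0.05, use_adjusted = TRUE) {
  stopifnot(is.data.frame(results), k >= 1, alpha > 0, alpha < 1)
  p <- if (use_adjusted) results$p_adj else results$p_raw
  utils::head(results[p < alpha, , drop = FALSE], k)
}

#' Map top pathways onto a disease-associated pathway list
#'
#' Case-insensitive exact-name intersection; the order of `top` is preserved.
#'
#' @param top a [top_pathways()] result (or any data frame with `set_name`).
#' @param disease_pathways character vector of disease-associated pathway
#'   names (or ids, when both sides carry ids).
#' @return the rows of `top` whose `set_name` appears in `disease_pathways`.
#' @export
map_disease_pathways <- function(top, disease_pathways) {
  stopifnot(is.data.frame(top), "set_name" %in% names(top))
  dz <- tolower(trimws(disease_pathways))
  out <- top[tolower(trimws(top$set_name)) %in% dz, , drop = FALSE]
  rownames(out) <- NULL
  out
}
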