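# Node centralities and the median-threshold key-target screen.
#
# Centralities are computed from scratch (single-source BFS + Brandes
# dependency accumulation) rather than delegated to a graph library, so the
# conventions below are explicit and testable against a brute-force oracle:
#   * degree        — number of incident edges (unweighted simple graph);
#   * betweenness   — fraction of all-pairs shortest paths passing through a
#                     node, normalized by the number of unordered pairs
#                     excluding the node, (N-1)(N-2)/2 (NetworkAnalyzer
#                     convention), hence in [0, 1];
#   * closeness     — reciprocal of the mean shortest-path distance to the
#                     nodes *reachable* from the node (component-wise), 0 for
#                     isolated nodes, hence in [0, 1].
# Edge confidence scores are ignored: all shortest paths are unweighted.

#' Degree, betweenness and closeness centralities
#'
#' @param net a non-empty igraph network.
#' @return a `data.frame` with one row per node and columns `gene`, `degree`,
#'   `betweenness`, `closeness`, in the network's vertex order.
#' @export
#' @examples
#' g <- igraph::make_graph(~ A - B - C - D - E)
#' centrality_table(g)
centrality_table <- function(net) {
  stopifnot(inherits(net, "igraph"))
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  adj <- lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
  deg <- lengths(adj)
  bc <- numeric(n)
  cc <- numeric(n)
  queue <- integer(n)
  stack <- integer(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)           # shortest-path counts
    preds <- vector("list", n)    # shortest-path predecessors
    dist[s] <- 0L
    sigma[s] <- 1
    queue[1L] <- s
    qh <- 1L; qt <- 1L; sp <- 0L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      sp <- sp + 1L; stack[sp] <- v
      dv1 <- dist[v] + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          qt <- qt + 1L
          queue[qt] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    reach <- dist > 0L
    cc[s] <- if (any(reach)) 1 / mean(dist[reach]) else 0
    delta <- numeric(n)
    if (sp > 1L) {
      for (i in sp:2L) {
        w <- stack[i]
        coef <- (1 + delta[w]) / sigma[w]
        for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
        bc[w] <- bc[w] + delta[w]
      }
    }
  }
  # each unordered pair contributed twice (once per endpoint as source)
  bc <- bc / 2
  if (n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  data.frame(gene = igraph::V(net)$name, degree = as.integer(deg),
             betweenness = bc, closeness = cc, stringsAsFactors = FALSE)
}

#' Median-threshold topological screen for key targets
#'
#' Key targets are the nodes whose degree strictly exceeds `degree_fold`
#' times the median degree of all nodes in the screened network, and whose
#' betweenness and closeness centralities strictly exceed the respective
#' medians. Medians over an even number of nodes are the mean of the two
#' middle values. The computed cutoffs are reported alongside the selection.
#'
#' @param table a [centrality_table()].
#' @param degree_fold multiplier applied to the median degree (default 2).
#' @return object of class `screening_result`: a list with `degree_cutoff`,
#'   `betweenness_cutoff`, `closeness_cutoff`, `key_targets` (sorted gene
#'   symbols), and `table` (the input with an added logical `is_key` column).
#' @export
screen_key_targets <- function(table, degree_fold = 2) {
  stopifnot(is.data.frame(table), nrow(table) > 0L,
            all(c("gene", "degree", "betweenness", "closeness") %in% names(table)),
            is.numeric(degree_fold), degree_fold > 0)
  dcut <- degree_fold * stats::median(table$degree)
  bcut <- stats::median(table$betweenness)
  ccut <- stats::median(table$closeness)
  is_key <- table$degree > dcut & table$betweenness > bcut &
    table$closeness > ccut
  out <- table
  out$is_key <- is_key
  structure(list(degree_cutoff = dcut, betweenness_cutoff = bcut,
                 closeness_cutoff = ccut,
                 key_targets = sort(table$gene[is_key]), table = out),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(paste0("screening_result: %d key target(s)\n",
                     "  cutoffs: degree > %g, betweenness > %g, closeness > %g\n"),
              length(x$key_targets), x$degree_cutoff, x$betweenness_cutoff,
              x$closeness_cutoff))
  invisible(x)
}

#' Aligned degree/betweenness series for profile plots
#'
#' Rows ordered by descending degree, ties broken lexicographically by gene
#' symbol — the ordering used for the paired degree/betweenness profile of
#' screened targets.
#'
#' @param table a [centrality_table()] (optionally subset to key targets).
#' @return a `data.frame` with columns `gene`, `degree`, `betweenness`.
#' @export
degree_betweenness_profile <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0L,
            all(c("gene", "degree", "betweenness") %in% names(table)))
  out <- table[order(-table$degree, table$gene),
               c("gene", "degree", "betweenness")]
  rownames(out) <- NULL
  out
}

#' Write a screening result to TSV + JSON
#'
#' @param result a [screen_key_targets()] result.
#' @param tsv_path output TSV (columns gene, degree, betweenness, closeness,
#'   is_key).
#' @param report_path optional JSON path for the cutoffs and key-target list.
#' @return `tsv_path`, invisibly.
#' @export
write_screening_result <- function(result, tsv_path, report_path = NULL) {
  stopifnot(inherits(result, "screening_result"))
  tab <- result$table
  tab$betweenness <- sprintf("%.8f", tab$betweenness)
  tab$closeness <- sprintf("%.8f", tab$closeness)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(degree_cutoff = result$degree_cutoff,
           betweenness_cutoff = result$betweenness_cutoff,
           closeness_cutoff = result$closeness_cutoff,
           key_targets = result$key_targets),
      report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
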