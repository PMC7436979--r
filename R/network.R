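# Construction of the compound-target / disease-target (CT-OT) interaction
# network and extraction of the common-target hub subnetwork.

#' Common targets of a compound map and a disease set
#'
#' The intersection of the union of all compound target sets with the disease
#' target gene set. An empty intersection is a valid (logged) result.
#'
#' @param ct a [compound_target_map()].
#' @param dt a [disease_target_set()].
#' @return sorted character vector of common gene symbols.
#' @export
common_targets <- function(ct, dt) {
  stopifnot(inherits(ct, "compound_target_map"),
            inherits(dt, "disease_target_set"))
  out <- sort(intersect(all_compound_targets(ct), dt$genes))
  if (!length(out))
    message("common_targets: compound and disease target sets are disjoint")
  out
}

#' Build the CT-OT interaction network
#'
#' Candidate nodes are the union of all compound targets and the disease
#' targets. Edges are the PPI edges with both endpoints among the candidates
#' and confidence strictly greater than `min_score`. Nodes left without any
#' surviving interaction are removed. Each retained node is labelled with a
#' role: `"common"` if it belongs to both target sets, else
#' `"compound_target"` or `"disease_target"`.
#'
#' @param ct a [compound_target_map()].
#' @param dt a [disease_target_set()].
#' @param ppi data frame of PPI edges with columns `a`, `b`, `score` (as
#'   returned by [read_ppi_edges()]; scores in `[0, 1]`).
#' @param min_score strict lower confidence bound (default 0.4).
#' @return an undirected igraph with vertex attribute `role` and edge
#'   attribute `score`; attribute `n_isolates_removed` records dropped nodes.
#' @export
build_ct_ot_network <- function(ct, dt, ppi, min_score = 0.4) {
  stopifnot(inherits(ct, "compound_target_map"),
            inherits(dt, "disease_target_set"),
            is.data.frame(ppi), all(c("a", "b", "score") %in% names(ppi)))
  ctg <- all_compound_targets(ct)
  candidates <- sort(union(ctg, dt$genes))
  if (!length(candidates)) stop("no targets supplied", call. = FALSE)
  common <- intersect(ctg, dt$genes)
  keep <- ppi$score > min_score & ppi$a %in% candidates & ppi$b %in% candidates
  edges <- ppi[keep, c("a", "b", "score"), drop = FALSE]
  role <- ifelse(candidates %in% common, "common",
                 ifelse(candidates %in% ctg, "compound_target",
                        "disease_target"))
  net <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = candidates, role = role,
                          stringsAsFactors = FALSE))
  net <- igraph::simplify(net, edge.attr.comb = list(score = "max"))
  remove_isolates(net)
}

#' Remove isolated nodes from a network
#'
#' Applied to every constructed network: targets without any interaction are
#' not informative for topology-based screening.
#'
#' @param net an igraph network.
#' @return the network without degree-zero vertices; the number removed is
#'   stored in the graph attribute `n_isolates_removed`.
#' @export
remove_isolates <- function(net) {
  iso <- which(igraph::degree(net) == 0L)
  if (length(iso)) {
    message(sprintf("removed %d isolated node(s)", length(iso)))
    net <- igraph::delete_vertices(net, iso)
  }
  igraph::set_graph_attr(net, "n_isolates_removed", length(iso))
}

#' Extract the hub subnetwork of seed nodes and their first neighbors
#'
#' Takes the induced subgraph on the seeds plus every node at graph distance 1
#' from a seed (so seed-seed, seed-neighbor and neighbor-neighbor edges are
#' all retained, mirroring selection-based subnetwork extraction in standard
#' network viewers), then removes isolated nodes. Seeds absent from the
#' network are dropped with a warning; an empty effective seed set is an
#' error.
#'
#' @param net an igraph network.
#' @param seeds character vector of gene symbols (typically the common
#'   targets).
#' @return the induced igraph subnetwork.
#' @export
extract_hub_network <- function(net, seeds) {
  stopifnot(inherits(net, "igraph"))
  seeds <- unique(normalize_genes(seeds))
  missing <- setdiff(seeds, igraph::V(net)$name)
  if (length(missing)) {
    warning(sprintf("dropping %d seed(s) absent from the network: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")),
            call. = FALSE)
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) stop("no seeds present in the network", call. = FALSE)
  vs <- igraph::V(net)[igraph::V(net)$name %in% seeds]
  nbr <- unique(unlist(igraph::adjacent_vertices(net, vs)))
  keep <- union(as.integer(vs), as.integer(nbr))
  sub <- igraph::induced_subgraph(net, keep)
  remove_isolates(sub)
}
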