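# Compound-level network assembly and docking-score post-processing.

#' Build the compound to key-target network
#'
#' Nodes are compounds plus targets: by default only the key targets
#' themselves (`retain = "key"`), optionally every hub-network target
#' (`retain = "hub"`). A compound-target edge is added wherever a compound's
#' predicted target set contains a retained target; PPI edges are the hub
#' edges induced on the retained targets. Compounds hitting no retained
#' target are excluded (count reported) and isolated nodes removed. Node
#' degree is stored in the vertex attribute `size` for renderers that scale
#' symbols by degree.
#'
#' @param ct a [compound_target_map()].
#' @param key character vector of key-target gene symbols (must intersect the
#'   hub network's nodes).
#' @param hub the hub igraph network (provides the PPI edges).
#' @param retain `"key"` (default) or `"hub"`.
#' @return an igraph with vertex attributes `type` (`"compound"`/`"target"`),
#'   `role`, and `size`; edge attribute `kind`
#'   (`"compound-target"`/`"ppi"`).
#' @export
build_compound_key_target_network <- function(ct, key, hub,
                                              retain = c("key", "hub")) {
  stopifnot(inherits(ct, "compound_target_map"), inherits(hub, "igraph"))
  retain <- match.arg(retain)
  key <- unique(normalize_genes(key))
  if (!length(key)) stop("empty key-target set", call. = FALSE)
  absent <- setdiff(key, igraph::V(hub)$name)
  if (length(absent)) {
    warning(sprintf("%d key target(s) absent from the hub network dropped",
                    length(absent)), call. = FALSE)
    key <- setdiff(key, absent)
  }
  if (!length(key)) stop("no key targets present in the hub network",
                         call. = FALSE)
  targets <- if (retain == "hub") igraph::V(hub)$name else key
  ppi <- igraph::as_data_frame(
    igraph::induced_subgraph(hub, igraph::V(hub)$name %in% targets),
    what = "edges")
  ct_edges <- do.call(rbind, lapply(names(ct$entries), function(cmp) {
    hit <- intersect(ct$entries[[cmp]], targets)
    if (!length(hit)) return(NULL)
    data.frame(from = cmp, to = hit, stringsAsFactors = FALSE)
  }))
  n_excluded <- sum(vapply(ct$entries,
                           function(g) !length(intersect(g, targets)), TRUE))
  if (n_excluded > 0L)
    message(sprintf("%d compound(s) with no retained target excluded",
                    n_excluded))
  if (is.null(ct_edges))
    stop("no compound targets any retained key target", call. = FALSE)
  edges <- rbind(
    data.frame(from = ct_edges$from, to = ct_edges$to,
               kind = "compound-target", stringsAsFactors = FALSE),
    if (nrow(ppi)) data.frame(from = ppi$from, to = ppi$to, kind = "ppi",
                              stringsAsFactors = FALSE))
  compounds <- unique(ct_edges$from)
  role <- vertex_attr_or(hub, "role", "unknown")
  names(role) <- igraph::V(hub)$name
  vertices <- data.frame(
    name = c(compounds, targets),
    type = c(rep("compound", length(compounds)),
             rep("target", length(targets))),
    role = c(rep("compound", length(compounds)),
             unname(role[targets])),
    stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vertices)
  net <- remove_isolates(net)
  igraph::set_vertex_attr(net, "size", value = igraph::degree(net))
}

#' Build a compound-target-pathway tripartite network
#'
#' Target nodes are the key targets belonging to at least one selected
#' pathway; a target-pathway edge is added for each membership, and a
#' compound-target edge wherever a compound's target set contains the target.
#' Compounds with no edge are dropped. Pathway-pathway and compound-pathway
#' edges never occur by construction, and the endpoint types of every edge
#' are validated before returning.
#'
#' @param ct a [compound_target_map()].
#' @param key character vector of key-target gene symbols.
#' @param pathway_membership named list: pathway name -> character vector of
#'   member genes, or a [gene_set_collection()].
#' @param selected_pathways character vector of pathway names to include
#'   (must all be present in `pathway_membership`).
#' @return an igraph with vertex attribute `type` in
#'   `{"compound", "target", "pathway"}` and edge attribute `kind` in
#'   `{"compound-target", "target-pathway"}`.
#' @export
build_ctp_network <- function(ct, key, pathway_membership, selected_pathways) {
  stopifnot(inherits(ct, "compound_target_map"))
  if (inherits(pathway_membership, "gene_set_collection"))
    pathway_membership <- lapply(pathway_membership$sets, `[[`, "members")
  stopifnot(is.list(pathway_membership), !is.null(names(pathway_membership)))
  if (!length(selected_pathways))
    stop("no pathways selected", call. = FALSE)
  missing <- setdiff(selected_pathways, names(pathway_membership))
  if (length(missing))
    stop(sprintf("selected pathway(s) absent from membership: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  key <- unique(normalize_genes(key))
  tp_edges <- do.call(rbind, lapply(selected_pathways, function(pw) {
    members <- intersect(key, normalize_genes(pathway_membership[[pw]]))
    if (!length(members)) return(NULL)
    data.frame(from = members, to = pw, stringsAsFactors = FALSE)
  }))
  if (is.null(tp_edges))
    stop("no key target belongs to any selected pathway", call. = FALSE)
  targets <- unique(tp_edges$from)
  ct_edges <- do.call(rbind, lapply(names(ct$entries), function(cmp) {
    hit <- intersect(ct$entries[[cmp]], targets)
    if (!length(hit)) return(NULL)
    data.frame(from = cmp, to = hit, stringsAsFactors = FALSE)
  }))
  compounds <- if (is.null(ct_edges)) character() else unique(ct_edges$from)
  edges <- rbind(
    if (!is.null(ct_edges))
      data.frame(from = ct_edges$from, to = ct_edges$to,
                 kind = "compound-target", stringsAsFactors = FALSE),
    data.frame(from = tp_edges$from, to = tp_edges$to,
               kind = "target-pathway", stringsAsFactors = FALSE))
  vertices <- data.frame(
    name = c(compounds, targets, unique(tp_edges$to)),
    type = c(rep("compound", length(compounds)),
             rep("target", length(targets)),
             rep("pathway", length(unique(tp_edges$to)))),
    stringsAsFactors = FALSE)
  net <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vertices)
  validate_tripartite(net)
  net
}

#' Validate tripartite edge-type safety
#'
#' Checks that every edge's endpoint types match its `kind`: compound-target
#' edges join a compound to a target, target-pathway edges a target to a
#' pathway, and `ppi` edges two targets. Called by the builders; exported so
#' tests and downstream code can re-verify any network.
#'
#' @param net an igraph with vertex attribute `type` and edge attribute
#'   `kind`.
#' @return `TRUE` invisibly; errors on a violation.
#' @export
validate_tripartite <- function(net) {
  el <- igraph::as_data_frame(net, what = "edges")
  type <- igraph::V(net)$type
  names(type) <- igraph::V(net)$name
  pair <- paste(pmin(type[el$from], type[el$to]),
                pmax(type[el$from], type[el$to]), sep = "|")
  ok <- (el$kind == "compound-target" & pair == "compound|target") |
    (el$kind == "target-pathway" & pair == "pathway|target") |
    (el$kind == "ppi" & pair == "target|target")
  if (!all(ok))
    stop("tripartite type violation: edge kind does not match endpoint types",
         call. = FALSE)
  invisible(TRUE)
}

#' Ligand-normalized docking-score ratios
#'
#' For every non-ligand (molecule, target) record, the ratio of the
#' molecule's docking score to the score of that target's original ligand.
#' Missing docking scores (no pose generated) propagate as missing cells.
#' Each ratio is categorized with half-open intervals at the configured
#' cutoffs: `weak` below `cutoffs[1]`, `moderate` in
#' `[cutoffs[1], cutoffs[2])`, `strong` at or above `cutoffs[2]`, and `none`
#' for missing cells. The default bands (0.8, 1.0) are a package convention —
#' a ratio at or above the original ligand's score is called strong.
#'
#' @param table a [docking_table()].
#' @param cutoffs numeric length-2 increasing vector: (weak/moderate,
#'   moderate/strong) boundaries. Default `c(0.8, 1.0)`.
#' @return object of class `docking_ratio_matrix`: a list with `ratios`
#'   (compound x target numeric matrix, `NA` = missing), `categories`
#'   (character matrix, same shape), `cutoffs`, and `ligand_scores`.
#' @export
docking_ratios <- function(table, cutoffs = c(0.8, 1.0)) {
  stopifnot(inherits(table, "docking_table"),
            length(cutoffs) == 2L, cutoffs[1] < cutoffs[2])
  df <- as.data.frame(table)
  lig <- df[df$is_ligand, , drop = FALSE]
  bad <- lig$target[lig$score <= 0]
  if (length(bad))
    stop(sprintf("non-positive ligand score for target(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  baseline <- stats::setNames(lig$score, lig$target)
  cmp <- df[!df$is_ligand, , drop = FALSE]
  compounds <- unique(cmp$molecule)
  targets <- unique(df$target)
  ratios <- matrix(NA_real_, length(compounds), length(targets),
                   dimnames = list(compounds, targets))
  idx <- cbind(match(cmp$molecule, compounds), match(cmp$target, targets))
  ratios[idx] <- cmp$score / baseline[cmp$target]
  categories <- matrix("none", length(compounds), length(targets),
                       dimnames = dimnames(ratios))
  categories[!is.na(ratios) & ratios < cutoffs[1]] <- "weak"
  categories[!is.na(ratios) & ratios >= cutoffs[1] & ratios < cutoffs[2]] <-
    "moderate"
  categories[!is.na(ratios) & ratios >= cutoffs[2]] <- "strong"
  structure(list(ratios = ratios, categories = categories, cutoffs = cutoffs,
                 ligand_scores = baseline),
            class = "docking_ratio_matrix")
}

#' @export
print.docking_ratio_matrix <- function(x, ...) {
  cat(sprintf("docking_ratio_matrix: %d compounds x %d targets (%d missing)\n",
              nrow(x$ratios), ncol(x$ratios), sum(is.na(x$ratios))))
  invisible(x)
}

#' Render the docking-ratio heat map and its CSV twin
#'
#' Rows are compounds, columns targets, in input order (no clustering by
#' default). Missing cells are drawn in a neutral grey; the CSV twin is
#' always written so the numbers behind the figure are machine-readable.
#' All-missing columns are rendered and flagged with a message.
#'
#' @param matrix a [docking_ratios()] result.
#' @param image_path output image path (`.png` or `.pdf`).
#' @param csv_path output CSV path; defaults to `image_path` with a `.csv`
#'   extension.
#' @param cluster cluster rows/columns (default `FALSE`).
#' @return named list of the written paths, invisibly.
#' @export
ratio_heatmap <- function(matrix, image_path,
                          csv_path = sub("\\.[A-Za-z]+$", ".csv", image_path),
                          cluster = FALSE) {
  stopifnot(inherits(matrix, "docking_ratio_matrix"))
  m <- matrix$ratios
  utils::write.csv(m, csv_path, row.names = TRUE, na = "")
  empty_cols <- colnames(m)[colSums(!is.na(m)) == 0L]
  if (length(empty_cols))
    message(sprintf("ratio_heatmap: all-missing column(s): %s",
                    paste(empty_cols, collapse = ", ")))
  if (any(is.finite(m))) {
    pheatmap::pheatmap(
      m, cluster_rows = cluster, cluster_cols = cluster,
      color = grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(51),
      na_col = "#BBBBBB", filename = image_path, silent = TRUE)
  } else {
    # degenerate all-missing matrix: emit a blank placeholder panel
    if (grepl("\\.pdf$", image_path)) grDevices::pdf(image_path)
    else grDevices::png(image_path)
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no docking results")
    grDevices::dev.off()
  }
  invisible(list(image = image_path, csv = csv_path))
}
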