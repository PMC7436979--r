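# Readers and writers for the tabular and graph formats the pipeline touches,
# plus constructors for the shared in-memory containers.

#' Construct a compound-to-target map
#'
#' @param entries named list: compound id -> character vector of gene symbols.
#' @param provenance optional data frame with columns `compound`, `gene`,
#'   `source` recording which database tag supported each association.
#' @return object of class `compound_target_map` with deduplicated, sorted,
#'   normalized target sets.
#' @export
compound_target_map <- function(entries, provenance = NULL) {
  stopifnot(is.list(entries))
  if (length(entries) && is.null(names(entries)))
    stop("entries must be a named list keyed by compound id", call. = FALSE)
  entries <- lapply(entries, function(g) sort(unique(normalize_genes(g))))
  if (is.null(provenance)) {
    provenance <- data.frame(compound = character(), gene = character(),
                             source = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("compound", "gene", "source") %in% names(provenance)))
    provenance$gene <- normalize_genes(provenance$gene)
    provenance <- unique(provenance[, c("compound", "gene", "source")])
    known <- paste(provenance$compound,
                   provenance$gene) %in%
      paste(rep(names(entries), lengths(entries)), unlist(entries))
    if (!all(known))
      stop("provenance refers to (compound, gene) pairs absent from entries",
           call. = FALSE)
  }
  structure(list(entries = entries, provenance = provenance),
            class = "compound_target_map")
}

#' @export
print.compound_target_map <- function(x, ...) {
  cat(sprintf("compound_target_map: %d compounds, %d distinct targets\n",
              length(x$entries), length(all_compound_targets(x))))
  invisible(x)
}

#' Union of all compound target sets
#'
#' @param ct a [compound_target_map()].
#' @return sorted character vector of distinct gene symbols.
#' @export
all_compound_targets <- function(ct) {
  stopifnot(inherits(ct, "compound_target_map"))
  sort(unique(unlist(ct$entries, use.names = FALSE)))
}

#' Construct a disease target set
#'
#' @param genes character vector of gene symbols.
#' @param provenance optional data frame with columns `gene`, `source`.
#' @return object of class `disease_target_set`.
#' @export
disease_target_set <- function(genes, provenance = NULL) {
  genes <- sort(unique(normalize_genes(genes)))
  if (is.null(provenance)) {
    provenance <- data.frame(gene = character(), source = character(),
                             stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene", "source") %in% names(provenance)))
    provenance$gene <- normalize_genes(provenance$gene)
    provenance <- unique(provenance[, c("gene", "source")])
  }
  structure(list(genes = genes, provenance = provenance),
            class = "disease_target_set")
}

#' @export
print.disease_target_set <- function(x, ...) {
  cat(sprintf("disease_target_set: %d genes\n", length(x$genes)))
  invisible(x)
}

#' Read a compound-target association table
#'
#' Accepts TSV/CSV tables with one (compound, gene) association per row and an
#' optional source-database column. Symbols are uppercased and trimmed,
#' duplicate associations merged with the union of their source tags, and rows
#' with a blank gene cell skipped (count reported via a message).
#'
#' @param path file path.
#' @param dialect optional named list mapping the roles `compound`, `gene`,
#'   `source` to column names in the file; by default conventional names are
#'   matched case-insensitively (`compound`/`compound_id`/`molecule`,
#'   `gene`/`target`/`symbol`/`gene_symbol`, `source`/`database`/`db`).
#' @return a [compound_target_map()]. An empty file yields an empty map with a
#'   warning, not an error.
#' @export
read_compound_targets <- function(path, dialect = NULL) {
  stopifnot(file.exists(path))
  df <- read_table_auto(path)
  if (nrow(df) == 0L) {
    warning(sprintf("'%s' contains no associations; returning an empty map",
                    path), call. = FALSE)
    return(compound_target_map(structure(list(), names = character())))
  }
  ccol <- find_column(df, dialect$compound %||%
                        c("compound", "compound_id", "molecule"), "compound")
  gcol <- find_column(df, dialect$gene %||%
                        c("gene", "target", "symbol", "gene_symbol"), "gene")
  scol <- find_column(df, dialect$source %||% c("source", "database", "db"),
                      "source", required = FALSE)
  compound <- trimws(as.character(df[[ccol]]))
  gene <- trimws(as.character(df[[gcol]]))
  keep <- !is.na(gene) & gene != "" & !is.na(compound) & compound != ""
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message(sprintf("read_compound_targets: skipped %d row(s) with blank cells",
                    n_skipped))
  compound <- compound[keep]
  gene <- normalize_genes(gene[keep])
  source <- if (is.null(scol)) rep("unspecified", length(gene)) else
    trimws(as.character(df[[scol]]))[keep]
  entries <- lapply(split(gene, compound), function(g) sort(unique(g)))
  prov <- unique(data.frame(compound = compound, gene = gene, source = source,
                            stringsAsFactors = FALSE))
  compound_target_map(entries, prov)
}

#' Read a disease target gene list
#'
#' Accepts either a plain list (one symbol per line, an optional header line
#' named `gene`/`symbol`/`target` is skipped) or a TSV/CSV table with a gene
#' column and optional source column.
#'
#' @inheritParams read_compound_targets
#' @return a [disease_target_set()]. An empty file yields an empty set with a
#'   warning.
#' @export
read_disease_targets <- function(path, dialect = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("[\t,]", first)) {
    df <- read_table_auto(path)
    if (nrow(df) == 0L) {
      warning(sprintf("'%s' is empty; returning an empty target set", path),
              call. = FALSE)
      return(disease_target_set(character()))
    }
    gcol <- find_column(df, dialect$gene %||%
                          c("gene", "target", "symbol", "gene_symbol"), "gene")
    scol <- find_column(df, dialect$source %||% c("source", "database", "db"),
                        "source", required = FALSE)
    gene <- trimws(as.character(df[[gcol]]))
    keep <- !is.na(gene) & gene != ""
    if (any(!keep))
      message(sprintf("read_disease_targets: skipped %d blank row(s)",
                      sum(!keep)))
    gene <- normalize_genes(gene[keep])
    source <- if (is.null(scol)) rep("unspecified", length(gene)) else
      trimws(as.character(df[[scol]]))[keep]
    return(disease_target_set(gene, data.frame(gene = gene, source = source,
                                               stringsAsFactors = FALSE)))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  if (length(lines) &&
      tolower(lines[1L]) %in% c("gene", "symbol", "target", "gene_symbol"))
    lines <- lines[-1L]
  if (!length(lines)) {
    warning(sprintf("'%s' is empty; returning an empty target set", path),
            call. = FALSE)
    return(disease_target_set(character()))
  }
  disease_target_set(normalize_genes(lines))
}

#' Read a STRING-style PPI edge list
#'
#' Expects a TSV with two node columns and a combined confidence score. The
#' score scale is auto-detected: if any value exceeds 1 the column is treated
#' as the 0-1000 export dialect and divided by 1000; values above 1000 are an
#' error unless `scale` is given explicitly. Self-loops are dropped (count
#' reported), duplicate unordered pairs collapsed keeping the maximum score,
#' and only edges with score strictly greater than `min_score` kept.
#'
#' @param path file path.
#' @param min_score confidence threshold in `[0, 1]`; edges must exceed it
#'   strictly (default 0.4, the conventional medium-confidence cut).
#' @param scale `"auto"` (default), `"unit"` for scores already in `[0, 1]`,
#'   or `"thousand"` for the 0-1000 export dialect.
#' @return data frame with columns `a`, `b`, `score` (normalized to `[0, 1]`,
#'   canonicalized so `a < b`), with attributes `n_self_loops` and
#'   `n_duplicates` recording dropped rows.
#' @export
read_ppi_edges <- function(path, min_score = 0.4,
                           scale = c("auto", "unit", "thousand")) {
  stopifnot(file.exists(path), min_score >= 0, min_score <= 1)
  scale <- match.arg(scale)
  df <- read_table_auto(path)
  n1 <- find_column(df, c("node1", "protein1", "from", "a", "source_node"),
                    "node1")
  n2 <- find_column(df, c("node2", "protein2", "to", "b", "target_node"),
                    "node2")
  sc <- find_column(df, c("combined_score", "score", "weight", "confidence"),
                    "combined_score")
  a <- normalize_genes(df[[n1]], drop_invalid = FALSE)
  b <- normalize_genes(df[[n2]], drop_invalid = FALSE)
  score <- as.numeric(df[[sc]])
  if (anyNA(score)) stop("non-numeric confidence scores", call. = FALSE)
  if (scale == "auto") {
    if (any(score > 1000))
      stop("scores exceed 1000; pass scale = 'unit' or 'thousand' explicitly",
           call. = FALSE)
    scale <- if (any(score > 1)) "thousand" else "unit"
  }
  if (scale == "thousand") score <- score / 1000
  if (any(score < 0) || any(score > 1))
    stop("confidence scores outside [0, 1] after normalization", call. = FALSE)
  ppi_edges(a, b, score, min_score = min_score)
}

# Canonicalize an edge table: drop self-loops (logged), collapse duplicate
# unordered pairs keeping the max score, apply the strict score filter.
ppi_edges <- function(a, b, score, min_score = 0) {
  self <- a == b
  if (any(self))
    message(sprintf("dropped %d self-loop(s)", sum(self)))
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  score <- score[!self]
  key <- paste(a2, b2, sep = "\r")
  n_dup <- length(key) - length(unique(key))
  if (n_dup > 0L) {
    score <- tapply(score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    a2 <- vapply(parts, `[[`, "", 1L)
    b2 <- vapply(parts, `[[`, "", 2L)
    score <- unname(score)
  }
  keep <- score > min_score
  out <- data.frame(a = a2[keep], b = b2[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- sum(self)
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element a list with fields `name`,
#'   `description`, `members` (character vector of gene symbols), or simply a
#'   character vector of members (name taken from the list name, empty
#'   description).
#' @param universe optional background gene universe. Defaults to the union
#'   of all member sets ("annotation" universe).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets)))
    stop("sets must be named", call. = FALSE)
  sets <- mapply(function(s, nm) {
    if (is.character(s)) s <- list(name = nm, description = "", members = s)
    stopifnot(is.list(s), !is.null(s$members))
    s$name <- s$name %||% nm
    s$description <- s$description %||% ""
    s$members <- sort(unique(normalize_genes(s$members)))
    if (!length(s$members)) stop("gene set '", nm, "' is empty", call. = FALSE)
    s
  }, sets, names(sets), SIMPLIFY = FALSE)
  annotated <- sort(unique(unlist(lapply(sets, `[[`, "members"))))
  if (is.null(universe)) universe <- annotated
  else universe <- sort(unique(normalize_genes(universe)))
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT format: one set per line, tab-separated fields
#' `name`, `description`, then member genes.
#'
#' @param path file path.
#' @return a [gene_set_collection()] with the annotation universe.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields",
                   i), call. = FALSE)
    sets[[f[1L]]] <- list(name = f[1L], description = f[2L],
                          members = f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease-pathway list
#'
#' One pathway name (or id) per line; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of pathway names.
#' @export
read_pathway_list <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines[lines != ""]
}

#' Construct a docking-score table
#'
#' Each record is a (molecule, target) pair with a docking score (arbitrary
#' positive units) or `NA` for pairs where no pose could be generated —
#' missingness is distinct from a zero score. Every target must carry exactly
#' one ligand-flagged row (its original co-crystallized ligand) with a present
#' score; those rows provide the normalization baseline.
#'
#' @param records data frame with columns `molecule`, `target`, `score`,
#'   `is_ligand`.
#' @return object of class `docking_table`.
#' @export
docking_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("molecule", "target", "score", "is_ligand") %in% names(records)))
  records$molecule <- as.character(records$molecule)
  records$target <- normalize_genes(records$target, drop_invalid = FALSE)
  records$score <- as.numeric(records$score)
  records$is_ligand <- as.logical(records$is_ligand)
  if (anyNA(records$is_ligand))
    stop("is_ligand must be TRUE/FALSE", call. = FALSE)
  if (anyDuplicated(records[, c("molecule", "target")]))
    stop("duplicate (molecule, target) records", call. = FALSE)
  for (tg in unique(records$target)) {
    lig <- records[records$target == tg & records$is_ligand, , drop = FALSE]
    if (nrow(lig) != 1L)
      stop(sprintf("target %s must have exactly one ligand row (found %d)",
                   tg, nrow(lig)), call. = FALSE)
    if (is.na(lig$score))
      stop(sprintf("ligand score for target %s is missing", tg), call. = FALSE)
  }
  structure(records, class = c("docking_table", "data.frame"))
}

#' Read a docking-score table from CSV
#'
#' Expected columns: `molecule`, `target`, `score`, `is_ligand`. Blank score
#' cells become missing values (`NA`), never zero.
#'
#' @param path CSV file path.
#' @return a [docking_table()].
#' @export
read_docking_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  m <- find_column(df, c("molecule", "compound", "ligand_id"), "molecule")
  t <- find_column(df, c("target", "receptor", "protein"), "target")
  s <- find_column(df, c("score", "libdockscore", "docking_score"), "score")
  l <- find_column(df, c("is_ligand", "ligand", "original_ligand"), "is_ligand")
  docking_table(data.frame(molecule = df[[m]], target = df[[t]],
                           score = suppressWarnings(as.numeric(df[[s]])),
                           is_ligand = df[[l]] %in% c(TRUE, "TRUE", "true", 1, "1", "yes"),
                           stringsAsFactors = FALSE))
}

#' Write a docking-score table to CSV
#'
#' @param table a [docking_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_docking_table <- function(table, path) {
  df <- as.data.frame(table)
  df$score <- ifelse(is.na(df$score), "", sprintf("%.4f", df$score))
  df$is_ligand <- ifelse(df$is_ligand, "TRUE", "FALSE")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interaction network to disk
#'
#' @param net an igraph interaction network (vertex attributes `name`, `role`;
#'   edge attribute `score`).
#' @param path output path. For `format = "tsv"` the path is used as a prefix:
#'   `<path>_edges.tsv` and `<path>_nodes.tsv` are written.
#' @param format `"graphml"` (lossless, default), `"tsv"` (lossless node and
#'   edge tables), or `"sif"` (Cytoscape simple-interaction format; scores and
#'   roles are not representable and are dropped).
#' @return the main file path written, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv", "sif")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "igraph"))
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(gene = igraph::V(net)$name,
                      role = vertex_attr_or(net, "role", "unknown"),
                      stringsAsFactors = FALSE)
  edges <- igraph::as_data_frame(net, what = "edges")
  if (format == "tsv") {
    ef <- paste0(path, "_edges.tsv")
    nf <- paste0(path, "_nodes.tsv")
    edges_out <- data.frame(a = edges$from, b = edges$to,
                            score = sprintf("%.6f", edges$score))
    utils::write.table(edges_out, ef, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(nodes, nf, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ef))
  }
  # SIF: connected pairs as "a pp b"; isolated nodes as bare names
  lines <- if (nrow(edges)) paste(edges$from, "pp", edges$to) else character()
  iso <- setdiff(nodes$gene, unique(c(edges$from, edges$to)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read an interaction network from disk
#'
#' @param path path written by [write_network()] (for `"tsv"`, the same
#'   prefix).
#' @param format `"graphml"` or `"tsv"`.
#' @return an igraph network with vertex `role` and edge `score` attributes.
#' @export
read_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    net <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::vertex_attr(net, "id")))
      net <- igraph::delete_vertex_attr(net, "id")
    return(net)
  }
  edges <- utils::read.table(paste0(path, "_edges.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  nodes <- utils::read.table(paste0(path, "_nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes$gene,
                                                      role = nodes$role))
}

vertex_attr_or <- function(net, attr, default) {
  v <- igraph::vertex_attr(net, attr)
  if (is.null(v)) rep(default, igraph::vcount(net)) else v
}
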