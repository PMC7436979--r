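# Seeded synthetic-data generators. These emulate the statistical structure
# the screening pipeline assumes — a heavy-tailed PPI graph whose hubs carry
# the signal, compound/disease target sets sharing a small planted common
# core located at those hubs, a gene-set collection with one planted
# over-represented set, and a docking table with designated above-baseline
# pairs — so every stage is exercisable offline and planted structure can be
# recovered. Every generator is a pure function of (config, seed).

#' Synthetic-dataset configuration
#'
#' Defaults describe the scale of the study the pipeline re-implements:
#' 16 compounds with ~20 predicted targets each, ~60 disease genes, a
#' 500-gene interactome, a handful of true hub targets shared by both sides,
#' and a 16 x 13 docking panel.
#'
#' @param n_genes interactome size.
#' @param attach_m preferential-attachment edges per new node.
#' @param n_compounds number of compounds.
#' @param targets_per_compound predicted targets per compound.
#' @param n_disease_targets disease target-set size.
#' @param n_planted_hubs number of planted hub targets.
#' @param hub_inclusion_prob probability a planted hub enters each target set.
#' @param n_genesets number of gene sets in the collection.
#' @param geneset_size_range inclusive (min, max) gene-set size.
#' @param planted_set_overlap fraction of planted hubs placed in the planted
#'   gene set.
#' @param n_dock_targets number of docking targets.
#' @param strong_pair_fraction fraction of compound-target docking cells
#'   designated strong (score above the ligand baseline).
#' @param missing_fraction fraction of non-ligand docking cells with no
#'   docking result.
#' @param seed integer master seed.
#' @return a named list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L, attach_m = 2L, n_compounds = 16L,
                             targets_per_compound = 20L,
                             n_disease_targets = 60L, n_planted_hubs = 6L,
                             hub_inclusion_prob = 0.9, n_genesets = 20L,
                             geneset_size_range = c(10L, 40L),
                             planted_set_overlap = 1.0, n_dock_targets = 13L,
                             strong_pair_fraction = 0.2,
                             missing_fraction = 0.05, seed = 0L) {
  cfg <- list(n_genes = as.integer(n_genes), attach_m = as.integer(attach_m),
              n_compounds = as.integer(n_compounds),
              targets_per_compound = as.integer(targets_per_compound),
              n_disease_targets = as.integer(n_disease_targets),
              n_planted_hubs = as.integer(n_planted_hubs),
              hub_inclusion_prob = hub_inclusion_prob,
              n_genesets = as.integer(n_genesets),
              geneset_size_range = as.integer(geneset_size_range),
              planted_set_overlap = planted_set_overlap,
              n_dock_targets = as.integer(n_dock_targets),
              strong_pair_fraction = strong_pair_fraction,
              missing_fraction = missing_fraction, seed = as.integer(seed))
  counts <- c("n_genes", "attach_m", "n_compounds", "targets_per_compound",
              "n_disease_targets", "n_planted_hubs", "n_genesets",
              "n_dock_targets")
  stopifnot(all(unlist(cfg[counts]) > 0L),
            length(cfg$geneset_size_range) == 2L,
            cfg$geneset_size_range[1] <= cfg$geneset_size_range[2],
            cfg$hub_inclusion_prob >= 0, cfg$hub_inclusion_prob <= 1,
            cfg$planted_set_overlap >= 0, cfg$planted_set_overlap <= 1,
            cfg$strong_pair_fraction >= 0, cfg$strong_pair_fraction <= 1,
            cfg$missing_fraction >= 0, cfg$missing_fraction <= 1,
            cfg$n_planted_hubs < cfg$n_genes)
  structure(cfg, class = c("synthetic_config", "list"))
}

synthetic_gene_names <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a scale-free PPI edge list by preferential attachment
#'
#' The seed graph is a star on `m + 1` nodes (node 1 the center); every
#' subsequent node attaches to `m` distinct existing nodes with probability
#' proportional to their current degree. The construction forces exactly
#' `m * (n - m)` edges. Confidence scores are drawn Uniform(0.41, 1), so all
#' edges pass the conventional 0.4 filter.
#'
#' @param n number of genes (`n > m`).
#' @param m edges attached per new node (`m >= 1`).
#' @param seed integer seed; the output is a pure function of `(n, m, seed)`.
#' @return data frame with columns `a`, `b`, `score` (`a < b` by node id).
#' @export
generate_ppi <- function(n, m, seed) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (n <= m) stop("n must exceed m", call. = FALSE)
  with_local_seed(seed, {
    n_edges <- m * (n - m)
    from <- integer(n_edges)
    to <- integer(n_edges)
    deg <- integer(n)
    # star seed: center 1, leaves 2..m+1
    k <- m
    from[seq_len(m)] <- 1L
    to[seq_len(m)] <- seq_len(m) + 1L
    deg[1L] <- m
    deg[2:(m + 1L)] <- 1L
    if (n > m + 1L) {
      for (v in (m + 2L):n) {
        existing <- seq_len(v - 1L)
        tgt <- sample(existing, m, prob = deg[existing])
        from[k + seq_len(m)] <- tgt
        to[k + seq_len(m)] <- v
        deg[tgt] <- deg[tgt] + 1L
        deg[v] <- m
        k <- k + m
      }
    }
    genes <- synthetic_gene_names(n)
    data.frame(a = genes[pmin(from, to)], b = genes[pmax(from, to)],
               score = stats::runif(n_edges, 0.41, 1.0),
               stringsAsFactors = FALSE)
  })
}

# Highest-degree nodes of an edge list, ties broken by gene id.
planted_hub_genes <- function(ppi, n_genes, n_hubs) {
  genes <- synthetic_gene_names(n_genes)
  deg <- table(factor(c(ppi$a, ppi$b), levels = genes))
  genes[order(-as.integer(deg), genes)][seq_len(n_hubs)]
}

#' Generate compound and disease target sets around planted hubs
#'
#' The planted hubs are the `n_planted_hubs` highest-degree genes of the PPI
#' graph (ties by gene id). Each compound's target set includes each hub
#' independently with probability `hub_inclusion_prob` and is filled with
#' uniformly drawn non-hub genes up to `targets_per_compound`; the disease
#' set is built the same way up to `n_disease_targets`. The truth record's
#' `common` field lists the hubs present both in some compound set and in the
#' disease set.
#'
#' @param ppi a [generate_ppi()] edge list.
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `ct` ([compound_target_map()]), `dt`
#'   ([disease_target_set()]), and `truth` (list with `planted_hubs`,
#'   `common`).
#' @export
generate_targets <- function(ppi, config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$targets_per_compound > config$n_genes)
    stop("targets_per_compound exceeds the gene pool", call. = FALSE)
  genes <- synthetic_gene_names(config$n_genes)
  hubs <- planted_hub_genes(ppi, config$n_genes, config$n_planted_hubs)
  pool <- setdiff(genes, hubs)
  with_local_seed(seed, {
    draw_set <- function(size) {
      incl <- hubs[stats::runif(length(hubs)) < config$hub_inclusion_prob]
      n_fill <- max(size - length(incl), 0L)
      sort(c(incl, sample(pool, n_fill)))
    }
    entries <- lapply(seq_len(config$n_compounds),
                      function(i) draw_set(config$targets_per_compound))
    names(entries) <- sprintf("CMP%02d", seq_len(config$n_compounds))
    dz <- draw_set(config$n_disease_targets)
    ct <- compound_target_map(entries)
    dt <- disease_target_set(dz)
    truth <- list(planted_hubs = hubs,
                  common = hubs[hubs %in% all_compound_targets(ct) &
                                  hubs %in% dt$genes])
    list(ct = ct, dt = dt, truth = truth)
  })
}

#' Generate a gene-set collection with one planted over-represented set
#'
#' The planted set (`PW_PLANTED`) contains `planted_set_overlap` of the
#' planted members plus uniform filler genes; the remaining sets are uniform
#' draws within the configured size range. The returned disease-pathway list
#' contains the planted set's name plus one decoy set name.
#'
#' @param genes full gene pool.
#' @param planted_members genes to plant (typically the planted hubs).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `collection` ([gene_set_collection()]),
#'   `disease_pathways` (character), `planted_name`.
#' @export
generate_genesets <- function(genes, planted_members, config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  planted_members <- unique(normalize_genes(planted_members))
  lo <- config$geneset_size_range[1]; hi <- config$geneset_size_range[2]
  if (length(planted_members) > length(genes))
    stop("planted set larger than the gene pool", call. = FALSE)
  with_local_seed(seed, {
    sizes <- sample(lo:hi, config$n_genesets, replace = TRUE)
    n_pl <- round(config$planted_set_overlap * length(planted_members))
    chosen <- if (n_pl > 0L) sort(sample(planted_members, n_pl)) else character()
    planted_size <- max(sizes[1L], length(chosen))
    planted <- sort(c(chosen, sample(setdiff(genes, chosen),
                                     planted_size - length(chosen))))
    sets <- list(PW_PLANTED = list(name = "PW_PLANTED",
                                   description = "planted synthetic set",
                                   members = planted))
    for (i in seq_len(config$n_genesets - 1L)) {
      nm <- sprintf("PW_RND_%03d", i)
      sets[[nm]] <- list(name = nm, description = "random synthetic set",
                         members = sort(sample(genes, sizes[i + 1L])))
    }
    decoy <- if (length(sets) > 1L) names(sets)[2L] else character()
    list(collection = gene_set_collection(sets),
         disease_pathways = c("PW_PLANTED", decoy),
         planted_name = "PW_PLANTED")
  })
}

#' Generate a docking-score table with planted strong pairs
#'
#' Each target gets a ligand baseline score drawn Uniform(80, 140). A
#' designated fraction of compound-target cells are planted strong: their
#' scores are the baseline times Uniform(1.0, 1.2); all other cells score
#' baseline times Uniform(0.5, 0.9). A `missing_fraction` of non-ligand cells
#' is blanked to emulate pairs for which no docking pose could be generated
#' (these may include planted strong pairs — missingness is not informative).
#'
#' @param compounds character vector of molecule ids.
#' @param targets character vector of target gene symbols.
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `table` ([docking_table()]) and `truth` (data frame of
#'   planted strong `molecule`/`target` pairs).
#' @export
generate_docking <- function(compounds, targets, config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(seed, {
    baseline <- stats::setNames(stats::runif(length(targets), 80, 140),
                                targets)
    grid <- expand.grid(molecule = compounds, target = targets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_cells <- nrow(grid)
    strong_idx <- sample(n_cells, round(config$strong_pair_fraction * n_cells))
    mult <- stats::runif(n_cells, 0.5, 0.9)
    mult[strong_idx] <- stats::runif(length(strong_idx), 1.0, 1.2)
    grid$score <- baseline[grid$target] * mult
    miss_idx <- sample(n_cells, round(config$missing_fraction * n_cells))
    grid$score[miss_idx] <- NA_real_
    grid$is_ligand <- FALSE
    lig <- data.frame(molecule = paste0("LIGAND_", targets), target = targets,
                      score = unname(baseline), is_ligand = TRUE,
                      stringsAsFactors = FALSE)
    list(table = docking_table(rbind(grid, lig)),
         truth = grid[sort(strong_idx), c("molecule", "target")])
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all generators with sub-seeds derived from the master seed
#' (`seed`, `seed + 1`, `seed + 2`, `seed + 3` for the PPI, target sets,
#' gene sets, and docking table respectively) and cross-checks the truth
#' record against the generated tables.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with fields `ppi`, `ct`, `dt`,
#'   `collection`, `disease_pathways`, `docking`, `truth`, `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- config$seed
  ppi <- generate_ppi(config$n_genes, config$attach_m, seed)
  tg <- generate_targets(ppi, config, seed + 1L)
  gs <- generate_genesets(synthetic_gene_names(config$n_genes),
                          tg$truth$planted_hubs, config, seed + 2L)
  deg <- table(factor(c(ppi$a, ppi$b),
                      levels = synthetic_gene_names(config$n_genes)))
  dock_targets <- names(sort(deg, decreasing = TRUE))[
    seq_len(min(config$n_dock_targets, config$n_genes))]
  dock_targets <- dock_targets[order(dock_targets)]
  dk <- generate_docking(names(tg$ct$entries), dock_targets, config, seed + 3L)
  truth <- list(planted_hubs = tg$truth$planted_hubs,
                common = tg$truth$common,
                planted_set = gs$planted_name,
                strong_pairs = dk$truth)
  # consistency of the truth record with the generated tables
  stopifnot(all(truth$common %in% all_compound_targets(tg$ct)),
            all(truth$common %in% tg$dt$genes),
            truth$planted_set %in% names(gs$collection$sets))
  structure(list(ppi = ppi, ct = tg$ct, dt = tg$dt,
                 collection = gs$collection,
                 disease_pathways = gs$disease_pathways,
                 docking = dk$table, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset in the pipeline's input dialects
#'
#' Emits exactly the file formats the readers consume: a TSV PPI edge list
#' (`ppi.tsv`), compound-target and disease-target tables
#' (`compound_targets.tsv`, `disease_targets.tsv`), a GMT collection
#' (`genesets.gmt`), a disease-pathway list (`disease_pathways.txt`), a
#' docking CSV (`docking.csv`), and the truth record (`truth.json`). Number
#' formatting is fixed so identical seeds give byte-identical files.
#'
#' @param dataset a [generate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  ppi <- dataset$ppi
  utils::write.table(
    data.frame(node1 = ppi$a, node2 = ppi$b,
               combined_score = sprintf("%.6f", ppi$score)),
    p("ppi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ct_df <- data.frame(
    compound = rep(names(dataset$ct$entries), lengths(dataset$ct$entries)),
    gene = unlist(dataset$ct$entries, use.names = FALSE),
    source = "synthetic")
  utils::write.table(ct_df, p("compound_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = dataset$dt$genes, source = "synthetic"),
                     p("disease_targets.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(dataset$collection, p("genesets.gmt"))
  writeLines(dataset$disease_pathways, p("disease_pathways.txt"))
  write_docking_table(dataset$docking, p("docking.csv"))
  jsonlite::write_json(dataset$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  paths <- c(ppi = p("ppi.tsv"), compound_targets = p("compound_targets.tsv"),
             disease_targets = p("disease_targets.tsv"),
             genesets = p("genesets.gmt"),
             disease_pathways = p("disease_pathways.txt"),
             docking = p("docking.csv"), truth = p("truth.json"))
  invisible(paths)
}
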