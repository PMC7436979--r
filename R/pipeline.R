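# End-to-end orchestration: config validation, staged execution, and a
# machine-readable run report.

default_params <- function() {
  list(min_score = 0.4, degree_fold = 2, alpha = 0.05, top_k = 15L,
       method = "ease", adjust = "BH", ratio_cutoffs = c(0.8, 1.0),
       heatmap = FALSE)
}

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or YAML file) with either an `inputs`
#' block naming the input files (`compound_targets`, `disease_targets`,
#' `ppi`, `genesets`, optionally `disease_pathways`, `docking`) or a
#' `simulate` block of [synthetic_config()] overrides — never both — plus an
#' optional `params` block and a `seed`. Returns the violations found; an
#' empty character vector means the configuration is valid.
#'
#' @param config named list or path to a YAML file.
#' @return character vector of human-readable violations (empty if ok).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file '%s' missing", config))
    config <- yaml::read_yaml(config)
  }
  v <- character()
  if (!is.list(config)) return("config must be a named list")
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_inputs && has_sim)
    v <- c(v, "inputs and simulate blocks are mutually exclusive")
  if (!has_inputs && !has_sim)
    v <- c(v, "one of 'inputs' or 'simulate' is required")
  if (has_inputs) {
    for (key in c("compound_targets", "disease_targets", "ppi", "genesets")) {
      f <- config$inputs[[key]]
      if (is.null(f)) v <- c(v, sprintf("inputs.%s is required", key))
      else if (!file.exists(f)) v <- c(v, sprintf("inputs.%s: file '%s' missing", key, f))
    }
    for (key in c("disease_pathways", "docking")) {
      f <- config$inputs[[key]]
      if (!is.null(f) && !file.exists(f))
        v <- c(v, sprintf("inputs.%s: file '%s' missing", key, f))
    }
  }
  if (has_sim) {
    bad <- setdiff(names(config$simulate), names(formals(synthetic_config)))
    if (length(bad))
      v <- c(v, sprintf("unknown simulate key(s): %s", paste(bad, collapse = ", ")))
  }
  p <- utils::modifyList(default_params(), config$params %||% list())
  if (!is.numeric(p$min_score) || p$min_score < 0 || p$min_score > 1)
    v <- c(v, "params.min_score must be in [0, 1]")
  if (!is.numeric(p$alpha) || p$alpha <= 0 || p$alpha >= 1)
    v <- c(v, "params.alpha must be in (0, 1)")
  if (!is.numeric(p$top_k) || p$top_k < 1)
    v <- c(v, "params.top_k must be >= 1")
  if (!is.numeric(p$degree_fold) || p$degree_fold <= 0)
    v <- c(v, "params.degree_fold must be positive")
  if (!p$method %in% c("ease", "hypergeometric"))
    v <- c(v, "params.method must be 'ease' or 'hypergeometric'")
  if (!p$adjust %in% c("BH", "none"))
    v <- c(v, "params.adjust must be 'BH' or 'none'")
  if (length(p$ratio_cutoffs) != 2L || p$ratio_cutoffs[1] >= p$ratio_cutoffs[2])
    v <- c(v, "params.ratio_cutoffs must be two increasing numbers")
  v
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Executes read (or simulate) -> common targets -> CT-OT network -> hub
#' extraction -> centralities -> key-target screen -> over-representation ->
#' disease-pathway mapping -> compound-target-pathway network -> docking
#' ratios (when a score table is supplied), writing every intermediate under
#' `outdir` and returning a run report with stage counts, thresholds, top and
#' common pathways, output paths, a config hash and the seed. Identical
#' config + inputs yield an identical report (no timestamps are recorded).
#' Any stage error aborts with the stage name and cause.
#'
#' @param config named list or YAML file path; see [validate_config()].
#' @param outdir output directory.
#' @return the run report (class `run_report`), invisibly; also written as
#'   `report.json` under `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  violations <- validate_config(config)
  if (length(violations))
    stop(paste(c("invalid configuration:", violations), collapse = "\n  "),
         call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- utils::modifyList(default_params(), config$params %||% list())
  seed <- as.integer(config$seed %||% 0L)

  if (!is.null(config$simulate)) {
    sim_cfg <- run_stage("simulate", do.call(
      synthetic_config, utils::modifyList(config$simulate, list(seed = seed))))
    paths <- run_stage("simulate", {
      ds <- generate_dataset(sim_cfg)
      write_dataset(ds, file.path(outdir, "inputs"))
    })
    inputs <- as.list(paths[c("compound_targets", "disease_targets", "ppi",
                              "genesets", "disease_pathways", "docking")])
  } else {
    inputs <- config$inputs
  }

  ct <- run_stage("read_compound_targets",
                  read_compound_targets(inputs$compound_targets))
  dt <- run_stage("read_disease_targets",
                  read_disease_targets(inputs$disease_targets))
  ppi <- run_stage("read_ppi_edges",
                   read_ppi_edges(inputs$ppi, min_score = params$min_score))
  collection <- run_stage("read_gmt", read_gmt(inputs$genesets))
  dz_pathways <- if (!is.null(inputs$disease_pathways))
    run_stage("read_pathway_list", read_pathway_list(inputs$disease_pathways))
  else character()
  dock <- if (!is.null(inputs$docking))
    run_stage("read_docking_table", read_docking_table(inputs$docking))

  common <- run_stage("common_targets", common_targets(ct, dt))
  ctot <- run_stage("build_ct_ot_network",
                    build_ct_ot_network(ct, dt, ppi, params$min_score))
  hub <- run_stage("extract_hub_network", extract_hub_network(ctot, common))
  tab <- run_stage("centralities", centrality_table(hub))
  scr <- run_stage("screen_key_targets",
                   screen_key_targets(tab, params$degree_fold))
  if (length(scr$key_targets)) {
    enr <- run_stage("enrich",
                     enrich(scr$key_targets, collection,
                            method = params$method, adjust = params$adjust))
  } else {
    message("no key targets passed the screen; skipping enrichment")
    enr <- data.frame(set_name = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_raw = numeric(), p_adj = numeric(),
                      fold_enrichment = numeric(), genes = character(),
                      stringsAsFactors = FALSE)
  }
  top <- run_stage("top_pathways",
                   top_pathways(enr, k = params$top_k, alpha = params$alpha,
                                use_adjusted = params$adjust == "BH"))
  common_pw <- run_stage("map_disease_pathways",
                         map_disease_pathways(top, dz_pathways))

  # report records output paths relative to outdir so identical config+seed
  # produces a byte-identical report wherever it runs
  out <- function(f) file.path(outdir, f)
  write_network(ctot, out("ctot.graphml"))
  write_network(hub, out("hub.graphml"))
  write_screening_result(scr, out("key_targets.tsv"), out("thresholds.json"))
  utils::write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(common_pw$set_name, out("common_pathways.txt"))
  outputs <- list(ctot = "ctot.graphml", hub = "hub.graphml",
                  key_targets = "key_targets.tsv",
                  thresholds = "thresholds.json",
                  enrichment = "enrichment.tsv",
                  common_pathways = "common_pathways.txt")

  ctp_nodes <- 0L
  if (nrow(common_pw) > 0L) {
    ctp <- run_stage("build_ctp_network",
                     build_ctp_network(ct, scr$key_targets, collection,
                                       common_pw$set_name))
    write_network(ctp, out("ctp.graphml"))
    outputs$ctp <- "ctp.graphml"
    ctp_nodes <- igraph::vcount(ctp)
  }

  dock_missing <- NA_integer_
  if (!is.null(dock)) {
    drm <- run_stage("docking_ratios",
                     docking_ratios(dock, params$ratio_cutoffs))
    utils::write.csv(drm$ratios, out("ratios.csv"), na = "")
    utils::write.csv(drm$categories, out("categories.csv"))
    outputs$ratios <- "ratios.csv"
    outputs$categories <- "categories.csv"
    if (isTRUE(params$heatmap)) {
      ratio_heatmap(drm, out("ratios.png"), out("ratios_heatmap.csv"))
      outputs$heatmap <- "ratios.png"
    }
    dock_missing <- sum(is.na(drm$ratios))
  }

  report <- structure(list(
    counts = list(
      compound_targets = length(all_compound_targets(ct)),
      disease_targets = length(dt$genes),
      common_targets = length(common),
      ctot_nodes = igraph::vcount(ctot), ctot_edges = igraph::ecount(ctot),
      hub_nodes = igraph::vcount(hub), hub_edges = igraph::ecount(hub),
      key_targets = length(scr$key_targets),
      significant_pathways = nrow(top),
      common_pathways = nrow(common_pw),
      ctp_nodes = ctp_nodes,
      ctot_isolates_removed = igraph::graph_attr(ctot, "n_isolates_removed"),
      hub_isolates_removed = igraph::graph_attr(hub, "n_isolates_removed"),
      docking_missing_cells = dock_missing),
    thresholds = list(degree = scr$degree_cutoff,
                      betweenness = scr$betweenness_cutoff,
                      closeness = scr$closeness_cutoff),
    common_targets = common,
    key_targets = scr$key_targets,
    top_pathways = top$set_name,
    common_pathways = common_pw$set_name,
    outputs = outputs,
    params = params,
    seed = seed,
    config_hash = config_hash(config)),
    class = "run_report")
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-24s %s\n", nm, x$counts[[nm]]))
  cat(sprintf("  cutoffs: degree > %g, betweenness > %g, closeness > %g\n",
              x$thresholds$degree, x$thresholds$betweenness,
              x$thresholds$closeness))
  invisible(x)
}
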