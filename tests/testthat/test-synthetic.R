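test_that("preferential-attachment generator has the forced edge count", {
  # star seed on m+1 nodes plus m edges per later node -> m * (n - m) edges
  expect_equal(nrow(generate_ppi(100, 2, seed = 5)), 196L)
  expect_equal(nrow(generate_ppi(50, 3, seed = 5)), 3L * 47L)
  small <- generate_ppi(3, 1, seed = 1)
  expect_equal(nrow(small), 2L)
  expect_true(all(small$score > 0.4 & small$score <= 1))
  expect_error(generate_ppi(2, 2, seed = 1), "exceed")
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_ppi(200, 2, seed = 9), generate_ppi(200, 2, seed = 9))
  expect_false(identical(generate_ppi(200, 2, seed = 9),
                         generate_ppi(200, 2, seed = 10)))
  cfg <- synthetic_config(n_genes = 100L, n_disease_targets = 20L,
                          targets_per_compound = 10L, seed = 4L)
  d1 <- suppressMessages(generate_dataset(cfg))
  d2 <- suppressMessages(generate_dataset(cfg))
  expect_identical(d1, d2)

  # byte-identical files, GMT included
  out1 <- file.path(tempdir(), "sim_a"); out2 <- file.path(tempdir(), "sim_b")
  p1 <- write_dataset(d1, out1); p2 <- write_dataset(d2, out2)
  for (nm in names(p1))
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
                     readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
                     label = nm)
})

test_that("hub inclusion probability drives the planted common core", {
  ppi <- generate_ppi(100, 2, seed = 2)
  forced <- suppressMessages(generate_targets(
    ppi, synthetic_config(n_genes = 100L, hub_inclusion_prob = 1,
                          n_disease_targets = 20L, targets_per_compound = 10L),
    seed = 2))
  hubs <- forced$truth$planted_hubs
  expect_true(all(vapply(forced$ct$entries,
                         function(g) all(hubs %in% g), TRUE)))
  expect_true(all(hubs %in% forced$dt$genes))
  expect_setequal(forced$truth$common, hubs)

  null <- suppressMessages(generate_targets(
    ppi, synthetic_config(n_genes = 100L, hub_inclusion_prob = 0,
                          n_disease_targets = 20L, targets_per_compound = 10L),
    seed = 2))
  expect_length(null$truth$common, 0L)  # hubs excluded from every set
  expect_false(any(null$truth$planted_hubs %in% null$dt$genes))
})

test_that("planted common core stays in the 6 +/- 4 band across 100 seeds", {
  sizes <- vapply(1:100, function(s) {
    cfg <- synthetic_config(seed = s)
    ppi <- generate_ppi(cfg$n_genes, cfg$attach_m, cfg$seed)
    tg <- suppressMessages(generate_targets(ppi, cfg, cfg$seed + 1L))
    length(tg$truth$common)
  }, 0L)
  expect_true(all(sizes >= 2L & sizes <= 10L))
})

test_that("gene-set and docking generators plant recoverable structure", {
  ds <- suppressMessages(suppressWarnings(
    generate_dataset(synthetic_config(seed = 6))))
  planted <- ds$collection$sets[[ds$truth$planted_set]]
  # full overlap by default: every planted hub is in the planted set
  expect_true(all(ds$truth$planted_hubs %in% planted$members))
  expect_true(ds$truth$planted_set %in% ds$disease_pathways)

  drm <- docking_ratios(ds$docking)
  idx <- cbind(match(ds$truth$strong_pairs$molecule, rownames(drm$ratios)),
               match(ds$truth$strong_pairs$target, colnames(drm$ratios)))
  planted_ratios <- drm$ratios[idx]
  # planted strong pairs score above the ligand baseline by construction
  expect_true(all(planted_ratios[!is.na(planted_ratios)] >= 1.0))

  expect_error(generate_genesets(LETTERS[1:3], LETTERS[1:5],
                                 synthetic_config(), seed = 1),
               "larger than the gene pool")
})

test_that("truth record is consistent with the generated tables", {
  for (seed in c(1, 23)) {
    ds <- suppressMessages(suppressWarnings(
      generate_dataset(synthetic_config(seed = seed))))
    expect_true(all(ds$truth$common %in% all_compound_targets(ds$ct)))
    expect_true(all(ds$truth$common %in% ds$dt$genes))
    deg <- table(factor(c(ds$ppi$a, ds$ppi$b)))
    expect_true(min(deg[ds$truth$planted_hubs]) >=
                  sort(as.integer(deg), decreasing = TRUE)[
                    length(ds$truth$planted_hubs)])
    expect_true(all(paste(ds$truth$strong_pairs$molecule,
                          ds$truth$strong_pairs$target) %in%
                      paste(ds$docking$molecule, ds$docking$target)))
  }
})

test_that("written dataset files reload through the standard readers", {
  ds <- suppressMessages(generate_dataset(
    synthetic_config(n_genes = 80L, n_disease_targets = 15L,
                     targets_per_compound = 8L, n_compounds = 4L, seed = 12)))
  paths <- write_dataset(ds, file.path(tempdir(), "roundtrip"))
  expect_identical(read_compound_targets(paths[["compound_targets"]])$entries,
                   ds$ct$entries)
  expect_identical(read_disease_targets(paths[["disease_targets"]])$genes,
                   ds$dt$genes)
  ppi_back <- read_ppi_edges(paths[["ppi"]], min_score = 0)
  expect_equal(nrow(ppi_back), nrow(ds$ppi))
  col_back <- read_gmt(paths[["genesets"]])
  expect_identical(lapply(col_back$sets, `[[`, "members"),
                   lapply(ds$collection$sets, `[[`, "members"))
  dock_back <- read_docking_table(paths[["docking"]])
  expect_equal(sum(is.na(dock_back$score)), sum(is.na(ds$docking$score)))
})
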