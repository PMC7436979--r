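toy_hub <- function() suppressMessages(extract_hub_network(toy_ctot(),
                                                           c("G3", "G4")))

test_that("compound to key-target network follows the retention rule", {
  ct1 <- compound_target_map(list(C1 = "G3"))
  hub <- toy_hub()
  net <- suppressMessages(build_compound_key_target_network(ct1, "G3", hub))
  expect_setequal(igraph::V(net)$name, c("C1", "G3"))
  expect_equal(igraph::ecount(net), 1L)

  ct2 <- compound_target_map(list(C1 = c("G3", "G9"), C2 = "G5"))
  net <- suppressMessages(build_compound_key_target_network(ct2, "G3", hub))
  expect_setequal(igraph::V(net)$name, c("C1", "G3"))   # C2 excluded: G5 not key

  net <- suppressMessages(build_compound_key_target_network(
    ct2, "G3", hub, retain = "hub"))
  expect_true(all(c("C1", "C2", "G5") %in% igraph::V(net)$name))
  expect_true("ppi" %in% igraph::E(net)$kind)
  expect_equal(sort(unique(igraph::V(net)$type)), c("compound", "target"))
  expect_equal(igraph::V(net)$size, unname(igraph::degree(net)))

  expect_message(build_compound_key_target_network(ct2, "G3", hub),
                 "no retained target excluded")
  expect_error(build_compound_key_target_network(ct1, character(), hub),
               "empty key")
})

test_that("compound-target-pathway network is tripartite and type-safe", {
  ct <- compound_target_map(list(C1 = c("A", "B"), C2 = "C", C3 = "Z"))
  membership <- list(P1 = c("A", "B", "X"), P2 = c("B", "C"))
  net <- build_ctp_network(ct, c("A", "B", "C"), membership, c("P1", "P2"))
  types <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  expect_equal(unname(types[c("C1", "A", "P1")]),
               c("compound", "target", "pathway"))
  expect_false("C3" %in% igraph::V(net)$name)   # no edge -> dropped
  expect_false("X" %in% igraph::V(net)$name)    # not a key target
  expect_true(validate_tripartite(net))

  expect_error(build_ctp_network(ct, "A", membership, character()),
               "no pathways selected")
  expect_error(build_ctp_network(ct, "A", membership, "P9"), "absent")
  expect_error(build_ctp_network(ct, "Q", membership, "P1"), "no key target")
})

test_that("docking ratios normalize by the ligand baseline and propagate missingness", {
  dk <- docking_table(data.frame(
    molecule = c("CMP1", "CMP2", "CMP3", "LIG"),
    target = "TP53",
    score = c(110, 100, NA, 100),
    is_ligand = c(FALSE, FALSE, FALSE, TRUE)))
  drm <- docking_ratios(dk)
  expect_equal(drm$ratios["CMP1", "TP53"], 1.1)
  expect_equal(drm$ratios["CMP2", "TP53"], 1.0)
  expect_true(is.na(drm$ratios["CMP3", "TP53"]))
  expect_equal(drm$categories["CMP3", "TP53"], "none")

  bad <- docking_table(data.frame(molecule = c("C", "L"), target = "EGFR",
                                  score = c(50, -1),
                                  is_ligand = c(FALSE, TRUE)))
  expect_error(docking_ratios(bad), "EGFR")
})

test_that("ratio categories honor half-open boundaries and scale invariance", {
  mk <- function(scores) docking_table(data.frame(
    molecule = c(sprintf("C%d", seq_along(scores)), "LIG"),
    target = "T1", score = c(scores, 100),
    is_ligand = c(rep(FALSE, length(scores)), TRUE)))
  drm <- docking_ratios(mk(c(79.999, 80, 99.999, 100, 120)))
  expect_equal(unname(drm$categories[, "T1"]),
               c("weak", "moderate", "moderate", "strong", "strong"))

  # multiplying every score for a target (ligand included) by c > 0 leaves
  # ratios and categories unchanged
  scaled <- docking_table(data.frame(
    molecule = c("C1", "C2", "LIG"), target = "T1",
    score = c(50, 120, 100) * 3.5, is_ligand = c(FALSE, FALSE, TRUE)))
  expect_equal(docking_ratios(scaled)$ratios,
               docking_ratios(mk(c(50, 120)))$ratios, tolerance = 1e-12)
  expect_equal(docking_ratios(scaled)$categories,
               docking_ratios(mk(c(50, 120)))$categories)
})

test_that("heat map emits a faithful CSV twin and flags empty columns", {
  ds <- suppressMessages(suppressWarnings(
    generate_dataset(synthetic_config(seed = 3))))
  drm <- docking_ratios(ds$docking)
  expect_equal(dim(drm$ratios), c(16L, 13L))
  png <- file.path(tempdir(), "ratios.png")
  out <- ratio_heatmap(drm, png)
  back <- as.matrix(read.csv(out$csv, row.names = 1, check.names = FALSE))
  expect_equal(back, drm$ratios, tolerance = 1e-6)
  expect_true(file.exists(png))

  one <- docking_table(data.frame(molecule = c("C1", "LIG"), target = "T1",
                                  score = c(NA, 100),
                                  is_ligand = c(FALSE, TRUE)))
  expect_message(ratio_heatmap(docking_ratios(one),
                               file.path(tempdir(), "one.png")),
                 "all-missing")
})
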