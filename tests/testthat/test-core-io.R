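test_that("compound-target reader normalizes case, merges duplicates, skips blanks", {
  path <- write_lines_tmp(c("compound\tgene\tsource",
                            "C1\ttp53\tdbA",
                            "C1\tTP53\tdbB",
                            "C2\tIL6\tdbA"))
  ct <- read_compound_targets(path)
  expect_s3_class(ct, "compound_target_map")
  expect_equal(ct$entries, list(C1 = "TP53", C2 = "IL6"))
  expect_setequal(ct$provenance$source[ct$provenance$gene == "TP53"],
                  c("dbA", "dbB"))

  path2 <- write_lines_tmp(c("compound\tgene", "C1\tTP53", "C1\t", "C2\tIL6"))
  expect_message(ct2 <- read_compound_targets(path2), "skipped 1 row")
  expect_equal(all_compound_targets(ct2), c("IL6", "TP53"))

  path3 <- write_lines_tmp(c("compound\tnotes", "C1\tx"))
  expect_error(read_compound_targets(path3), "gene")

  empty <- write_lines_tmp("compound\tgene")
  expect_warning(ct3 <- read_compound_targets(empty), "empty")
  expect_length(ct3$entries, 0L)
})

test_that("disease-target reader handles plain lists, tables, and empties", {
  path <- write_lines_tmp(c("IL6", "il6", "TNF"), ext = ".txt")
  dt <- read_disease_targets(path)
  expect_equal(dt$genes, c("IL6", "TNF"))

  tsv <- write_lines_tmp(c("gene\tsource", "tnf\tomim", "IL6\tdisgenet"))
  dt2 <- read_disease_targets(tsv)
  expect_equal(dt2$genes, c("IL6", "TNF"))
  expect_setequal(dt2$provenance$source, c("omim", "disgenet"))

  empty <- write_lines_tmp(character(), ext = ".txt")
  expect_warning(dt3 <- read_disease_targets(empty), "empty")
  expect_length(dt3$genes, 0L)
})

test_that("PPI reader applies dialect detection, dedup, self-loop and strict threshold rules", {
  path <- write_lines_tmp(c("node1\tnode2\tcombined_score",
                            "A\tB\t900", "B\tA\t850", "A\tA\t999",
                            "C\tD\t350"))
  edges <- suppressMessages(read_ppi_edges(path, min_score = 0.4))
  expect_equal(edges, data.frame(a = "A", b = "B", score = 0.9),
               ignore_attr = TRUE)
  expect_equal(attr(edges, "n_self_loops"), 1L)
  expect_equal(attr(edges, "n_duplicates"), 1L)

  # strict inequality at the boundary: 0.41 kept, 0.4 dropped
  b <- write_lines_tmp(c("node1\tnode2\tcombined_score",
                         "A\tB\t0.41", "C\tD\t0.4"))
  kept <- read_ppi_edges(b, min_score = 0.4)
  expect_equal(kept$a, "A")

  # 10-row toy file, 4 rows at or below 0.4 -> 6 edges survive
  rows <- sprintf("N%02d\tM%02d\t%.2f", 1:10, 1:10,
                  c(0.9, 0.1, 0.55, 0.40, 0.8, 0.2, 0.41, 0.39, 0.95, 0.5))
  ten <- write_lines_tmp(c("node1\tnode2\tcombined_score", rows))
  expect_equal(nrow(read_ppi_edges(ten, 0.4)), 6L)

  # scores above 1000 need an explicit dialect
  big <- write_lines_tmp(c("node1\tnode2\tcombined_score", "A\tB\t1500"))
  expect_error(read_ppi_edges(big), "explicit")
})

test_that("0-1000 and 0-1 dialects load identically after normalization", {
  set.seed(42)
  n <- 30L
  a <- sprintf("A%02d", 1:n)
  b <- sprintf("B%02d", 1:n)
  s <- round(runif(n, 0.05, 0.99), 3)
  unit <- write_lines_tmp(c("node1\tnode2\tcombined_score",
                            sprintf("%s\t%s\t%.3f", a, b, s)))
  thousand <- write_lines_tmp(c("node1\tnode2\tcombined_score",
                                sprintf("%s\t%s\t%d", a, b,
                                        as.integer(round(s * 1000)))))
  e1 <- read_ppi_edges(unit, 0.4, scale = "unit")
  e2 <- read_ppi_edges(thousand, 0.4, scale = "auto")
  expect_equal(e1, e2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GMT parsing, validation and round-trip", {
  path <- write_lines_tmp(c("S1\tdesc\tA\tB", "S2\tother\tB\tC\tD"),
                          ext = ".gmt")
  col <- read_gmt(path)
  expect_equal(col$sets$S1$members, c("A", "B"))
  expect_equal(col$universe, c("A", "B", "C", "D"))

  bad <- write_lines_tmp(c("S1\tdesc\tA", "S2\tonlydesc"), ext = ".gmt")
  expect_error(read_gmt(bad), "line 2")

  out <- tempfile(fileext = ".gmt")
  write_gmt(col, out)
  expect_equal(read_gmt(out), col)
})

test_that("docking table reader keeps missing scores distinct from zero", {
  path <- write_lines_tmp(c("molecule,target,score,is_ligand",
                            "CMP1,TP53,110.5,FALSE",
                            "CMP2,TP53,,FALSE",
                            "LIG_TP53,TP53,100,TRUE"), ext = ".csv")
  dk <- read_docking_table(path)
  expect_true(is.na(dk$score[dk$molecule == "CMP2"]))
  expect_false(any(dk$score == 0, na.rm = TRUE))

  # a target without its ligand row violates the type invariant
  expect_error(docking_table(data.frame(molecule = "CMP1", target = "TP53",
                                        score = 1, is_ligand = FALSE)),
               "exactly one ligand")
})

test_that("network writers round-trip nodes, roles, edges and scores", {
  net <- toy_ctot()
  for (fmt in c("graphml", "tsv")) {
    path <- tempfile()
    write_network(net, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
    key <- function(g) {
      df <- igraph::as_data_frame(g, what = "edges")
      df$score <- round(as.numeric(df$score), 6)
      df[order(pmin(df$from, df$to), pmax(df$from, df$to)),
         c("from", "to", "score")]
    }
    expect_equal(key(back), key(net), ignore_attr = TRUE)
    roles <- function(g)
      igraph::V(g)$role[order(igraph::V(g)$name)]
    expect_equal(roles(back), roles(net))
  }
  sif <- tempfile(fileext = ".sif")
  write_network(net, sif, format = "sif")
  expect_equal(length(readLines(sif)), igraph::ecount(net))
})

test_that("gene normalization enforces the symbol invariants", {
  expect_equal(normalize_genes(c(" tp53", "IL6 ", "il6")),
               c("TP53", "IL6", "IL6"))
  expect_error(normalize_genes("TP 53"), "whitespace")
  expect_equal(apply_alias_table(c("p53", "IL6"),
                                 data.frame(alias = "P53", symbol = "TP53")),
               c("TP53", "IL6"))
})
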