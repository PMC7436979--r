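# Shared fixtures (built in code) and independent brute-force oracles.

# --- TOY fixture: 8 genes, 8 scored edges, overlapping target sets ---------

toy_ppi <- function() {
  data.frame(
    a = c("G1", "G1", "G2", "G3", "G3", "G4", "G6", "G7"),
    b = c("G2", "G3", "G3", "G4", "G5", "G5", "G7", "G8"),
    score = c(0.9, 0.8, 0.7, 0.6, 0.8, 0.5, 0.3, 0.9),
    stringsAsFactors = FALSE)
}

toy_ct <- function() {
  compound_target_map(list(C1 = c("G1", "G2"), C2 = c("G3", "G4")))
}

toy_dt <- function() disease_target_set(c("G3", "G4", "G5", "G7"))

toy_ctot <- function(min_score = 0.4) {
  suppressMessages(build_ct_ot_network(toy_ct(), toy_dt(), toy_ppi(),
                                       min_score))
}

# igraph from an edge data frame (a, b[, score])
graph_from_edges <- function(df, vertices = NULL) {
  if (is.null(df$score)) df$score <- 1
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = vertices)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# --- independent centrality oracle (adjacency-matrix powers) ---------------
# Number of shortest s-t paths in an unweighted graph equals the number of
# walks of length dist(s, t), i.e. (A^d)[s, t]; betweenness follows from
# sigma_st(v) = (A^{d(s,v)})[s, v] * (A^{d(v,t)})[v, t] when
# d(s, v) + d(v, t) = d(s, t). Entirely independent of the BFS/Brandes path.
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  cnt <- matrix(0, n, n)
  diag(cnt) <- 1
  P <- diag(n)
  for (k in seq_len(max(n - 1L, 1L))) {
    P <- P %*% adj
    newly <- is.infinite(dist) & P > 0
    dist[newly] <- k
    cnt[newly] <- P[newly]
  }
  cc <- vapply(seq_len(n), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) 1 / mean(d) else 0
  }, 0)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s < t && s != v && t != v && is.finite(dist[s, t]) &&
          is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        acc <- acc + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
    bc[v] <- acc
  }
  if (n > 2L) bc <- bc / ((n - 1) * (n - 2) / 2)
  list(betweenness = bc, closeness = cc, degree = rowSums(adj))
}

# Seeded random simple graph on <= 8 nodes, returned with its adjacency.
random_test_graph <- function(seed) {
  set.seed(seed)
  n <- sample(2:8, 1L)
  p <- runif(1L, 0.2, 0.8)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1L) / 2L, 1L, p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  list(graph = g, adj = adj)
}

# --- independent hypergeometric tail oracle --------------------------------
# Direct combinatorial summation: P(X >= k) = sum_x C(K,x) C(N-K,n-x) / C(N,n).
oracle_hyper_tail <- function(k, K, n, N) {
  x <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

run_default_recovery <- function(seed) {
  ds <- suppressMessages(suppressWarnings(
    generate_dataset(synthetic_config(seed = seed))))
  common <- suppressMessages(common_targets(ds$ct, ds$dt))
  net <- suppressMessages(build_ct_ot_network(ds$ct, ds$dt, ds$ppi))
  hub <- suppressMessages(suppressWarnings(extract_hub_network(net, common)))
  scr <- screen_key_targets(centrality_table(hub))
  list(dataset = ds, common = common, ctot = net, hub = hub, screen = scr)
}
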