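# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, brute force and closed forms only.

# P(overlap >= r) by literal enumeration of all C(m, n) draws of the second
# set against a fixed first set of size t. Only feasible for small m.
hyper_upper_enum <- function(r, t, n, m) {
  if (r <= 0) return(1)
  if (n == 0) return(0)
  first <- seq_len(t)
  draws <- utils::combn(m, n)
  mean(apply(draws, 2, function(d) sum(d %in% first) >= r))
}

# Two-group log-rank by direct O/E/V tabulation at each event time.
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d_tot <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + d1 - e1
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  (o_minus_e)^2 / v
}

# Steady state of the restart walk by direct linear solve.
rwr_solve <- function(W, p0, restart) {
  n <- nrow(W)
  as.vector(restart * solve(diag(n) - (1 - restart) * as.matrix(W), p0))
}

# All-pairs shortest-path distances by BFS (unweighted).
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# Exact shortest-path betweenness by path counting (Brandes-style forward
# counts + explicit pair enumeration); fine for graphs of a few dozen nodes.
betweenness_by_hand <- function(adj) {
  n <- nrow(adj)
  D <- bfs_distances(adj)
  # number of shortest paths between every pair
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ])]))) {
      if (d == 0) next
      for (v in which(D[s, ] == d)) {
        preds <- which(adj[v, ] > 0 & D[s, ] == d - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# A small connected bipartite network fixture built from explicit edges.
toy_network <- function(edges) {
  cerna_network(data.frame(lncRNA = edges[, 1], PCG = edges[, 2],
                           stringsAsFactors = FALSE))
}

# Small fast simulation config for tests.
test_config <- function(...) {
  defaults <- list(n_patients = 20, n_lncRNA = 40, n_PCG = 100,
                   n_miRNA = 150, n_de_lnc = 15, n_de_pcg = 40,
                   n_true_cerna = 10, n_cerna_modules = 4,
                   targets_per_gene = 10, overlap_boost = 8,
                   n_seed_genes = 20, seed_bias = 0.3,
                   signature_coefs = c(-0.9, -0.7), rng_seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}
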