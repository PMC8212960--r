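test_that("column normalization yields stochastic columns", {
  # single edge u-v
  W <- column_normalize(toy_network(cbind("u", "v")))
  expect_equal(as.matrix(W), matrix(c(0, 1, 1, 0), 2,
                                    dimnames = list(c("u", "v"), c("u", "v"))))
  # star K1,3: the center's column has entries 1/3
  star <- toy_network(cbind("c", c("p1", "p2", "p3")))
  Ws <- column_normalize(star)
  expect_equal(unname(Ws[c("p1", "p2", "p3"), "c"]), rep(1 / 3, 3))
  # random bipartite graph: all column sums 1 within 1e-12
  set.seed(2)
  edges <- unique(cbind(paste0("l", sample(25, 120, TRUE)),
                        paste0("p", sample(25, 120, TRUE))))
  Wr <- column_normalize(toy_network(edges))
  expect_true(all(abs(Matrix::colSums(Wr) - 1) < 1e-12))
})

test_that("restart-only walk returns the seed vector", {
  net <- toy_network(cbind(paste0("l", 1:4), paste0("p", c(1, 1, 2, 2))))
  W <- column_normalize(net)
  sc <- rwr_propagate(W, c("p1", "p2"), restart = 1)
  expect_equal(unname(sc[c("p1", "p2")]), c(0.5, 0.5))
  expect_equal(sum(sc), 1)
})

test_that("iterative walk matches the direct linear solve", {
  # two-node and path graphs with hand-checkable structure
  net2 <- toy_network(cbind("u", "v"))
  W2 <- column_normalize(net2)
  sc2 <- rwr_propagate(W2, "u", restart = 0.5)
  p0 <- c(1, 0)
  expect_equal(as.numeric(sc2), rwr_solve(W2, p0, 0.5), tolerance = 1e-8)

  path <- toy_network(rbind(c("a", "b"), c("c", "b")))  # a - b - c
  Wp <- column_normalize(path)
  scp <- rwr_propagate(Wp, "a", restart = 0.3)
  p0p <- as.numeric(colnames(Wp) == "a")
  expect_equal(as.numeric(scp), rwr_solve(Wp, p0p, 0.3), tolerance = 1e-8)
  # scores decay with distance from the seed
  expect_true(scp["a"] > scp["b"] && scp["b"] > scp["c"])

  # random graphs: oracle equivalence, conservation and fixed point
  set.seed(4)
  for (i in 1:10) {
    n_l <- sample(10:60, 1)
    edges <- unique(cbind(paste0("l", sample(n_l, 4 * n_l, TRUE)),
                          paste0("p", sample(n_l, 4 * n_l, TRUE))))
    W <- column_normalize(toy_network(edges))
    seeds <- sample(grep("^p", colnames(W), value = TRUE), 3)
    r <- runif(1, 0.2, 0.9)
    sc <- rwr_propagate(W, seeds, restart = r)
    p0 <- as.numeric(colnames(W) %in% seeds) / 3
    expect_lt(max(abs(sc - rwr_solve(W, p0, r))), 1e-8)
    resid <- sum(abs(sc - ((1 - r) * as.vector(W %*% sc) + r * p0)))
    expect_lt(resid, 1e-10)
    expect_equal(sum(sc), 1, tolerance = 1e-9)
  }
})

test_that("unmapped seeds are dropped and an empty mapping errors", {
  net <- toy_network(cbind("l1", "p1"))
  W <- column_normalize(net)
  expect_message(sc <- rwr_propagate(W, c("p1", "zzz"), restart = 0.5),
                 "not present")
  expect_error(rwr_propagate(W, "zzz"), "no seed")
})

test_that("forcing pseudo-seeds equal to the real seeds gives empirical p 0", {
  net <- toy_network(cbind(paste0("l", c(1, 2, 2, 3)),
                           paste0("p", c(1, 1, 2, 2))))
  res <- permutation_significance(net, "p1", n_perm = 50, rng_seed = 1,
                                  sampler = function(pool, k, iter) "p1")
  expect_true(all(res$table$empirical_p == 0))
  # the plus-one estimator keeps p strictly positive instead
  res1 <- permutation_significance(net, "p1", n_perm = 50, rng_seed = 1,
                                   plus_one = TRUE,
                                   sampler = function(pool, k, iter) "p1")
  expect_true(all(res1$table$empirical_p == 1 / 51))
})

test_that("sampled empirical p converges to the exhaustive null tail", {
  # network small enough to enumerate every seed choice
  set.seed(9)
  edges <- unique(cbind(paste0("l", sample(4, 14, TRUE)),
                        paste0("p", sample(6, 14, TRUE))))
  net <- toy_network(edges)
  W <- column_normalize(net)
  pcgs <- grep("^p", colnames(W), value = TRUE)
  lncs <- grep("^l", colnames(W), value = TRUE)
  seeds <- pcgs[1:2]
  real <- rwr_propagate(W, seeds, restart = 0.7)[lncs]
  combos <- combn(pcgs, 2)
  perm_scores <- apply(combos, 2, function(s)
    rwr_propagate(W, s, restart = 0.7)[lncs])
  exact <- rowMeans(perm_scores > real)
  res <- permutation_significance(net, seeds, restart = 0.7, n_perm = 2000,
                                  rng_seed = 11)
  got <- res$table$empirical_p[match(lncs, res$table$node)]
  mc_se <- sqrt(exact * (1 - exact) / 2000)
  expect_true(all(abs(got - exact) <= 3 * mc_se + 1e-12))
})

test_that("empirical p-values are uniform under an unbiased null", {
  # seeds drawn uniformly from PCG nodes of a fixed background network:
  # exchangeable with the permutation draws, so p ~ U(0,1) (discretized)
  set.seed(21)
  edges <- unique(cbind(paste0("l", sample(60, 400, TRUE)),
                        paste0("p", sample(80, 400, TRUE))))
  net <- toy_network(edges)
  pcgs <- net$nodes$node[net$nodes$type == "PCG"]
  pvals <- unlist(lapply(1:6, function(i) {
    seeds <- sample(pcgs, 8)
    permutation_significance(net, seeds, n_perm = 250,
                             rng_seed = 30 + i)$table$empirical_p
  }))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("risk lncRNAs planted near biased seeds rank in the top decile", {
  # a short, focused disease-gene list concentrated on the signature
  # lncRNAs' partner PCGs -- the regime network propagation is meant for
  top_hits <- vapply(1:20, function(seed) {
    cfg <- test_config(n_lncRNA = 60, n_PCG = 150, n_de_lnc = 30,
                       n_de_pcg = 60, n_true_cerna = 25, n_cerna_modules = 8,
                       n_miRNA = 300, targets_per_gene = 10,
                       overlap_boost = 12, n_seed_genes = 6, seed_bias = 0.9,
                       rng_seed = 300 + seed)
    sim <- simulate_all(cfg)
    cand <- build_cerna_candidates(sim$mirna_pcg, sim$mirna_lnc,
                                   p_cut = 0.01)
    net <- cerna_network(cand)
    W <- column_normalize(net)
    seeds <- intersect(sim$seeds, colnames(W))
    sc <- rwr_propagate(W, seeds)
    lncs <- net$nodes$node[net$nodes$type == "lncRNA"]
    sig <- intersect(names(sim$truth$signature), lncs)
    if (length(sig) == 0) return(NA)
    ranks <- rank(-sc[lncs])[sig]
    all(ranks <= ceiling(length(lncs) / 10))
  }, logical(1))
  expect_gte(mean(top_hits, na.rm = TRUE), 0.8)
})

test_that("rank-sum comparison matches enumeration on small groups", {
  mk_result <- function(risk_scores, null_scores) {
    structure(list(table = data.frame(
      node = paste0("l", seq_len(length(risk_scores) + length(null_scores))),
      score = c(risk_scores, null_scores),
      empirical_p = rep(c(0, 1), c(length(risk_scores), length(null_scores))),
      risk = rep(c(TRUE, FALSE), c(length(risk_scores), length(null_scores))))),
      class = "rwr_result")
  }
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1 (2/20 orderings)
  res <- compare_score_distributions(mk_result(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  # complete separation at n1 = n2 = 10: U = 100, exact tail by enumeration
  res2 <- compare_score_distributions(mk_result(11:20, 1:10))
  expect_equal(res2$statistic, 100)
  ranks_all <- combn(20, 10, function(idx) sum(idx))
  u_all <- ranks_all - sum(1:10)  # rank-sum minus its minimum = U statistic
  p_enum <- mean(u_all >= 100) * 2
  expect_equal(res2$p, p_enum)
  # identical multisets: statistic at the null center, p = 1
  res3 <- compare_score_distributions(mk_result(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res3$p, 1)
  expect_error(compare_score_distributions(mk_result(numeric(0), 1:3)),
               "nonempty")
})
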