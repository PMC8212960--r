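#' Column-normalized transition matrix of a network
#'
#' Builds the random-walk transition matrix `W[i, j] = A[i, j] / degree(j)`
#' from the unweighted adjacency of a ceRNA network (or any igraph graph).
#' Every column of a node with degree >= 1 sums to exactly 1. Isolated
#' nodes cannot host a walker and are excluded with a message.
#'
#' @param x a [cerna_network()] or an [igraph::igraph] graph.
#' @return a sparse `dgCMatrix` with node names as dimnames.
#' @export
column_normalize <- function(x) {
  g <- if (inherits(x, "cerna_network")) cerna_igraph(x)
       else if (inherits(x, "igraph")) x
       else stop("`x` must be a cerna_network or an igraph graph")
  if (igraph::vcount(g) == 0) stop("network is empty")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1                                   # unweighted walk
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    message("excluding ", sum(deg == 0), " isolated node(s) from the walk")
    keep <- deg > 0
    A <- A[keep, keep, drop = FALSE]
    deg <- deg[keep]
  }
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- list(names(deg), names(deg))
  methods::as(W, "CsparseMatrix")
}

# Core iteration P_{t+1} = (1 - r) W P_t + r P0, column-wise over a matrix
# of start vectors; stops when every column's L1 change is below tol.
rwr_iterate <- function(W, P0, restart, tol = 1e-10, max_iter = 10000L) {
  P <- P0
  for (it in seq_len(max_iter)) {
    P1 <- (1 - restart) * as.matrix(W %*% P) + restart * P0
    delta <- max(colSums(abs(P1 - P)))
    P <- P1
    if (delta < tol) return(list(P = P, iterations = it, delta = delta))
  }
  warning("random walk did not reach tol within max_iter iterations")
  list(P = P, iterations = max_iter, delta = delta)
}

#' Random walk with restart from seed nodes
#'
#' Iterates `p_{t+1} = (1 - r) W p_t + r p_0` until the L1 change falls
#' below `tol`. The restart vector `p_0` is uniform over the seed nodes
#' (`1 / #seeds` each), so the steady state sums to 1 on the seeds'
#' component; scores are proportional to the unnormalized variant and
#' identical in rank.
#'
#' @param W transition matrix from [column_normalize()].
#' @param seeds character vector of seed node names; seeds absent from the
#'   network are dropped with a message, and an error is raised if none maps.
#' @param restart restart probability `r` in `(0, 1]`.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return named numeric vector of steady-state probabilities over all
#'   nodes, with attributes `iterations` and `delta`.
#' @export
rwr_propagate <- function(W, seeds, restart = 0.7, tol = 1e-10,
                          max_iter = 10000L) {
  stopifnot(restart > 0, restart <= 1, tol > 0)
  idx <- match(unique(seeds), colnames(W))
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " seed(s) not present in the network")
    idx <- idx[!is.na(idx)]
  }
  if (length(idx) == 0) stop("no seed node maps into the network")
  p0 <- numeric(ncol(W))
  p0[idx] <- 1 / length(idx)
  res <- rwr_iterate(W, matrix(p0, ncol = 1), restart, tol, max_iter)
  out <- res$P[, 1]
  names(out) <- colnames(W)
  attr(out, "iterations") <- res$iterations
  attr(out, "delta") <- res$delta
  out
}

#' Permutation significance of lncRNA walk scores
#'
#' Runs the restart walk from the real disease seeds, then `n_perm` times
#' from pseudo-seeds drawn uniformly without replacement from the PCG nodes
#' of the network (the network topology is held fixed; `mode = "rewire"`
#' instead resamples a degree-preserving rewiring of the graph each
#' iteration and walks from the real seeds). For each lncRNA, `m` counts the
#' permutations whose score strictly exceeds the real one; the empirical
#' p-value is `m / n_perm` (or the small-sample-safe `(m + 1) / (n_perm +
#' 1)` with `plus_one = TRUE`). lncRNAs with `p < p_cutoff` are flagged as
#' risk lncRNAs.
#'
#' @param network a [cerna_network()].
#' @param seeds character vector of disease seed PCG ids.
#' @param restart restart probability.
#' @param n_perm number of permutations.
#' @param rng_seed integer seed for the permutation draws.
#' @param p_cutoff risk call threshold on the empirical p-value.
#' @param tol,max_iter forwarded to the walk.
#' @param plus_one use the `(m + 1) / (n + 1)` estimator.
#' @param mode `"seed_resample"` (default) or `"rewire"`.
#' @param sampler optional function `(pool, k, iter)` returning the
#'   pseudo-seed node names of iteration `iter`; used for testing.
#' @param chunk number of permutations propagated simultaneously.
#' @return object of class `rwr_result`: list with `table` (one row per
#'   lncRNA: `node`, `score`, `empirical_p`, `risk`), `scores` (all nodes),
#'   `seeds_used`, and the configuration.
#' @export
permutation_significance <- function(network, seeds, restart = 0.7,
                                     n_perm = 10000L, rng_seed = 1L,
                                     p_cutoff = 0.05, tol = 1e-10,
                                     max_iter = 10000L, plus_one = FALSE,
                                     mode = c("seed_resample", "rewire"),
                                     sampler = NULL, chunk = 2000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "cerna_network"), n_perm >= 1)
  W <- column_normalize(network)
  types <- network$nodes$type[match(colnames(W), network$nodes$node)]
  pcg_nodes <- colnames(W)[types == "PCG"]
  lnc_nodes <- colnames(W)[types == "lncRNA"]
  real <- rwr_propagate(W, seeds, restart, tol, max_iter)
  seeds_used <- intersect(unique(seeds), colnames(W))
  k <- length(seeds_used)
  if (k > length(pcg_nodes))
    stop("more mapped seeds than PCG nodes; cannot resample without replacement")
  real_lnc <- real[lnc_nodes]

  set.seed(rng_seed)
  m <- integer(length(lnc_nodes))
  if (mode == "seed_resample") {
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      P0 <- matrix(0, ncol(W), nb)
      for (b in seq_len(nb)) {
        ps <- if (is.null(sampler)) sample(pcg_nodes, k)
              else sampler(pcg_nodes, k, done + b)
        P0[match(ps, colnames(W)), b] <- 1 / k
      }
      Pinf <- rwr_iterate(W, P0, restart, tol, max_iter)$P
      m <- m + rowSums(Pinf[match(lnc_nodes, colnames(W)), , drop = FALSE] >
                         real_lnc)
      done <- done + nb
    }
  } else {
    g <- cerna_igraph(network)
    for (b in seq_len(n_perm)) {
      gp <- igraph::rewire(g, igraph::keeping_degseq(
        niter = 10 * igraph::ecount(g)))
      Wp <- column_normalize(gp)
      sc <- rwr_propagate(Wp, seeds_used, restart, tol, max_iter)
      m <- m + (sc[lnc_nodes] > real_lnc)
    }
  }
  emp_p <- if (plus_one) (m + 1) / (n_perm + 1) else m / n_perm
  tab <- data.frame(node = lnc_nodes,
                    score = unname(real_lnc),
                    empirical_p = emp_p,
                    risk = emp_p < p_cutoff,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$empirical_p, -tab$score), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 scores = stats::setNames(as.numeric(real), names(real)),
                 seeds_used = seeds_used,
                 restart = restart, n_perm = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed), p_cutoff = p_cutoff,
                 mode = mode, tol = tol),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf(paste0("rwr_result: %d lncRNAs scored from %d seeds ",
                     "(r = %g, %d permutations); %d risk lncRNAs at p < %g\n"),
              nrow(x$table), length(x$seeds_used), x$restart, x$n_perm,
              sum(x$table$risk), x$p_cutoff))
  invisible(x)
}

#' Compare walk scores of risk vs non-risk lncRNAs
#'
#' Two-sided Wilcoxon rank-sum test on the real RWR scores of the lncRNAs
#' flagged as risk against the rest.
#'
#' @param result an `rwr_result` from [permutation_significance()].
#' @return list with `statistic` (the rank-sum U of the risk group) and `p`.
#' @export
compare_score_distributions <- function(result) {
  stopifnot(inherits(result, "rwr_result"))
  x <- result$table$score[result$table$risk]
  y <- result$table$score[!result$table$risk]
  if (length(x) == 0 || length(y) == 0)
    stop("both risk and non-risk groups must be nonempty")
  # exact p for small untied samples, normal approximation with tie
  # correction otherwise (ties among walk scores are routine)
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
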