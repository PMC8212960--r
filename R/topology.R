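#' Node centralities of the ceRNA network
#'
#' Degree (edge count), shortest-path betweenness normalized by
#' `(N - 1)(N - 2) / 2`, and closeness with the Wasserman-Faust component
#' correction: for a node reaching `k` other nodes at total distance `S`,
#' closeness is `(k / S) * (k / (N - 1))`, which stays finite on
#' disconnected graphs. `closeness = "harmonic"` instead averages
#' reciprocal distances. The per-metric top-`top_k` nodes are reported,
#' along with the hub set appearing in the top list of at least two metrics.
#'
#' @param network a [cerna_network()] or an igraph graph.
#' @param top_k size of the per-metric top lists.
#' @param closeness `"wf"` (Wasserman-Faust, default) or `"harmonic"`.
#' @return list with `table` (node, type, degree, betweenness, closeness and
#'   per-metric ranks), `top` (a list of three character vectors) and `hubs`.
#' @export
node_centralities <- function(network, top_k = 20,
                              closeness = c("wf", "harmonic")) {
  closeness <- match.arg(closeness)
  g <- if (inherits(network, "cerna_network")) cerna_igraph(network)
       else network
  N <- igraph::vcount(g)
  if (N == 0) stop("network is empty")
  deg <- igraph::degree(g)
  btw <- if (N > 2) igraph::betweenness(g, normalized = TRUE)
         else stats::setNames(numeric(N), igraph::V(g)$name)
  D <- igraph::distances(g)
  diag(D) <- Inf
  clo <- apply(D, 1, function(d) {
    fin <- is.finite(d)
    k <- sum(fin)
    if (closeness == "harmonic")
      return(if (N > 1) sum(1 / d[fin]) / (N - 1) else 0)
    s <- sum(d[fin])
    if (k == 0 || s == 0 || N == 1) 0 else (k / s) * (k / (N - 1))
  })
  rank_desc <- function(x) rank(-x, ties.method = "min")
  tab <- data.frame(node = igraph::V(g)$name,
                    type = if (!is.null(igraph::V(g)$type))
                             igraph::V(g)$type else NA_character_,
                    degree = unname(deg),
                    betweenness = unname(btw),
                    closeness = unname(clo),
                    rank_degree = rank_desc(unname(deg)),
                    rank_betweenness = rank_desc(unname(btw)),
                    rank_closeness = rank_desc(unname(clo)),
                    stringsAsFactors = FALSE)
  top <- lapply(c(degree = "rank_degree", betweenness = "rank_betweenness",
                  closeness = "rank_closeness"),
                function(col) tab$node[tab[[col]] <= top_k])
  in_top <- rowSums(cbind(tab$rank_degree <= top_k,
                          tab$rank_betweenness <= top_k,
                          tab$rank_closeness <= top_k))
  list(table = tab, top = top, hubs = tab$node[in_top >= 2])
}

#' Log-log least-squares fit of the degree distribution
#'
#' Ordinary least squares of `log10(frequency)` on `log10(degree)` over the
#' observed (nonzero) degrees, the usual presentation of an approximate
#' power-law degree distribution.
#'
#' @param degrees integer vector of node degrees.
#' @return list with `slope`, `intercept`, `r_squared` and the fitted
#'   histogram `data` (degree, frequency).
#' @export
powerlaw_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(k) < 3) stop("need >= 3 distinct degrees for the fit")
  fit <- stats::lm(log10(freq) ~ log10(k))
  ss_tot <- sum((log10(freq) - mean(log10(freq)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       data = data.frame(degree = k, frequency = freq))
}

#' Read a GMT gene-set collection
#'
#' @param path path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Over-representation analysis against supplied gene sets
#'
#' Upper-tail hypergeometric test per gene set: given a universe of size
#' `|universe|`, a set intersecting the universe in `K` genes, and a query
#' of `|genes|` genes overlapping the set in `x`, the p-value is
#' `P(X >= x)` -- the same kernel as [shared_mirna_test()]. Gene sets with
#' no member in the universe are skipped.
#'
#' @param genes query gene ids (must all belong to `universe`).
#' @param universe background gene ids.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param p_adjust method passed to [stats::p.adjust()].
#' @return data.frame with `set`, `set_size` (within the universe),
#'   `overlap`, `p`, `q`, `genes` (comma-separated overlap), sorted by `p`.
#' @export
ora <- function(genes, universe, gene_sets, p_adjust = "BH") {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!all(genes %in% universe))
    stop("`genes` must be a subset of `universe`")
  rows <- lapply(names(gene_sets), function(nm) {
    sa <- intersect(gene_sets[[nm]], universe)
    if (length(sa) == 0) return(NULL)
    ov <- intersect(genes, sa)
    data.frame(set = nm,
               set_size = length(sa),
               overlap = length(ov),
               p = hyper_upper(length(ov), length(sa), length(genes),
                               length(universe)),
               genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0),
                      genes = character(0)))
  out$q <- stats::p.adjust(out$p, p_adjust)
  out <- out[order(out$p), c("set", "set_size", "overlap", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

#' PCG neighborhoods of a set of lncRNAs
#'
#' Returns the PCGs adjacent to at least `min_shared` of the given lncRNAs,
#' along with the per-PCG count of adjacent query lncRNAs, the per-lncRNA
#' count of PCG partners, and the pairwise Jaccard similarity of the
#' lncRNAs' neighbor sets.
#'
#' @param network a [cerna_network()].
#' @param lncRNAs query lncRNA ids (must be network nodes; missing ones are
#'   dropped with a message).
#' @param min_shared minimum number of query lncRNAs a PCG must touch.
#' @return list with `pcgs`, `pcg_counts` (data.frame PCG, n_lncRNA),
#'   `lnc_counts` (data.frame lncRNA, n_PCG), `jaccard` (matrix).
#' @export
lncRNA_neighbor_genes <- function(network, lncRNAs, min_shared = 2) {
  stopifnot(inherits(network, "cerna_network"))
  lncRNAs <- unique(lncRNAs)
  present <- lncRNAs %in% network$nodes$node
  if (!all(present)) {
    message(sum(!present), " query lncRNA(s) not in the network")
    lncRNAs <- lncRNAs[present]
  }
  if (length(lncRNAs) == 0) stop("no query lncRNA maps into the network")
  sub <- network$edges[network$edges$lncRNA %in% lncRNAs, , drop = FALSE]
  pcg_counts <- as.data.frame(table(PCG = sub$PCG),
                              stringsAsFactors = FALSE)
  names(pcg_counts)[2] <- "n_lncRNA"
  pcg_counts <- pcg_counts[order(-pcg_counts$n_lncRNA, pcg_counts$PCG), ]
  rownames(pcg_counts) <- NULL
  lnc_counts <- data.frame(
    lncRNA = lncRNAs,
    n_PCG = vapply(lncRNAs,
                   function(l) sum(sub$lncRNA == l), integer(1)),
    stringsAsFactors = FALSE)
  nb <- lapply(lncRNAs, function(l) unique(sub$PCG[sub$lncRNA == l]))
  names(nb) <- lncRNAs
  jac <- outer(seq_along(nb), seq_along(nb), Vectorize(function(i, j) {
    u <- length(union(nb[[i]], nb[[j]]))
    if (u == 0) 0 else length(intersect(nb[[i]], nb[[j]])) / u
  }))
  dimnames(jac) <- list(lncRNAs, lncRNAs)
  list(pcgs = pcg_counts$PCG[pcg_counts$n_lncRNA >= min_shared],
       pcg_counts = pcg_counts,
       lnc_counts = lnc_counts,
       jaccard = jac)
}

#' Tumor/normal separation by risk-lncRNA clustering
#'
#' Bidirectional average-linkage hierarchical clustering on the selected
#' genes' z-scored `log2(x + 1)` expression, with correlation distance
#' `1 - Pearson`. The sample dendrogram is cut at `k = 2` and the cut
#' labels are compared with the tumor/normal annotation via the adjusted
#' Rand index and best-matching accuracy. Constant gene rows are dropped
#' with a warning.
#'
#' @param es an [expression_set()].
#' @param genes gene ids to cluster on (>= 2 after dropping constants).
#' @param k number of sample clusters to cut (2 for tumor/normal).
#' @return list with `sample_clusters` (named integer vector), `gene_order`
#'   (dendrogram order of the genes), `ari`, `accuracy`.
#' @export
bicluster_check <- function(es, genes, k = 2) {
  stopifnot(inherits(es, "expr_set"), length(genes) >= 2,
            ncol(es$expr) >= 4)
  missing <- setdiff(genes, rownames(es$expr))
  if (length(missing))
    stop("gene(s) not in the matrix: ", paste(missing, collapse = ", "))
  M <- log2p1(es$expr[genes, , drop = FALSE])
  const <- apply(M, 1, stats::sd) == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene row(s)")
    M <- M[!const, , drop = FALSE]
  }
  if (nrow(M) < 2) stop("fewer than 2 non-constant genes")
  Z <- t(scale(t(M)))
  hc_samples <- stats::hclust(stats::as.dist(1 - stats::cor(Z)),
                              method = "average")
  hc_genes <- stats::hclust(stats::as.dist(1 - stats::cor(t(Z))),
                            method = "average")
  cl <- stats::cutree(hc_samples, k = k)
  labels <- es$samples$tissue[match(names(cl), es$samples$sample)]
  ari <- mclust::adjustedRandIndex(cl, labels)
  acc <- if (k == 2) {
    a <- mean((cl == 1) == (labels == "tumor"))
    max(a, 1 - a)
  } else NA_real_
  list(sample_clusters = cl,
       gene_order = rownames(Z)[hc_genes$order],
       ari = ari,
       accuracy = acc)
}
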