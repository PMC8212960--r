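#' Hypergeometric upper-tail probability in log-gamma space
#'
#' `P(X >= r)` for `X ~ Hypergeometric(m, t, n)`: the chance that two target
#' sets of sizes `t` and `n`, drawn from a universe of `m` miRNAs, share at
#' least `r` members. Computed by summing `choose(t, i) * choose(m - t,
#' n - i) / choose(m, n)` over `i >= r` with log-gamma arithmetic, so
#' universes in the thousands do not overflow. `r <= 0` gives exactly 1.
#'
#' @param r observed overlap (integer scalar or vector).
#' @param t,n the two set sizes (recycled with `r`).
#' @param m universe size; must satisfy `m >= max(t, n)`.
#' @return numeric vector of upper-tail probabilities in `[0, 1]`.
#' @export
hyper_upper <- function(r, t, n, m) {
  if (any(t > m) || any(n > m))
    stop("set sizes cannot exceed the universe size m")
  args <- data.frame(r = r, t = t, n = n)
  vapply(seq_len(nrow(args)), function(k) {
    r <- args$r[k]; t <- args$t[k]; n <- args$n[k]
    if (r <= 0) return(1)
    kmax <- min(t, n)
    if (r > kmax) return(0)
    i <- r:kmax
    lw <- lchoose(t, i) + lchoose(m - t, n - i) - lchoose(m, n)
    mx <- max(lw)
    min(exp(mx + log(sum(exp(lw - mx)))), 1)
  }, numeric(1))
}

#' Shared-miRNA test for one candidate ceRNA pair
#'
#' Counts the miRNAs shared by the target sets of a lncRNA and a PCG and
#' scores the overlap with the upper-tail hypergeometric probability against
#' a universe of `m` miRNAs.
#'
#' @param lnc_set,pcg_set character (or integer) vectors of miRNA ids
#'   targeting the lncRNA / the PCG.
#' @param m miRNA universe size.
#' @return list with `r` (shared count), `t` (PCG set size), `n` (lncRNA set
#'   size) and `p_hyper`.
#' @export
shared_mirna_test <- function(lnc_set, pcg_set, m) {
  lnc_set <- unique(lnc_set)
  pcg_set <- unique(pcg_set)
  t <- length(pcg_set)
  n <- length(lnc_set)
  r <- length(intersect(lnc_set, pcg_set))
  list(r = r, t = t, n = n, p_hyper = hyper_upper(r, t, n, m))
}

normalize_interactions <- function(tab) {
  stopifnot(is.data.frame(tab), ncol(tab) >= 2)
  tab <- tab[, 1:2]
  names(tab) <- c("miRNA", "target")
  unique(tab)
}

#' Candidate ceRNA pairs by shared-miRNA significance
#'
#' Scores every (lncRNA, PCG) pair sharing at least one miRNA with the
#' hypergeometric test and keeps pairs with `p_hyper < p_cut`. Pairs with no
#' shared miRNA are never emitted. The miRNA universe defaults to the union
#' of miRNAs appearing in either table.
#'
#' @param tab_pcg,tab_lnc interaction edge lists, first column miRNA id,
#'   second column target (PCG / lncRNA) id. Duplicate edges are ignored.
#' @param p_cut hypergeometric p-value threshold.
#' @param m optional universe-size override.
#' @param lnc_ids,pcg_ids optional restriction of the targets considered
#'   (e.g. the differentially expressed genes).
#' @return data.frame with columns `lncRNA`, `PCG`, `r`, `t`, `n`,
#'   `p_hyper`, sorted by `p_hyper`.
#' @export
build_cerna_candidates <- function(tab_pcg, tab_lnc, p_cut = 0.01, m = NULL,
                                   lnc_ids = NULL, pcg_ids = NULL) {
  tab_pcg <- normalize_interactions(tab_pcg)
  tab_lnc <- normalize_interactions(tab_lnc)
  stopifnot(nrow(tab_pcg) > 0, nrow(tab_lnc) > 0)
  mirs <- union(tab_pcg$miRNA, tab_lnc$miRNA)
  if (is.null(m)) m <- length(mirs)
  if (!is.null(pcg_ids)) tab_pcg <- tab_pcg[tab_pcg$target %in% pcg_ids, ]
  if (!is.null(lnc_ids)) tab_lnc <- tab_lnc[tab_lnc$target %in% lnc_ids, ]
  if (nrow(tab_pcg) == 0 || nrow(tab_lnc) == 0)
    return(data.frame(lncRNA = character(0), PCG = character(0),
                      r = integer(0), t = integer(0), n = integer(0),
                      p_hyper = numeric(0)))
  lncs <- unique(tab_lnc$target)
  pcgs <- unique(tab_pcg$target)
  L <- Matrix::sparseMatrix(i = match(tab_lnc$target, lncs),
                            j = match(tab_lnc$miRNA, mirs),
                            x = 1, dims = c(length(lncs), length(mirs)))
  P <- Matrix::sparseMatrix(i = match(tab_pcg$target, pcgs),
                            j = match(tab_pcg$miRNA, mirs),
                            x = 1, dims = c(length(pcgs), length(mirs)))
  R <- L %*% Matrix::t(P)              # shared-miRNA counts, r >= 1 stored
  trip <- Matrix::summary(R)
  n_size <- Matrix::rowSums(L)
  t_size <- Matrix::rowSums(P)
  out <- data.frame(lncRNA = lncs[trip$i],
                    PCG = pcgs[trip$j],
                    r = as.integer(trip$x),
                    t = as.integer(t_size[trip$j]),
                    n = as.integer(n_size[trip$i]),
                    stringsAsFactors = FALSE)
  # many pairs repeat the same (r, t, n); compute each distinct triple once
  key <- paste(out$r, out$t, out$n)
  uk <- !duplicated(key)
  pu <- hyper_upper(out$r[uk], out$t[uk], out$n[uk], m)
  out$p_hyper <- pu[match(key, key[uk])]
  out <- out[out$p_hyper < p_cut, , drop = FALSE]
  out <- out[order(out$p_hyper, out$lncRNA, out$PCG), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positively co-expressed DE lncRNA-PCG pairs
#'
#' Pearson correlation of `log2(x + 1)` expression between every DE lncRNA
#' and DE PCG over the selected samples (tumor by default, matching the
#' dysregulated-network framing; `tissue = "all"` uses every sample). The
#' two-sided p-value comes from `t = pcc * sqrt((N - 2) / (1 - pcc^2))` on
#' `N - 2` df. Only positive correlations above `pcc_cut` are retained.
#' Zero-variance genes are skipped with a message.
#'
#' @param es an [expression_set()].
#' @param de_lnc,de_pcg character vectors of DE lncRNA / PCG ids.
#' @param pcc_cut signed Pearson threshold (retain `pcc > pcc_cut`).
#' @param p_cut correlation p-value threshold.
#' @param tissue `"tumor"`, `"normal"` or `"all"`.
#' @return data.frame with columns `lncRNA`, `PCG`, `pcc`, `p_pcc`.
#' @export
coexpression_pairs <- function(es, de_lnc, de_pcg, pcc_cut = 0.5,
                               p_cut = 0.01, tissue = "tumor") {
  stopifnot(inherits(es, "expr_set"))
  mat <- if (identical(tissue, "all")) es$expr else expr_tissue(es, tissue)
  N <- ncol(mat)
  if (N < 4) stop("need >= 4 samples for the correlation test")
  de_lnc <- intersect(de_lnc, rownames(mat))
  de_pcg <- intersect(de_pcg, rownames(mat))
  X <- log2p1(mat[de_lnc, , drop = FALSE])
  Y <- log2p1(mat[de_pcg, , drop = FALSE])
  const_x <- apply(X, 1, stats::sd) == 0
  const_y <- apply(Y, 1, stats::sd) == 0
  if (any(const_x) || any(const_y))
    message("skipping ", sum(const_x) + sum(const_y),
            " zero-variance gene(s) in the correlation scan")
  X <- X[!const_x, , drop = FALSE]
  Y <- Y[!const_y, , drop = FALSE]
  if (nrow(X) == 0 || nrow(Y) == 0)
    return(data.frame(lncRNA = character(0), PCG = character(0),
                      pcc = numeric(0), p_pcc = numeric(0)))
  C <- stats::cor(t(X), t(Y))
  C2 <- pmin(C^2, 1)
  tt <- C * sqrt((N - 2) / pmax(1 - C2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tt), df = N - 2)
  P[C2 >= 1] <- 0
  hit <- which(C > pcc_cut & P < p_cut, arr.ind = TRUE)
  out <- data.frame(lncRNA = rownames(C)[hit[, 1]],
                    PCG = colnames(C)[hit[, 2]],
                    pcc = C[hit],
                    p_pcc = P[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncRNA, out$PCG), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bipartite ceRNA network container
#'
#' An undirected bipartite graph of lncRNA and PCG nodes given as an edge
#' table. Every edge connects one lncRNA to one PCG; duplicate edges are
#' collapsed.
#'
#' @param edges data.frame with columns `lncRNA` and `PCG` plus any edge
#'   statistics (`r`, `p_hyper`, `pcc`, `p_pcc`, ...).
#' @param node_attrs optional data.frame of node attributes with a `gene`
#'   column (e.g. a [paired_moderated_t()] table supplying `log2FC`, `p`).
#' @return object of class `cerna_network`: list with `edges` and `nodes`.
#' @export
cerna_network <- function(edges, node_attrs = NULL) {
  stopifnot(is.data.frame(edges), all(c("lncRNA", "PCG") %in% names(edges)))
  edges <- edges[!duplicated(edges[, c("lncRNA", "PCG")]), , drop = FALSE]
  if (any(edges$lncRNA == edges$PCG)) stop("self-loops are not allowed")
  nodes <- data.frame(node = c(unique(edges$lncRNA), unique(edges$PCG)),
                      type = rep(c("lncRNA", "PCG"),
                                 c(length(unique(edges$lncRNA)),
                                   length(unique(edges$PCG)))),
                      stringsAsFactors = FALSE)
  if (!is.null(node_attrs) && "gene" %in% names(node_attrs)) {
    idx <- match(nodes$node, node_attrs$gene)
    for (col in intersect(c("log2FC", "p", "q"), names(node_attrs)))
      nodes[[col]] <- node_attrs[[col]][idx]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("cerna_network: %d lncRNAs, %d PCGs, %d edges\n",
              sum(x$nodes$type == "lncRNA"), sum(x$nodes$type == "PCG"),
              nrow(x$edges)))
  invisible(x)
}

#' Convert a ceRNA network to an igraph object
#'
#' @param net a [cerna_network()].
#' @return an undirected [igraph::igraph] graph with node attribute `type`.
#' @export
cerna_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(net$edges[, c("lncRNA", "PCG")],
                                directed = FALSE, vertices = net$nodes)
}

#' Intersect the miRNA-mediated and co-expression networks
#'
#' The dysregulated ceRNA network keeps exactly the (lncRNA, PCG) pairs
#' present in both the hypergeometric candidate list and the co-expression
#' list; edge attributes are merged from the two sources and the node set is
#' restricted to endpoints of retained edges.
#'
#' @param cerna candidate table from [build_cerna_candidates()].
#' @param coexpr pair table from [coexpression_pairs()].
#' @param node_attrs optional DE table attached as node attributes.
#' @return a [cerna_network()].
#' @export
intersect_networks <- function(cerna, coexpr, node_attrs = NULL) {
  edges <- merge(cerna, coexpr, by = c("lncRNA", "PCG"))
  edges <- edges[order(edges$lncRNA, edges$PCG), , drop = FALSE]
  cerna_network(edges, node_attrs = node_attrs)
}

#' Read a ceRNA network edge list from TSV
#'
#' @param path a TSV with at least the columns `lncRNA` and `PCG`.
#' @return a [cerna_network()].
#' @export
read_cerna_network <- function(path) {
  cerna_network(utils::read.delim(path, stringsAsFactors = FALSE))
}
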