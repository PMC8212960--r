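#' Paired tumor/normal expression container
#'
#' Bundles a nonnegative FPKM-like gene-by-sample matrix with gene annotation
#' (gene id and type, `"lncRNA"` or `"PCG"`) and sample metadata (sample id,
#' patient id, tissue). The design is strictly paired: every patient must
#' contribute exactly one `"tumor"` and one `"normal"` sample.
#'
#' @param expr numeric matrix, genes in rows, samples in columns; rownames are
#'   gene ids and colnames are sample ids. Values must be nonnegative.
#' @param genes data.frame with columns `gene` and `type`
#'   (`"lncRNA"`/`"PCG"`), one row per row of `expr` in the same order.
#' @param samples data.frame with columns `sample`, `patient`, `tissue`
#'   (`"tumor"`/`"normal"`), one row per column of `expr` in the same order.
#' @return An object of class `expr_set`: a list with elements `expr`,
#'   `genes`, `samples`.
#' @examples
#' ex <- matrix(rexp(8), 2, 4,
#'              dimnames = list(c("lnc1", "pcg1"), paste0("s", 1:4)))
#' es <- expression_set(
#'   ex,
#'   data.frame(gene = c("lnc1", "pcg1"), type = c("lncRNA", "PCG")),
#'   data.frame(sample = paste0("s", 1:4),
#'              patient = c("p1", "p1", "p2", "p2"),
#'              tissue  = c("tumor", "normal", "tumor", "normal")))
#' es
#' @export
expression_set <- function(expr, genes, samples) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  stopifnot(is.data.frame(genes), is.data.frame(samples))
  if (!all(c("gene", "type") %in% names(genes)))
    stop("`genes` needs columns 'gene' and 'type'")
  if (!all(c("sample", "patient", "tissue") %in% names(samples)))
    stop("`samples` needs columns 'sample', 'patient' and 'tissue'")
  if (nrow(genes) != nrow(expr) || nrow(samples) != ncol(expr))
    stop("dimension mismatch between `expr` and its metadata")
  if (anyNA(expr) || any(expr < 0))
    stop("expression values must be nonnegative and non-missing")
  if (!all(genes$type %in% c("lncRNA", "PCG")))
    stop("gene type must be 'lncRNA' or 'PCG'")
  if (!all(samples$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if (anyDuplicated(genes$gene)) stop("duplicated gene ids")
  if (anyDuplicated(samples$sample)) stop("duplicated sample ids")
  rownames(expr) <- genes$gene
  colnames(expr) <- samples$sample
  tab <- table(samples$patient, samples$tissue)
  if (!all(tab == 1L))
    stop("paired design violated: every patient needs exactly one tumor ",
         "and one normal sample")
  structure(list(expr = expr,
                 genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes (%d lncRNA, %d PCG) x %d samples (%d patients)\n",
              nrow(x$expr), sum(x$genes$type == "lncRNA"),
              sum(x$genes$type == "PCG"), ncol(x$expr),
              length(unique(x$samples$patient))))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$expr)

# log2(x + 1) working transform used throughout the pipeline (FPKM zeros)
log2p1 <- function(x) log2(x + 1)

#' Extract the submatrix for one tissue
#'
#' @param es an [expression_set()].
#' @param tissue `"tumor"` or `"normal"`.
#' @return numeric matrix restricted to the samples of that tissue.
#' @export
expr_tissue <- function(es, tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  es$expr[, es$samples$tissue == tissue, drop = FALSE]
}

# Tumor and normal matrices with columns aligned patient-by-patient.
paired_matrices <- function(es) {
  s <- es$samples
  pts <- unique(s$patient)
  tum <- s$sample[match(paste0(pts, ".tumor"), paste0(s$patient, ".", s$tissue))]
  nor <- s$sample[match(paste0(pts, ".normal"), paste0(s$patient, ".", s$tissue))]
  list(tumor = es$expr[, tum, drop = FALSE],
       normal = es$expr[, nor, drop = FALSE],
       patients = pts)
}

# Row-subset an expr_set, keeping metadata aligned. `keep` is logical or index.
subset_genes <- function(es, keep) {
  expression_set(es$expr[keep, , drop = FALSE],
                 es$genes[keep, , drop = FALSE],
                 es$samples)
}
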