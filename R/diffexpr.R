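#' Remove low-expression genes
#'
#' Drops genes whose group-mean FPKM falls below `min_mean`. Under the
#' default `"both"` rule a gene is retained only when its mean is at least
#' `min_mean` in the tumor group AND in the normal group; under `"either"` a
#' single qualifying group suffices. Gene order is preserved.
#'
#' @param es an [expression_set()].
#' @param min_mean minimum group-mean expression (FPKM units).
#' @param rule `"both"` (default) or `"either"`.
#' @return the filtered [expression_set()].
#' @export
filter_low_expression <- function(es, min_mean = 1,
                                  rule = c("both", "either")) {
  rule <- match.arg(rule)
  stopifnot(inherits(es, "expr_set"))
  mt <- rowMeans(expr_tissue(es, "tumor"))
  mn <- rowMeans(expr_tissue(es, "normal"))
  keep <- if (rule == "both") mt >= min_mean & mn >= min_mean
          else mt >= min_mean | mn >= min_mean
  if (!any(keep))
    warning("no gene passes the expression filter")
  subset_genes(es, keep)
}

# Moment-matching fit of the scaled-F model for gene-wise sample variances:
# s^2 ~ s0^2 * F(df, d0). Matching mean and variance of log(s^2) gives d0
# (via the inverse trigamma) and s0^2. Zero variances are excluded from the
# fit; they are still shrunk toward s0^2 downstream.
fit_var_prior <- function(s2, df) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2)
    return(list(d0 = Inf, s02 = if (length(z)) exp(mean(z)) else 0))
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(df / 2) + digamma(d0 / 2) - log(d0 / df))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  }
  list(d0 = d0, s02 = s02)
}

# Solve trigamma(y) = x by Newton iteration on the log scale.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Paired moderated t-test on log2 expression
#'
#' For each gene, per-patient differences
#' `d_p = log2(tumor_p + 1) - log2(normal_p + 1)` give the log2 fold change
#' (their mean) and an ordinary paired t. Empirical-Bayes variance shrinkage
#' borrows strength across genes: the gene-wise variances are modelled as
#' scaled-F around a prior `(d0, s0^2)` estimated by moment matching on log
#' variances, the posterior variance is
#' `s2_post = (d0 * s0^2 + df * s^2) / (d0 + df)`, and the moderated t uses
#' `df + d0` degrees of freedom. Genes with zero within-pair variance never
#' divide by zero: their statistic is driven by the shrunk variance
#' (and defined as 0 when the fold change is also 0).
#'
#' @param es an [expression_set()] with at least 3 complete patient pairs.
#' @param shrink set `FALSE` to disable shrinkage (`d0 = 0` limit), giving
#'   the ordinary paired t-test.
#' @return data.frame with one row per gene: `gene`, `type`, `mean_tumor`,
#'   `mean_normal` (raw FPKM scale), `log2FC`, `t`, `df_total`, `p`, `q`
#'   (Benjamini-Hochberg). Attributes `d0` and `s02` carry the fitted prior.
#' @export
paired_moderated_t <- function(es, shrink = TRUE) {
  stopifnot(inherits(es, "expr_set"))
  pm <- paired_matrices(es)
  n <- length(pm$patients)
  if (n < 3) stop("need >= 3 complete patient pairs")
  D <- log2p1(pm$tumor) - log2p1(pm$normal)
  lfc <- rowMeans(D)
  df <- n - 1
  s2 <- rowSums((D - lfc)^2) / df

  if (shrink) {
    prior <- fit_var_prior(s2, df)
    d0 <- prior$d0
    s02 <- prior$s02
    s2_post <- if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df)
               else rep(s02, length(s2))
    df_total <- df + d0
  } else {
    d0 <- 0
    s02 <- NA_real_
    s2_post <- s2
    df_total <- df
  }

  se <- sqrt(s2_post / n)
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = es$genes$gene,
                    type = es$genes$type,
                    mean_tumor = rowMeans(pm$tumor),
                    mean_normal = rowMeans(pm$normal),
                    log2FC = lfc,
                    t = tstat,
                    df_total = df_total,
                    p = p,
                    q = stats::p.adjust(p, "BH"),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Select differentially expressed genes
#'
#' Applies the significance and fold-change thresholds to a
#' [paired_moderated_t()] table. The default combines them with AND
#' (`p < p_thresh` and `|log2FC| > lfc_thresh`); `rule = "or"` accepts
#' either condition alone.
#'
#' @param table a DE table from [paired_moderated_t()].
#' @param p_thresh raw p-value threshold.
#' @param lfc_thresh absolute log2 fold-change threshold.
#' @param rule `"and"` (default) or `"or"`.
#' @return list with elements `lncRNA` and `PCG`, each a character vector of
#'   selected gene ids.
#' @export
select_de <- function(table, p_thresh = 0.05, lfc_thresh = 1,
                      rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(nrow(table) > 0)
  hit_p <- table$p < p_thresh
  hit_fc <- abs(table$log2FC) > lfc_thresh
  hit <- if (rule == "and") hit_p & hit_fc else hit_p | hit_fc
  list(lncRNA = table$gene[hit & table$type == "lncRNA"],
       PCG = table$gene[hit & table$type == "PCG"])
}
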