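#' Simulation configuration for the synthetic study
#'
#' Defines every knob of the synthetic-data generator that emulates the
#' pipeline's inputs: a paired tumor/normal FPKM-like expression matrix,
#' miRNA-target interaction tables, a disease seed-gene list, and a survival
#' table -- all with planted ground truth. Defaults mirror the breast-cancer
#' study conditions the pipeline was designed for: 112 paired patients,
#' 1,251 lncRNAs, 13,356 protein-coding genes, a 2,593-miRNA universe,
#' target-set sizes around 55 miRNAs per gene, 318 disease seed genes, and a
#' four-lncRNA prognostic signature with negative log-hazard coefficients.
#'
#' FPKM values are generated as `pmax(2^z - 1, 0)` with `z` Gaussian on the
#' log2 scale, so the pipeline's `log2(x + 1)` transform recovers Gaussian
#' working values. Differential expression is planted as a `de_lfc` log2
#' shift in tumor (sign randomized per gene); true ceRNA pairs additionally
#' share a tumor-only latent factor (weight `latent_weight`) inducing
#' positive tumor co-expression, and `overlap_boost` extra common miRNAs in
#' the interaction tables.
#'
#' @param n_patients number of patients; each contributes one tumor and one
#'   normal sample.
#' @param n_lncRNA,n_PCG,n_miRNA numbers of lncRNAs, protein-coding genes and
#'   miRNAs.
#' @param n_de_lnc,n_de_pcg planted differentially expressed gene counts.
#' @param de_lfc planted absolute log2 fold change (log2 units).
#' @param base_log_mean,base_log_sd mean and sd of the per-gene baseline on
#'   the log2-FPKM scale.
#' @param noise_sd within-gene, between-sample sd on the log2 scale.
#' @param n_true_cerna number of planted true ceRNA (lncRNA, PCG) pairs;
#'   both members are planted DE genes, each gene used in at most one pair.
#' @param targets_per_gene mean miRNA-target-set size (Poisson).
#' @param overlap_boost extra shared miRNAs injected into the target sets of
#'   all genes of a ceRNA module (hence into both members of every true
#'   pair).
#' @param latent_weight weight of the shared tumor-only latent factor
#'   (log2 units per unit of the standard-normal factor).
#' @param n_cerna_modules number of co-regulation modules the true pairs are
#'   grouped into. Pairs of one module share a single latent factor and a
#'   single boost miRNA set, so modules become connected bipartite blocks of
#'   the ceRNA network; module sizes are Zipf-distributed, which gives the
#'   network hubs and an approximately power-law degree distribution.
#'   `NULL` puts every pair in its own module (pure per-pair planting).
#' @param n_seed_genes number of disease seed PCGs emitted.
#' @param seed_bias fraction of seeds drawn from PCG partners of planted
#'   true ceRNA pairs (the remainder uniform over PCGs). The default keeps
#'   seeds a minority of the network's PCG nodes, as in real disease-gene
#'   lists where most network genes are not known disease genes.
#' @param signature_coefs numeric vector of true log-hazard coefficients
#'   (per log2-expression unit); its length sets the planted signature size.
#'   The signature lncRNAs are assigned among the planted DE lncRNAs that
#'   also belong to true ceRNA pairs.
#' @param censor_rate target fraction of censored patients, in `[0, 1)`.
#' @param baseline_hazard_scale baseline time scale (years) of the
#'   exponential event-time model.
#' @param rng_seed integer seed; identical configs with identical seeds give
#'   byte-identical outputs.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_all()], [simulate_expression()]
#' @export
simulation_config <- function(n_patients = 112,
                              n_lncRNA = 1251, n_PCG = 13356, n_miRNA = 2593,
                              n_de_lnc = 300, n_de_pcg = 2400,
                              de_lfc = 2,
                              base_log_mean = 3, base_log_sd = 1.5,
                              noise_sd = 1,
                              n_true_cerna = 200,
                              targets_per_gene = 55,
                              overlap_boost = 10,
                              latent_weight = 1.5,
                              n_cerna_modules = 40,
                              n_seed_genes = 318,
                              seed_bias = 0.2,
                              signature_coefs = c(-0.8, -0.7, -0.6, -0.5),
                              censor_rate = 0.7,
                              baseline_hazard_scale = 12,
                              rng_seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_lncRNA = as.integer(n_lncRNA), n_PCG = as.integer(n_PCG),
              n_miRNA = as.integer(n_miRNA),
              n_de_lnc = as.integer(n_de_lnc), n_de_pcg = as.integer(n_de_pcg),
              de_lfc = de_lfc,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              noise_sd = noise_sd,
              n_true_cerna = as.integer(n_true_cerna),
              targets_per_gene = targets_per_gene,
              overlap_boost = as.integer(overlap_boost),
              latent_weight = latent_weight,
              n_cerna_modules = if (is.null(n_cerna_modules)) NULL
                                else as.integer(n_cerna_modules),
              n_seed_genes = as.integer(n_seed_genes),
              seed_bias = seed_bias,
              signature_coefs = as.numeric(signature_coefs),
              censor_rate = censor_rate,
              baseline_hazard_scale = baseline_hazard_scale,
              rng_seed = as.integer(rng_seed))
  counts <- c("n_patients", "n_lncRNA", "n_PCG", "n_miRNA")
  for (f in counts)
    if (cfg[[f]] < 1L) stop("`", f, "` must be positive")
  if (cfg$n_de_lnc < 0 || cfg$n_de_lnc > cfg$n_lncRNA)
    stop("need 0 <= n_de_lnc <= n_lncRNA")
  if (cfg$n_de_pcg < 0 || cfg$n_de_pcg > cfg$n_PCG)
    stop("need 0 <= n_de_pcg <= n_PCG")
  if (cfg$n_true_cerna > min(cfg$n_de_lnc, cfg$n_de_pcg))
    stop("n_true_cerna cannot exceed min(n_de_lnc, n_de_pcg): ",
         "every true pair joins distinct planted DE genes")
  if (cfg$overlap_boost > cfg$n_miRNA)
    stop("overlap_boost cannot exceed the miRNA universe size")
  if (cfg$overlap_boost < 0) stop("overlap_boost must be >= 0")
  if (cfg$n_seed_genes > cfg$n_PCG)
    stop("n_seed_genes cannot exceed n_PCG")
  if (cfg$seed_bias < 0 || cfg$seed_bias > 1)
    stop("seed_bias must be in [0, 1]")
  if (length(cfg$signature_coefs) > max(cfg$n_true_cerna, 0L))
    stop("signature lncRNAs must fit inside the planted true ceRNA pairs; ",
         "increase n_true_cerna or shorten signature_coefs")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (cfg$baseline_hazard_scale <= 0) stop("baseline_hazard_scale must be > 0")
  if (is.na(cfg$rng_seed) || abs(cfg$rng_seed) > 2^31 - 100)
    stop("rng_seed must be a 32-bit integer")
  if (cfg$targets_per_gene < 0) stop("targets_per_gene must be >= 0")
  if (!is.null(cfg$n_cerna_modules) && cfg$n_cerna_modules < 1)
    stop("n_cerna_modules must be positive (or NULL for per-pair planting)")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d patients, %d lncRNA / %d PCG / %d miRNA, ",
                     "%d+%d planted DE, %d true ceRNA pairs, ",
                     "%d-lncRNA signature, seed %d\n"),
              x$n_patients, x$n_lncRNA, x$n_PCG, x$n_miRNA,
              x$n_de_lnc, x$n_de_pcg, x$n_true_cerna,
              length(x$signature_coefs), x$rng_seed))
  invisible(x)
}

sim_gene_ids <- function(config) {
  list(lnc = sprintf("lnc%04d", seq_len(config$n_lncRNA)),
       pcg = sprintf("pcg%05d", seq_len(config$n_PCG)),
       mir = sprintf("mir%04d", seq_len(config$n_miRNA)))
}

# The shared experimental design: which genes are DE (and in which direction),
# which (lncRNA, PCG) pairs are true ceRNA pairs, and which lncRNAs carry the
# survival signature. Re-derived deterministically from (config, rng_seed) so
# that simulate_expression() and simulate_interactions() agree without
# sharing state.
sim_design <- function(config) {
  ids <- sim_gene_ids(config)
  set.seed(config$rng_seed)
  de_lnc <- sample(ids$lnc, config$n_de_lnc)
  de_pcg <- sample(ids$pcg, config$n_de_pcg)
  sign_lnc <- sample(c(-1, 1), config$n_de_lnc, replace = TRUE)
  sign_pcg <- sample(c(-1, 1), config$n_de_pcg, replace = TRUE)
  k <- length(config$signature_coefs)
  n_pair <- config$n_true_cerna
  pair_lnc <- if (n_pair > 0) sample(de_lnc, n_pair) else character(0)
  pair_pcg <- if (n_pair > 0) sample(de_pcg, n_pair) else character(0)
  # co-regulation modules with Zipf-distributed sizes: pairs of a module
  # share one latent factor and one boost miRNA set, so the dysregulated
  # network acquires hubs and a heavy-tailed degree distribution. The
  # signature pairs are kept in singleton modules (each prognostic lncRNA a
  # distinct regulator exclusively coupled to its partner PCG), so disease
  # seeds drawn from their partners are specifically adjacent to them.
  n_mod <- if (is.null(config$n_cerna_modules)) max(n_pair, 1L)
           else min(config$n_cerna_modules, max(n_pair, 1L))
  module <- if (n_pair > 0)
    k + sample(seq_len(n_mod), n_pair, replace = TRUE,
               prob = 1 / seq_len(n_mod))
  else integer(0)
  if (k > 0) module[seq_len(k)] <- seq_len(k)
  # signature lncRNAs sit inside true ceRNA pairs, so that disease seeds
  # biased toward pair partners are network-adjacent to the signature
  sig_lnc <- if (k > 0) pair_lnc[seq_len(k)] else character(0)
  sig <- stats::setNames(config$signature_coefs, sig_lnc)
  list(ids = ids,
       de_lnc = stats::setNames(sign_lnc, de_lnc),
       de_pcg = stats::setNames(sign_pcg, de_pcg),
       pairs = data.frame(lncRNA = pair_lnc, PCG = pair_pcg,
                          module = module, stringsAsFactors = FALSE),
       signature = sig)
}

sim_truth <- function(design) {
  structure(list(de_lnc_ids = names(design$de_lnc),
                 de_pcg_ids = names(design$de_pcg),
                 de_sign_lnc = design$de_lnc,
                 de_sign_pcg = design$de_pcg,
                 true_cerna_pairs = design$pairs,
                 signature = design$signature,
                 seed_gene_ids = NULL),
            class = "sim_truth")
}

#' Simulate a paired tumor/normal expression matrix
#'
#' Non-DE genes share one per-gene log-normal law in both tissues; planted DE
#' genes are shifted by `de_lfc` (sign randomized per gene, recorded in the
#' truth) in tumor samples; planted true ceRNA pairs additionally share a
#' per-pair tumor-only latent factor that induces positive co-expression.
#'
#' @param config a [simulation_config()].
#' @return list with `es` (an [expression_set()] of `2 * n_patients` paired
#'   samples) and `truth` (planted DE ids with shift signs, true ceRNA pairs,
#'   signature coefficients).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients < 3L)
    stop("n_patients must be >= 3 (the paired test is undefined below that)")
  d <- sim_design(config)
  set.seed(config$rng_seed + 1L)
  genes <- c(d$ids$lnc, d$ids$pcg)
  G <- length(genes)
  np <- config$n_patients
  patients <- sprintf("pt%04d", seq_len(np))
  tum <- paste0(patients, "_T")
  nor <- paste0(patients, "_N")

  mu <- stats::rnorm(G, config$base_log_mean, config$base_log_sd)
  names(mu) <- genes
  # signature lncRNAs are kept expressed (baseline at or above the cohort
  # typical level): a prognostic marker below the detection filter would be
  # meaningless, and real signature candidates pass the FPKM filter
  if (length(d$signature))
    mu[names(d$signature)] <- pmax(mu[names(d$signature)],
                                   config$base_log_mean)
  z_t <- mu + matrix(stats::rnorm(G * np, 0, config$noise_sd), G, np)
  z_n <- mu + matrix(stats::rnorm(G * np, 0, config$noise_sd), G, np)
  rownames(z_t) <- rownames(z_n) <- genes

  # planted DE shift, tumor only
  z_t[names(d$de_lnc), ] <- z_t[names(d$de_lnc), , drop = FALSE] +
    d$de_lnc * config$de_lfc
  z_t[names(d$de_pcg), ] <- z_t[names(d$de_pcg), , drop = FALSE] +
    d$de_pcg * config$de_lfc

  # shared tumor-only latent factor per ceRNA module
  if (nrow(d$pairs) > 0 && config$latent_weight != 0) {
    mods <- sort(unique(d$pairs$module))
    f <- matrix(stats::rnorm(length(mods) * np), length(mods), np)
    fi <- match(d$pairs$module, mods)
    z_t[d$pairs$lncRNA, ] <- z_t[d$pairs$lncRNA, , drop = FALSE] +
      config$latent_weight * f[fi, , drop = FALSE]
    z_t[d$pairs$PCG, ] <- z_t[d$pairs$PCG, , drop = FALSE] +
      config$latent_weight * f[fi, , drop = FALSE]
  }

  expr <- cbind(pmax(2^z_t - 1, 0), pmax(2^z_n - 1, 0))
  colnames(expr) <- c(tum, nor)
  es <- expression_set(
    expr,
    data.frame(gene = genes,
               type = rep(c("lncRNA", "PCG"),
                          c(config$n_lncRNA, config$n_PCG)),
               stringsAsFactors = FALSE),
    data.frame(sample = c(tum, nor),
               patient = c(patients, patients),
               tissue = rep(c("tumor", "normal"), each = np),
               stringsAsFactors = FALSE))
  list(es = es, truth = sim_truth(d))
}

#' Simulate miRNA-target interaction tables
#'
#' Each gene receives an independent miRNA target set of size
#' `Poisson(targets_per_gene)` drawn from the miRNA universe; for every
#' planted true ceRNA pair, `overlap_boost` additional common miRNAs are
#' injected into both members' sets. No duplicate edges are emitted.
#'
#' @param config a [simulation_config()].
#' @return list with `mirna_pcg` and `mirna_lnc` edge data.frames
#'   (columns `miRNA`, `target`) and `truth`.
#' @export
simulate_interactions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- sim_design(config)
  set.seed(config$rng_seed + 2L)
  draw_sets <- function(gene_ids) {
    sizes <- pmin(stats::rpois(length(gene_ids), config$targets_per_gene),
                  config$n_miRNA)
    sets <- lapply(sizes, function(s) sample.int(config$n_miRNA, s))
    names(sets) <- gene_ids
    sets
  }
  lnc_sets <- draw_sets(d$ids$lnc)
  pcg_sets <- draw_sets(d$ids$pcg)
  if (nrow(d$pairs) > 0 && config$overlap_boost > 0) {
    for (mod in sort(unique(d$pairs$module))) {
      boost <- sample.int(config$n_miRNA, config$overlap_boost)
      rows <- which(d$pairs$module == mod)
      for (l in unique(d$pairs$lncRNA[rows]))
        lnc_sets[[l]] <- unique(c(lnc_sets[[l]], boost))
      for (p in unique(d$pairs$PCG[rows]))
        pcg_sets[[p]] <- unique(c(pcg_sets[[p]], boost))
    }
  }
  to_edges <- function(sets) {
    n <- lengths(sets)
    data.frame(miRNA = d$ids$mir[unlist(sets, use.names = FALSE)],
               target = rep(names(sets), n),
               stringsAsFactors = FALSE)
  }
  list(mirna_pcg = to_edges(pcg_sets),
       mirna_lnc = to_edges(lnc_sets),
       truth = sim_truth(d))
}

#' Simulate a survival table from tumor expression
#'
#' Event times are exponential with per-patient log-hazard
#' `sum(coef_i * centered log2(expr_i + 1))` over the planted signature
#' lncRNAs, scaled by `baseline_hazard_scale`. Censoring is independent
#' uniform, with its upper bound calibrated on the realized event times so
#' the expected censored fraction is approximately `censor_rate`. Age and
#' stage are simulated independent of expression.
#'
#' @param es an [expression_set()] holding the tumor samples of the cohort
#'   (normal samples, if present, are ignored).
#' @param config a [simulation_config()] (must be the one that generated
#'   `es`, so the signature lncRNAs exist in the matrix).
#' @return data.frame with columns `sample`, `time` (> 0, years), `event`
#'   (0/1), `age`, `stage` -- one row per patient (their tumor sample).
#' @export
simulate_survival <- function(es, config) {
  stopifnot(inherits(config, "sim_config"), inherits(es, "expr_set"))
  d <- sim_design(config)
  set.seed(config$rng_seed + 3L)
  tum <- expr_tissue(es, "tumor")
  sig <- d$signature
  if (length(sig)) {
    missing <- setdiff(names(sig), rownames(tum))
    if (length(missing))
      stop("signature lncRNA(s) not in the expression matrix: ",
           paste(missing, collapse = ", "))
    le <- log2p1(tum[names(sig), , drop = FALSE])
    lp <- as.vector(crossprod(le - rowMeans(le), sig))
  } else {
    lp <- rep(0, ncol(tum))
  }
  n <- ncol(tum)
  t_event <- stats::rexp(n, rate = exp(lp)) * config$baseline_hazard_scale
  if (config$censor_rate > 0) {
    cens_frac <- function(q) mean(pmin(t_event / q, 1)) - config$censor_rate
    q <- stats::uniroot(cens_frac,
                        interval = c(min(t_event) * 1e-6, max(t_event) * 1e6),
                        tol = 1e-10)$root
    t_cens <- stats::runif(n, 0, q)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  time <- pmax(time, 1e-8)
  data.frame(sample = colnames(tum),
             time = time,
             event = event,
             age = pmin(pmax(round(stats::rnorm(n, 58, 9)), 25), 90),
             stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                            prob = c(0.18, 0.55, 0.22, 0.05)),
             stringsAsFactors = FALSE)
}

#' Simulate the disease seed-gene list
#'
#' Draws `n_seed_genes` PCG ids, a `seed_bias` fraction of which come from
#' the partner pool (without replacement, up to pool exhaustion); the
#' remainder are uniform over the other PCGs. With `pool = "signature"`
#' (default) the partner pool is the PCG side of the ceRNA modules that
#' contain a signature lncRNA, so known disease genes cluster in the
#' network neighborhood of the planted risk lncRNAs; `pool = "all_pairs"`
#' uses the partners of every planted true ceRNA pair.
#'
#' @param truth the `truth` element returned by [simulate_expression()] or
#'   [simulate_interactions()].
#' @param config the matching [simulation_config()].
#' @param pool `"signature"` or `"all_pairs"`.
#' @return character vector of seed PCG ids.
#' @export
simulate_disease_genes <- function(truth, config,
                                   pool = c("signature", "all_pairs")) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  pool <- match.arg(pool)
  d <- sim_design(config)
  set.seed(config$rng_seed + 4L)
  pairs <- truth$true_cerna_pairs
  pool_ids <- if (pool == "signature" && length(truth$signature)) {
    sig_modules <- unique(pairs$module[pairs$lncRNA %in%
                                         names(truth$signature)])
    unique(pairs$PCG[pairs$module %in% sig_modules])
  } else {
    unique(pairs$PCG)
  }
  n <- config$n_seed_genes
  want_pool <- sum(stats::runif(n) < config$seed_bias)
  from_pool <- sample(pool_ids, min(want_pool, length(pool_ids)))
  rest <- sample(setdiff(d$ids$pcg, from_pool), n - length(from_pool))
  sample(c(from_pool, rest))
}

#' Run the full generator
#'
#' Convenience wrapper producing every pipeline input in one call.
#'
#' @param config a [simulation_config()].
#' @return list of class `lnc_sim` with elements `es`, `mirna_pcg`,
#'   `mirna_lnc`, `seeds`, `survival`, `truth`, `config`.
#' @export
simulate_all <- function(config) {
  ex <- simulate_expression(config)
  it <- simulate_interactions(config)
  truth <- ex$truth
  seeds <- simulate_disease_genes(truth, config)
  truth$seed_gene_ids <- seeds
  surv <- simulate_survival(ex$es, config)
  structure(list(es = ex$es,
                 mirna_pcg = it$mirna_pcg,
                 mirna_lnc = it$mirna_lnc,
                 seeds = seeds,
                 survival = surv,
                 truth = truth,
                 config = config),
            class = "lnc_sim")
}

#' Write a simulated study to disk
#'
#' Emits the plain-text files consumed by the pipeline readers:
#' `expression.tsv` (gene, type, one column per sample), `samples.tsv`,
#' `mirna_pcg.tsv`, `mirna_lnc.tsv`, `seeds.txt`, `survival.tsv`, and a
#' single `truth.tsv` (long format) holding the planted ground truth.
#'
#' @param sim result of [simulate_all()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "lnc_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(cbind(sim$es$genes, as.data.frame(sim$es$expr)), "expression.tsv")
  tsv(sim$es$samples, "samples.tsv")
  tsv(sim$mirna_pcg, "mirna_pcg.tsv")
  tsv(sim$mirna_lnc, "mirna_lnc.tsv")
  writeLines(sim$seeds, file.path(outdir, "seeds.txt"))
  tsv(sim$survival, "survival.tsv")
  tr <- sim$truth
  truth_long <- rbind(
    data.frame(section = "de_lnc", id1 = names(tr$de_sign_lnc), id2 = "",
               value = unname(tr$de_sign_lnc)),
    data.frame(section = "de_pcg", id1 = names(tr$de_sign_pcg), id2 = "",
               value = unname(tr$de_sign_pcg)),
    if (nrow(tr$true_cerna_pairs))
      data.frame(section = "true_cerna", id1 = tr$true_cerna_pairs$lncRNA,
                 id2 = tr$true_cerna_pairs$PCG,
                 value = as.numeric(tr$true_cerna_pairs$module)),
    if (length(tr$signature))
      data.frame(section = "signature", id1 = names(tr$signature), id2 = "",
                 value = unname(tr$signature)),
    if (length(tr$seed_gene_ids))
      data.frame(section = "seed_gene", id1 = tr$seed_gene_ids, id2 = "",
                 value = NA_real_))
  tsv(truth_long, "truth.tsv")
  invisible(outdir)
}

#' Read an expression matrix and sample table written by [write_simulation()]
#'
#' @param expr_path path to `expression.tsv` (columns `gene`, `type`, then
#'   one column per sample).
#' @param samples_path path to `samples.tsv` (`sample`, `patient`, `tissue`).
#' @return an [expression_set()].
#' @export
read_expression_set <- function(expr_path, samples_path) {
  ex <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  genes <- ex[, c("gene", "type")]
  mat <- as.matrix(ex[, setdiff(names(ex), c("gene", "type")), drop = FALSE])
  rownames(mat) <- genes$gene
  expression_set(mat[, samples$sample, drop = FALSE], genes, samples)
}
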