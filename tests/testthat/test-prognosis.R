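surv_df <- function(time, event, sample = NULL) {
  data.frame(sample = if (is.null(sample)) paste0("s", seq_along(time))
             else sample,
             time = time, event = event)
}

test_that("log-rank statistic matches the hand-tabulated example", {
  # 10 patients, alternating groups, mixed censoring; O/E/V tabulated by
  # hand (helper reproduces the arithmetic; the constant is frozen)
  sv <- surv_df(c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10),
                c(1, 1, 0, 1, 0, 1, 0, 1, 1, 0))
  g <- rep(c("A", "B"), each = 5)
  lt <- logrank_test(g, sv)
  expect_equal(lt$statistic, 0.0711566122, tolerance = 1e-8)
  expect_equal(lt$statistic, logrank_by_hand(sv$time, sv$event, g),
               tolerance = 1e-10)
  expect_equal(lt$p, pchisq(lt$statistic, 1, lower.tail = FALSE))
  # identical groups -> statistic 0, p 1
  sv2 <- surv_df(rep(c(1, 2, 3), 2), rep(1, 6))
  lt2 <- logrank_test(rep(c("A", "B"), each = 3), sv2)
  expect_equal(lt2$statistic, 0, tolerance = 1e-12)
  expect_equal(lt2$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(rep("A", 6), sv2), "two nonempty")
  expect_error(logrank_test(rep(c("A", "B"), 3), surv_df(1:6, rep(0, 6))),
               "no events")
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(13)
  sv <- surv_df(rexp(40), rbinom(40, 1, 0.7))
  ps <- vapply(1:200, function(i)
    logrank_test(sample(rep(c("A", "B"), 20)), sv)$p, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Kaplan-Meier estimate reduces to the ECDF without censoring", {
  set.seed(2)
  tms <- sort(sample(1:50, 20))
  km <- km_estimate(surv_df(tms, rep(1, 20)))
  ecdf_surv <- 1 - ecdf(tms)(km$curve$time)
  expect_equal(km$curve$surv, ecdf_surv, tolerance = 1e-12)
  expect_true(km$median_defined)
  # hand product on (1, 2+, 3, 4): S = 3/4, 3/4, 3/8, 0
  km2 <- km_estimate(surv_df(c(1, 2, 3, 4), c(1, 0, 1, 1)))
  expect_equal(km2$curve$surv, c(3 / 4, 3 / 4, 3 / 8, 0), tolerance = 1e-12)
  # all censored: S stays 1, median undefined
  km3 <- km_estimate(surv_df(1:5, rep(0, 5)))
  expect_true(all(km3$curve$surv == 1))
  expect_false(km3$median_defined)
})

test_that("Cox fit matches a grid-search oracle and behaves under the null", {
  # 4-subject toy data, binary covariate, no ties: compare with the argmax
  # of the explicitly enumerated partial likelihood
  sv <- surv_df(c(2, 5, 7, 9), c(1, 1, 1, 1))
  x <- c(1, 0, 1, 0)
  pl <- function(b) {
    risk <- function(at) sum(exp(b * x[sv$time >= at]))
    sum(vapply(which(sv$event == 1), function(i)
      b * x[i] - log(risk(sv$time[i])), numeric(1)))
  }
  grid <- seq(-4, 4, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit <- fit_cox(matrix(x, ncol = 1), sv)
  expect_equal(fit$coefficients$coef, b_grid, tolerance = 1e-4)
  expect_false(fit$separation)

  # covariate independent of survival: |coef| < 3 SE at n = 1000
  set.seed(3)
  svn <- surv_df(rexp(1000), rbinom(1000, 1, 0.8))
  xn <- rnorm(1000)
  fn <- fit_cox(matrix(xn, ncol = 1), svn)
  expect_lt(abs(fn$coefficients$coef), 3 * fn$coefficients$se)

  # planted effect 0.8 recovered within 0.15 across seeds
  coefs <- vapply(1:10, function(s) {
    set.seed(400 + s)
    xx <- rnorm(500)
    tt <- rexp(500, exp(0.8 * xx))
    fit_cox(matrix(xx, ncol = 1), surv_df(tt, rep(1, 500)))$coefficients$coef
  }, numeric(1))
  expect_lt(abs(mean(coefs) - 0.8), 0.15)

  expect_error(fit_cox(matrix(1, 10, 1), surv_df(1:10, rep(1, 10))),
               "constant")
})

test_that("risk scores are exact linear combinations of log2 expression", {
  mat <- rbind(lncA = rep(2^4 - 1, 3), lncB = rep(2^1 - 1, 3))
  colnames(mat) <- paste0("s", 1:3)
  sc <- risk_score(mat, c(lncA = 0.5, lncB = -2))
  expect_equal(unname(sc), rep(0.5 * 4 - 2 * 1, 3))   # = 0
  expect_equal(unname(sc), rep(0, 3))
  expect_equal(unname(risk_score(mat, c(lncA = 0, lncB = 0))), rep(0, 3))
  # single lncRNA with unit coefficient returns its transformed expression
  expect_equal(unname(risk_score(mat, c(lncA = 1))), rep(4, 3))
  expect_error(risk_score(mat, c(zzz = 1)), "zzz")
  expect_error(risk_score(mat, c(1, 2)), "named")
})

test_that("maxstat scan equals a brute-force cutoff search", {
  set.seed(5)
  n <- 30
  vals <- round(rnorm(n, 10, 3), 1)
  sv <- surv_df(rexp(n, exp(0.3 * scale(vals)[, 1])), rbinom(n, 1, 0.8))
  ms <- maxstat_cutoff(vals, sv)
  qs <- quantile(vals, c(0.1, 0.9), names = FALSE)
  cand <- sort(unique(vals))
  cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(vals)]
  brute <- vapply(cand, function(cc) {
    hi <- vals > cc
    if (!any(hi) || all(hi)) return(NA_real_)
    tryCatch(logrank_test(hi, sv)$statistic, error = function(e) NA_real_)
  }, numeric(1))
  expect_equal(ms$statistic, max(brute, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(ms$cutoff, cand[which.max(brute)])
  expect_true(ms$p_corrected >= ms$p)
  # perfectly separating values put the cutoff between the clusters
  sv_sep <- surv_df(c(rep(1, 10), rep(100, 10)), rep(1, 20))
  vals_sep <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  ms_sep <- maxstat_cutoff(vals_sep, sv_sep)
  expect_gte(ms_sep$cutoff, max(vals_sep[1:10]) - 1e-12)
  expect_lt(ms_sep$cutoff, min(vals_sep[11:20]))
  expect_error(maxstat_cutoff(rep(1, 20), sv_sep), "admissible")
})

test_that("survival screen keeps strong lncRNAs and reports anti-conservative nulls", {
  # planted signature lncRNAs retained at p < 0.05 in most runs
  kept <- vapply(1:10, function(s) {
    cfg <- test_config(n_patients = 150, signature_coefs = c(-1.2, 1.0),
                       censor_rate = 0.3, rng_seed = 600 + s)
    ex <- simulate_expression(cfg)
    sv <- simulate_survival(ex$es, cfg)
    scr <- screen_survival_lncRNAs(names(ex$truth$signature), ex$es, sv)
    all(scr$selected)
  }, logical(1))
  expect_gte(mean(kept), 0.9)

  # null lncRNAs: the maximally selected scan is anti-conservative, so the
  # raw-p selection rate exceeds the nominal level (documented behaviour)
  set.seed(77)
  n <- 120
  nulls <- paste0("n", 1:40)
  mat <- matrix(2^rnorm(40 * n, 4, 1), 40, n,
                dimnames = list(nulls, paste0("s", 1:n)))
  sv <- surv_df(rexp(n, 0.2), rbinom(n, 1, 0.7), sample = colnames(mat))
  scr <- screen_survival_lncRNAs(nulls, mat, sv)
  expect_gt(mean(scr$selected), 0.05)
  # empty candidate list is an empty table
  expect_equal(nrow(screen_survival_lncRNAs(character(0), mat, sv)), 0)
})

test_that("the search's vectorized log-rank equals the model-frame version", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    sv <- surv_df(round(rexp(n), 2) + 0.01, rbinom(n, 1, 0.7))  # ties likely
    hi <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(hi)) < 2 || sum(sv$event) == 0) next
    prep <- lncRisk:::logrank_prep(sv)
    expect_equal(lncRisk:::fast_logrank(hi, prep),
                 logrank_test(hi, sv)$statistic, tolerance = 1e-10)
  }
})

test_that("subset search counts all non-empty subsets and respects the contract", {
  set.seed(9)
  n <- 60
  genes <- paste0("l", 1:4)
  mat <- matrix(2^rnorm(4 * n, 4, 1), 4, n,
                dimnames = list(genes, paste0("s", 1:n)))
  sv <- surv_df(rexp(n, 0.2), rbinom(n, 1, 0.8), sample = colnames(mat))
  res <- exhaustive_signature_search(genes, mat, sv)
  expect_equal(nrow(res$models), 2^4 - 1)
  expect_false(any(duplicated(res$models$lncRNAs)))
  expect_equal(res$best$logrank_p, min(res$models$logrank_p, na.rm = TRUE))
  expect_equal(sum(res$best$group_sizes), n)
  # single candidate evaluates exactly one model
  res1 <- exhaustive_signature_search(genes[1], mat, sv)
  expect_equal(nrow(res1$models), 1)
  # risk-score linearity: scaling coefficients leaves split and p unchanged
  cf <- res$best$coefficients
  sc1 <- risk_score(mat[res$best$lncRNAs, , drop = FALSE], cf)
  sc2 <- risk_score(mat[res$best$lncRNAs, , drop = FALSE], 3 * cf)
  expect_equal(sc1 > median(sc1), sc2 > median(sc2))
})

test_that("planted signatures win the subset search in most runs", {
  hits <- vapply(1:10, function(s) {
    cfg <- test_config(n_patients = 400, n_lncRNA = 60, n_de_lnc = 25,
                       n_true_cerna = 12,
                       signature_coefs = c(-1.0, -0.9, 0.8),
                       censor_rate = 0.3, rng_seed = 700 + s)
    ex <- simulate_expression(cfg)
    sv <- simulate_survival(ex$es, cfg)
    sig <- names(ex$truth$signature)
    nulls <- setdiff(ex$truth$de_lnc_ids, sig)[1:7]
    res <- exhaustive_signature_search(c(sig, nulls), ex$es, sv)
    all(sig %in% res$best$lncRNAs)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("time-dependent AUC is 0.5 under the null and 1 for perfect ranking", {
  set.seed(15)
  n <- 2000
  sv <- surv_df(rexp(n, 0.3), rep(1, n))
  auc_null <- time_dependent_auc(rnorm(n), sv, horizons = c(1, 3))
  expect_true(all(abs(auc_null$auc - 0.5) < 0.05))
  # no censoring, score = -time: perfect discrimination at any horizon
  sv2 <- surv_df(1:100 / 10, rep(1, 100))
  auc_perf <- time_dependent_auc(-sv2$time, sv2, horizons = c(1, 3, 5))
  expect_equal(auc_perf$auc, c(1, 1, 1))
  # without censoring the IPCW estimate equals the plain rank AUC
  set.seed(16)
  scores <- rnorm(300)
  sv3 <- surv_df(rexp(300, exp(0.5 * scores)), rep(1, 300))
  for (tau in c(1, 3)) {
    case <- sv3$time <= tau
    ctrl <- sv3$time > tau
    plain <- mean(outer(scores[case], scores[ctrl], ">") +
                    0.5 * outer(scores[case], scores[ctrl], "=="))
    got <- time_dependent_auc(scores, sv3, horizons = tau)$auc
    expect_equal(got, plain, tolerance = 1e-12)
  }
  # horizon beyond follow-up has no controls -> NA
  expect_true(is.na(time_dependent_auc(rnorm(100), sv2,
                                       horizons = 20)$auc))
})

test_that("independence analysis reduces to the univariate fit for one covariate", {
  set.seed(17)
  n <- 200
  sv <- surv_df(rexp(n, 0.3), rbinom(n, 1, 0.8))
  grp <- sample(c("high", "low"), n, replace = TRUE)
  tab <- independence_analysis(grp, sv)
  expect_equal(tab$HR_uni, tab$HR_multi, tolerance = 1e-10)
  expect_equal(tab$p_uni, tab$p_multi, tolerance = 1e-10)
  # planted stage effect (HR 2) is recovered inside the confidence interval
  stage <- sample(c("I", "II", "III", "IV"), 1000, replace = TRUE)
  hz <- ifelse(stage %in% c("III", "IV"), 2, 1)
  sv2 <- surv_df(rexp(1000, 0.2 * hz), rbinom(1000, 1, 0.85))
  grp2 <- sample(c("high", "low"), 1000, replace = TRUE)
  tab2 <- independence_analysis(grp2, sv2, age = rnorm(1000, 58, 9),
                                stage = stage)
  row <- tab2[tab2$variable == "stage", ]
  expect_gt(2, row$lower_multi)
  expect_lt(2, row$upper_multi * 1.0000001)
  # null signature: CI covers 1
  row_sig <- tab2[tab2$variable == "signature", ]
  expect_true(row_sig$lower_multi < 1 && row_sig$upper_multi > 1)
})
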