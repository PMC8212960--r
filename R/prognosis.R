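check_survival <- function(survival) {
  stopifnot(is.data.frame(survival),
            all(c("time", "event") %in% names(survival)))
  if (any(survival$time <= 0)) stop("survival times must be > 0")
  if (!all(survival$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(survival)
}

surv_obj <- function(survival) {
  survival::Surv(survival$time, survival$event)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each event time,
#' observed vs expected events under the hypergeometric margins; the
#' chi-square statistic has 1 df.
#'
#' @param groups two-level grouping (factor/character/logical), one entry
#'   per row of `survival`.
#' @param survival data.frame with columns `time` and `event`.
#' @return list with `statistic` (chi-square), `p`, `obs`, `exp`, `n`.
#' @export
logrank_test <- function(groups, survival) {
  check_survival(survival)
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("need exactly two nonempty groups")
  if (sum(survival$event) < 1) stop("no events observed")
  sd <- survival::survdiff(surv_obj(survival) ~ g)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = unname(sd$obs), exp = unname(sd$exp),
       n = as.vector(table(g)))
}

# Lausen-Schumacher improved-Bonferroni approximation for the p-value of a
# maximally selected standardized statistic b over the quantile band
# (q1, q2). Reported alongside the raw minimum p for honesty about the
# selection bias of the cutpoint scan.
maxstat_corrected_p <- function(b, q1, q2) {
  if (!is.finite(b) || b <= 0) return(1)
  lg <- log((q2 * (1 - q1)) / (q1 * (1 - q2)))
  p <- stats::dnorm(b) * (b - 1 / b) * lg + 4 * stats::dnorm(b) / b
  min(max(p, 2 * stats::pnorm(-b)), 1)
}

#' Maximally selected log-rank cutpoint
#'
#' Scans every distinct value of `values` inside the quantile band as a
#' candidate cutoff (low group `<= cutoff`, high group `> cutoff`), computes
#' the two-group log-rank statistic for each admissible split, and returns
#' the cutoff maximizing it (ties resolved toward the lower cutoff).
#'
#' @param values numeric vector, one per patient (same order as `survival`).
#' @param survival data.frame with `time` and `event`.
#' @param quantile_range candidate band as quantile probabilities.
#' @return list with `cutoff`, `statistic` (chi-square), `p` (uncorrected
#'   minimum log-rank p), `p_corrected` (Lausen-Schumacher-type), and the
#'   scan table `candidates`.
#' @export
maxstat_cutoff <- function(values, survival, quantile_range = c(0.1, 0.9)) {
  check_survival(survival)
  stopifnot(length(values) == nrow(survival))
  qs <- stats::quantile(values, quantile_range, names = FALSE)
  cand <- sort(unique(values))
  cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(values)]
  stats_at <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    hi <- values > cand[i]
    if (!any(hi) || all(hi)) next
    lt <- tryCatch(logrank_test(hi, survival), error = function(e) NULL)
    if (!is.null(lt)) stats_at[i] <- lt$statistic
  }
  ok <- which(is.finite(stats_at))
  if (length(ok) == 0)
    stop("no admissible cutoff in the quantile range")
  best <- ok[which.max(stats_at[ok])]   # which.max -> first max = lower cutoff
  stat <- stats_at[best]
  list(cutoff = cand[best],
       statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       p_corrected = maxstat_corrected_p(sqrt(stat), quantile_range[1],
                                         quantile_range[2]),
       candidates = data.frame(cutoff = cand, statistic = stats_at))
}

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator; the median is the earliest time at which the
#' survival curve drops to 0.5 or below, flagged undefined if the curve
#' never reaches 0.5.
#'
#' @param survival data.frame with `time` and `event`.
#' @return list with `curve` (data.frame time, n_risk, n_event, n_censor,
#'   surv), `median`, `median_defined`.
#' @export
km_estimate <- function(survival) {
  check_survival(survival)
  sf <- survival::survfit(surv_obj(survival) ~ 1)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, n_censor = sf$n.censor,
                      surv = sf$surv)
  below <- curve$time[curve$surv <= 0.5]
  if (length(below)) list(curve = curve, median = min(below),
                          median_defined = TRUE)
  else list(curve = curve, median = NA_real_, median_defined = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling (via the survival
#' machinery). Reports hazard ratios with 95% confidence intervals from the
#' inverse information and flags non-convergence or (quasi-)complete
#' separation instead of failing silently.
#'
#' @param covariates numeric matrix or data.frame (patients in rows).
#' @param survival data.frame with `time` and `event`, same row order.
#' @return list with `coefficients` (data.frame term, coef, se, HR, lower,
#'   upper, p), `loglik`, `converged`, `separation`.
#' @export
fit_cox <- function(covariates, survival) {
  check_survival(survival)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == nrow(survival))
  if (nrow(X) <= ncol(X)) stop("need more patients than covariates")
  if (any(apply(X, 2, function(v) length(unique(v)) == 1)))
    stop("constant covariate")
  y <- surv_obj(survival)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(y ~ X, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  separation <- any(!is.finite(beta)) || any(abs(beta) > 15) || any(se > 100)
  z <- beta / se
  list(coefficients = data.frame(
         term = colnames(X),
         coef = unname(beta),
         se = unname(se),
         HR = unname(exp(beta)),
         lower = unname(exp(beta - 1.96 * se)),
         upper = unname(exp(beta + 1.96 * se)),
         p = unname(2 * stats::pnorm(-abs(z))),
         stringsAsFactors = FALSE),
       loglik = fit$loglik,
       converged = !warned,
       separation = separation)
}

#' Linear risk score from Cox coefficients
#'
#' `score_j = sum_i x_i * e_ij` where `e_ij` is the `log2(x + 1)`-transformed
#' expression of signature lncRNA `i` in patient `j` and `x_i` its Cox
#' coefficient.
#'
#' @param expression an [expression_set()] (tumor samples are used) or a
#'   genes-by-samples matrix of raw FPKM values.
#' @param coefficients named numeric vector of Cox coefficients; every name
#'   must be a row of the matrix.
#' @param transform apply `log2(x + 1)` to the matrix first (default TRUE;
#'   set FALSE if the matrix is already on the working scale).
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(expression, coefficients, transform = TRUE) {
  mat <- if (inherits(expression, "expr_set")) expr_tissue(expression, "tumor")
         else as.matrix(expression)
  if (is.null(names(coefficients)))
    stop("`coefficients` must be named by lncRNA id")
  missing <- setdiff(names(coefficients), rownames(mat))
  if (length(missing))
    stop("lncRNA(s) missing from the expression matrix: ",
         paste(missing, collapse = ", "))
  E <- mat[names(coefficients), , drop = FALSE]
  if (transform) E <- log2p1(E)
  colSums(coefficients * E)
}

align_expression <- function(expression, survival) {
  mat <- if (inherits(expression, "expr_set")) expr_tissue(expression, "tumor")
         else as.matrix(expression)
  if (!"sample" %in% names(survival))
    stop("survival table needs a `sample` column matching matrix columns")
  idx <- match(survival$sample, colnames(mat))
  if (anyNA(idx))
    stop("survival sample(s) missing from the expression matrix: ",
         paste(survival$sample[is.na(idx)], collapse = ", "))
  mat[, idx, drop = FALSE]
}

#' Screen lncRNAs for survival association
#'
#' For each candidate lncRNA: find its maximally selected expression
#' cutpoint ([maxstat_cutoff()] on `log2(x + 1)` values), split the
#' patients, and log-rank test the two groups. Candidates with raw log-rank
#' `p < p_cut` are selected; the Lausen-Schumacher corrected p is reported
#' alongside. Candidates whose cutpoint scan fails are skipped with a
#' message.
#'
#' @param candidates character vector of lncRNA ids.
#' @param expression an [expression_set()] or matrix (see [risk_score()]).
#' @param survival data.frame with `sample`, `time`, `event`.
#' @param p_cut selection threshold on the raw log-rank p.
#' @param quantile_range forwarded to [maxstat_cutoff()].
#' @return data.frame with `lncRNA`, `cutoff`, `statistic`, `p`,
#'   `p_corrected`, `selected`.
#' @export
screen_survival_lncRNAs <- function(candidates, expression, survival,
                                    p_cut = 0.05,
                                    quantile_range = c(0.1, 0.9)) {
  check_survival(survival)
  empty <- data.frame(lncRNA = character(0), cutoff = numeric(0),
                      statistic = numeric(0), p = numeric(0),
                      p_corrected = numeric(0), selected = logical(0))
  if (length(candidates) == 0) return(empty)
  mat <- align_expression(expression, survival)
  rows <- lapply(candidates, function(lnc) {
    if (!lnc %in% rownames(mat)) {
      message("candidate ", lnc, " not in the expression matrix; skipped")
      return(NULL)
    }
    vals <- log2p1(mat[lnc, ])
    ms <- tryCatch(maxstat_cutoff(vals, survival, quantile_range),
                   error = function(e) {
                     message("cutpoint scan failed for ", lnc, ": ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(ms)) return(NULL)
    data.frame(lncRNA = lnc, cutoff = ms$cutoff, statistic = ms$statistic,
               p = ms$p, p_corrected = ms$p_corrected,
               selected = ms$p < p_cut, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# Precomputed risk-set structure for the vectorized log-rank used inside
# the subset search (same O/E/V arithmetic as the log-rank above, O(n) per
# candidate split instead of one model frame per call).
logrank_prep <- function(survival) {
  ord <- order(survival$time)
  t_s <- survival$time[ord]
  e_s <- survival$event[ord]
  n <- length(t_s)
  first <- which(!duplicated(t_s))                  # first index per time
  last <- c(first[-1] - 1L, n)
  ce <- cumsum(e_s)
  d_tot <- diff(c(0, ce[last]))                    # events per distinct time
  atrisk <- n - first + 1L                         # total at risk
  keep <- d_tot > 0                                # only event times matter
  list(ord = ord, e_s = e_s, first = first, last = last,
       d_tot = d_tot, atrisk = atrisk, keep = keep, n = n)
}

# chi-square statistic of the two-group log-rank for a logical split
# (TRUE = high group), given a logrank_prep() structure.
fast_logrank <- function(hi, prep) {
  h_s <- hi[prep$ord]
  n1_at <- rev(cumsum(rev(h_s)))[prep$first]       # high-group at risk
  ce1 <- cumsum(prep$e_s * h_s)
  d1_all <- diff(c(0, ce1[prep$last]))             # high-group events
  k <- prep$keep
  n_at <- prep$atrisk[k]
  n1 <- n1_at[k]
  d <- prep$d_tot[k]
  d1 <- d1_all[k]
  e1 <- d * n1 / n_at
  v <- ifelse(n_at > 1,
              d * (n1 / n_at) * (1 - n1 / n_at) * (n_at - d) / (n_at - 1),
              0)
  vs <- sum(v)
  if (vs <= 0) return(NA_real_)
  (sum(d1 - e1))^2 / vs
}

#' Exhaustive prognostic-signature subset search
#'
#' Evaluates every non-empty subset of the candidate lncRNAs
#' (`2^k - 1` models): a joint Cox fit on the subset's `log2(x + 1)`
#' expressions gives the coefficients, patients are scored with
#' [risk_score()], dichotomized at the median score (or a per-model
#' maximally selected cutpoint with `split = "maxstat"`), and the two groups
#' are log-rank tested. The signature with the minimum log-rank p wins; ties
#' go to the smaller subset, then lexicographic order. Subsets whose Cox fit
#' or split fails are recorded as failed and the search continues.
#'
#' @param candidates character vector of 1 to 20 lncRNA ids.
#' @param expression an [expression_set()] or matrix.
#' @param survival data.frame with `sample`, `time`, `event`.
#' @param split `"median"` (default) or `"maxstat"`.
#' @param fit_fun optional replacement for the per-subset Cox fit: a
#'   function `(x_matrix, survival)` returning named coefficients (rows of
#'   `x_matrix` are the subset lncRNAs on the log2 scale). Used to stub the
#'   fit in counting checks.
#' @return list with `best` (a `signature_model`: lncRNAs, coefficients,
#'   scores, cutoff, groups, log-rank statistic and p, group sizes), and
#'   `models`, a data.frame holding every evaluated subset (`mask`,
#'   `lncRNAs`, `k`, `logrank_p`, `failed`).
#' @export
exhaustive_signature_search <- function(candidates, expression, survival,
                                        split = c("median", "maxstat"),
                                        fit_fun = NULL) {
  split <- match.arg(split)
  check_survival(survival)
  k <- length(candidates)
  if (k < 1 || k > 20) stop("need 1 to 20 candidate lncRNAs")
  mat <- align_expression(expression, survival)
  missing <- setdiff(candidates, rownames(mat))
  if (length(missing))
    stop("candidate(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  E <- log2p1(mat[candidates, , drop = FALSE])
  y <- surv_obj(survival)
  if (is.null(fit_fun))
    fit_fun <- function(x, survival) {
      f <- survival::coxph(y ~ t(x), ties = "efron",
                           control = survival::coxph.control(iter.max = 50))
      stats::setNames(stats::coef(f), rownames(x))
    }
  prep <- logrank_prep(survival)
  n_models <- 2^k - 1
  bits <- 2^(seq_len(k) - 1)
  mask_v <- integer(n_models)
  lnc_v <- character(n_models)
  k_v <- integer(n_models)
  p_v <- rep(NA_real_, n_models)
  fail_v <- logical(n_models)
  best <- list(p = Inf, idx = NULL, subset_key = "")
  for (mask in seq_len(n_models)) {
    idx <- which(bitwAnd(mask, bits) != 0)
    mask_v[mask] <- mask
    k_v[mask] <- length(idx)
    lnc_v[mask] <- paste(candidates[idx], collapse = ";")
    res <- tryCatch({
      cf <- fit_fun(E[idx, , drop = FALSE], survival)
      if (anyNA(cf)) stop("NA coefficient")
      sc <- colSums(cf * E[idx, , drop = FALSE])
      hi <- if (split == "median") sc > stats::median(sc)
            else sc > maxstat_cutoff(sc, survival)$cutoff
      if (!any(hi) || all(hi)) stop("degenerate split")
      stats::pchisq(fast_logrank(hi, prep), df = 1, lower.tail = FALSE)
    }, error = function(e) NA_real_)
    if (is.na(res)) {
      fail_v[mask] <- TRUE
    } else {
      p_v[mask] <- res
      key <- lnc_v[mask]
      if (res < best$p ||
          (res == best$p && (length(idx) < length(best$idx) ||
            (length(idx) == length(best$idx) && key < best$subset_key)))) {
        best <- list(p = res, idx = idx, subset_key = key)
      }
    }
  }
  models <- data.frame(mask = mask_v, lncRNAs = lnc_v, k = k_v,
                       logrank_p = p_v, failed = fail_v,
                       stringsAsFactors = FALSE)
  best_model <- NULL
  if (!is.null(best$idx)) {
    sig <- candidates[best$idx]
    cf <- fit_fun(E[best$idx, , drop = FALSE], survival)
    sc <- colSums(cf * E[best$idx, , drop = FALSE])
    cutoff <- if (split == "median") stats::median(sc)
              else maxstat_cutoff(sc, survival)$cutoff
    hi <- sc > cutoff
    lt <- logrank_test(hi, survival)
    km_hi <- km_estimate(survival[hi, , drop = FALSE])
    km_lo <- km_estimate(survival[!hi, , drop = FALSE])
    best_model <- structure(list(
      lncRNAs = sig,
      coefficients = stats::setNames(as.numeric(cf), sig),
      scores = stats::setNames(sc, survival$sample),
      cutoff = cutoff,
      split = split,
      groups = stats::setNames(ifelse(hi, "high", "low"), survival$sample),
      group_sizes = c(high = sum(hi), low = sum(!hi)),
      logrank_statistic = lt$statistic,
      logrank_p = lt$p,
      median_survival = c(high = km_hi$median, low = km_lo$median)),
      class = "signature_model")
  }
  list(best = best_model, models = models)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d lncRNAs (%s), log-rank p = %.3g\n",
              length(x$lncRNAs), paste(x$lncRNAs, collapse = ", "),
              x$logrank_p))
  cat(sprintf("  groups: %d high / %d low at %s cutoff %.4g; median survival %s vs %s\n",
              x$group_sizes["high"], x$group_sizes["low"], x$split, x$cutoff,
              format(x$median_survival["high"], digits = 4),
              format(x$median_survival["low"], digits = 4)))
  invisible(x)
}

km_eval <- function(times, surv, t, strict = FALSE) {
  i <- if (strict) sum(times < t) else sum(times <= t)
  if (i == 0) 1 else surv[i]
}

#' Time-dependent ROC AUC with censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each horizon: cases experienced
#' an event by the horizon, controls are still event-free beyond it, and
#' censoring is handled by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution (cases weighted by
#' `1 / G(T-)`). With no censoring this reduces exactly to the plain rank
#' AUC of cases vs controls. A horizon with no cases, no controls, or zero
#' censoring-survival is returned as `NA`.
#'
#' @param scores numeric risk scores, one per patient.
#' @param survival data.frame with `time` and `event`, same order.
#' @param horizons evaluation times (same units as `time`).
#' @return data.frame with `horizon`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(scores, survival, horizons = c(1, 3, 5, 10)) {
  check_survival(survival)
  stopifnot(length(scores) == nrow(survival))
  cs <- survival::survfit(survival::Surv(survival$time,
                                         1 - survival$event) ~ 1)
  out <- lapply(horizons, function(tau) {
    case <- survival$time <= tau & survival$event == 1
    ctrl <- survival$time > tau
    g_tau <- km_eval(cs$time, cs$surv, tau)
    if (!any(case) || !any(ctrl) || g_tau <= 0)
      return(data.frame(horizon = tau, auc = NA_real_,
                        n_cases = sum(case), n_controls = sum(ctrl)))
    w_case <- vapply(survival$time[case],
                     function(ti) 1 / km_eval(cs$time, cs$surv, ti,
                                              strict = TRUE),
                     numeric(1))
    s_case <- scores[case]
    s_ctrl <- scores[ctrl]
    cmp <- outer(s_case, s_ctrl, ">") + 0.5 * outer(s_case, s_ctrl, "==")
    auc <- sum(w_case * rowSums(cmp)) / (sum(w_case) * length(s_ctrl))
    data.frame(horizon = tau, auc = auc,
               n_cases = sum(case), n_controls = sum(ctrl))
  })
  do.call(rbind, out)
}

#' Prognostic independence of the signature
#'
#' Univariate Cox fits for the signature risk group and each clinical
#' covariate, plus one joint multivariable fit, with the usual clinical
#' codings: age above vs at/below `age_cut`, stage III/IV vs I/II, high vs
#' low risk. With a single covariate the multivariable fit reduces exactly
#' to the univariate one.
#'
#' @param risk_group character/factor `"high"`/`"low"`, one per patient.
#' @param survival data.frame with `time` and `event`, same order.
#' @param age optional numeric ages.
#' @param stage optional stages in `I`/`II`/`III`/`IV`.
#' @param age_cut age dichotomization threshold (years).
#' @return data.frame with one row per variable and columns for univariate
#'   and multivariable HR, 95% CI and Wald p.
#' @export
independence_analysis <- function(risk_group, survival, age = NULL,
                                  stage = NULL, age_cut = 58) {
  check_survival(survival)
  covs <- list(signature = as.numeric(risk_group == "high"))
  if (!is.null(age)) covs$age <- as.numeric(age > age_cut)
  if (!is.null(stage)) {
    stopifnot(all(stage %in% c("I", "II", "III", "IV")))
    covs$stage <- as.numeric(stage %in% c("III", "IV"))
  }
  X <- do.call(cbind, covs)
  uni <- lapply(seq_len(ncol(X)), function(j)
    fit_cox(X[, j, drop = FALSE], survival)$coefficients)
  multi <- fit_cox(X, survival)$coefficients
  data.frame(variable = colnames(X),
             coding = c(signature = "high vs low",
                        age = sprintf(">%g vs <=%g", age_cut, age_cut),
                        stage = "III,IV vs I,II")[colnames(X)],
             HR_uni = vapply(uni, function(u) u$HR, numeric(1)),
             lower_uni = vapply(uni, function(u) u$lower, numeric(1)),
             upper_uni = vapply(uni, function(u) u$upper, numeric(1)),
             p_uni = vapply(uni, function(u) u$p, numeric(1)),
             HR_multi = multi$HR,
             lower_multi = multi$lower,
             upper_multi = multi$upper,
             p_multi = multi$p,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
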