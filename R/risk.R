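# Genotype-score construction, logistic association models, nested-model
# comparison and cross-validated discrimination.

pheno01 <- function(phenotype) {
  y <- ifelse(phenotype == "case", 1L, ifelse(phenotype == "control", 0L, NA_integer_))
  if (anyNA(y)) {
    # samples with unknown phenotype take no part in modelling
    y
  } else y
}

#' Assign per-SNP risk alleles from case/control allele frequencies
#'
#' The risk allele of a SNP is the allele with higher frequency in cases than
#' in controls. Monomorphic SNPs are excluded with a warning; exact frequency
#' ties are flagged unresolved and excluded from scoring with a message.
#'
#' @param gm A [genotype_matrix()] with case/control phenotypes.
#' @return `data.frame` with columns `id`, `risk_allele` (`"ref"` or `"alt"`),
#'   `control_risk_freq` (risk-allele frequency in controls, used by the
#'   missing-genotype imputation), and `status`
#'   (`"ok"`, `"monomorphic"`, `"tie"`). Only `"ok"` rows enter scores.
#' @export
assign_risk_alleles <- function(gm) {
  y <- pheno01(gm$phenotype)
  if (!any(y %in% 1L) || !any(y %in% 0L))
    stop_("both cases and controls are required")
  case <- which(y == 1L); ctrl <- which(y == 0L)
  out <- lapply(seq_len(ncol(gm$codes)), function(j) {
    g <- gm$codes[, j]
    fa_all <- mean(g, na.rm = TRUE) / 2
    if (is.nan(fa_all) || fa_all %in% c(0, 1))
      return(data.frame(id = gm$variants$id[j], risk_allele = NA_character_,
                        control_risk_freq = NA_real_, status = "monomorphic",
                        stringsAsFactors = FALSE))
    fa_case <- mean(g[case], na.rm = TRUE) / 2
    fa_ctrl <- mean(g[ctrl], na.rm = TRUE) / 2
    if (isTRUE(all.equal(fa_case, fa_ctrl)))
      return(data.frame(id = gm$variants$id[j], risk_allele = NA_character_,
                        control_risk_freq = NA_real_, status = "tie",
                        stringsAsFactors = FALSE))
    risk <- if (fa_case > fa_ctrl) "alt" else "ref"
    crf <- if (risk == "alt") fa_ctrl else 1 - fa_ctrl
    data.frame(id = gm$variants$id[j], risk_allele = risk,
               control_risk_freq = crf, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$status == "monomorphic"))
    warn_("excluded %d monomorphic SNP(s)", sum(out$status == "monomorphic"))
  if (any(out$status == "tie"))
    message(sprintf("excluded %d SNP(s) with tied case/control frequencies",
                    sum(out$status == "tie")))
  out
}

#' Unweighted genotype score
#'
#' Per-sample sum of risk-allele counts over the scored SNP set. Missing
#' genotypes are imputed as twice the control risk-allele frequency (mean
#' imputation, keeping scores comparable across samples); `missing_policy =
#' "drop_rescale"` instead averages over observed SNPs and rescales to the
#' full SNP count. Samples missing every scored genotype are dropped with a
#' warning.
#'
#' @param gm A [genotype_matrix()].
#' @param risk_map [assign_risk_alleles()] output (or a compatible
#'   `data.frame`); only `status == "ok"` rows are used.
#' @param missing_policy `"impute"` (default) or `"drop_rescale"`.
#' @return Object of class `genotype_score`: named numeric vector of scores
#'   with attributes `snps` (ids used) and `risk_map`.
#' @export
genotype_score <- function(gm, risk_map, missing_policy = c("impute", "drop_rescale")) {
  missing_policy <- match.arg(missing_policy)
  rm_ok <- risk_map[risk_map$status == "ok", , drop = FALSE]
  absent <- setdiff(rm_ok$id, gm$variants$id)
  if (length(absent)) stop_("risk_map SNP(s) absent from genotypes: %s",
                            paste(absent, collapse = ", "))
  if (nrow(rm_ok) == 0) stop_("no scorable SNPs in risk_map")
  j <- match(rm_ok$id, gm$variants$id)
  g <- gm$codes[, j, drop = FALSE]
  # risk-allele count: alt-risk = code, ref-risk = 2 - code
  flip <- rm_ok$risk_allele == "ref"
  g[, flip] <- 2 - g[, flip, drop = FALSE]
  all_missing <- rowSums(!is.na(g)) == 0
  if (any(all_missing)) {
    warn_("dropped %d sample(s) with all scored genotypes missing", sum(all_missing))
    g <- g[!all_missing, , drop = FALSE]
  }
  if (missing_policy == "impute") {
    imput <- 2 * rm_ok$control_risk_freq
    for (k in which(colSums(is.na(g)) > 0)) g[is.na(g[, k]), k] <- imput[k]
    score <- rowSums(g)
  } else {
    score <- rowMeans(g, na.rm = TRUE) * nrow(rm_ok)
  }
  structure(score, snps = rm_ok$id, risk_map = rm_ok, class = "genotype_score")
}

#' @export
print.genotype_score <- function(x, ...) {
  cat(sprintf("genotype_score over %d SNP(s), %d samples; range [%.2f, %.2f]\n",
              length(attr(x, "snps")), length(x), min(x), max(x)))
  invisible(x)
}

#' Fit a logistic regression association model
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()] with convergence
#' tolerance 1e-10) of a case indicator on the supplied predictors, reporting
#' per-term odds ratios with Wald 95% confidence intervals and p-values.
#' Apparent separation (non-convergence or runaway coefficients) is an error
#' naming the offending predictor.
#'
#' @param design `data.frame` or matrix of per-sample predictors.
#' @param y Binary case indicator (0/1) or the phenotype labels of a
#'   [genotype_matrix()].
#' @return Object of class `logistic_fit`: `$coefficients` table (estimate,
#'   se, or, or_lo, or_hi, z, p), `$loglik`, `$n`, `$glm` (the underlying
#'   fit).
#' @export
fit_logistic <- function(design, y) {
  design <- as.data.frame(design)
  if (is.character(y) || is.factor(y)) y <- pheno01(as.character(y))
  keep <- !is.na(y) & stats::complete.cases(design)
  design <- design[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) <= ncol(design)) stop_("need more samples than predictors")
  const <- vapply(design, function(z) length(unique(z)) < 2, logical(1))
  if (any(const)) stop_("constant predictor(s): %s",
                        paste(names(design)[const], collapse = ", "))
  dat <- cbind(.y = y, design)
  fit <- glm(.y ~ ., data = dat, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  co <- summary(fit)$coefficients
  big <- abs(co[-1, "Estimate"]) > 15
  if (!fit$converged || any(big)) {
    off <- if (any(big)) rownames(co)[-1][big][1] else "(unknown)"
    stop_("logistic fit failed to converge (possible separation); offending predictor: %s", off)
  }
  z <- qnorm(0.975)
  tab <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                    se = co[, "Std. Error"],
                    or = exp(co[, "Estimate"]),
                    or_lo = exp(co[, "Estimate"] - z * co[, "Std. Error"]),
                    or_hi = exp(co[, "Estimate"] + z * co[, "Std. Error"]),
                    z = co[, "z value"], p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, loglik = as.numeric(logLik(fit)),
                 n = length(y), glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic_fit: n = %d, logLik = %.3f\n", x$n, x$loglik))
  tab <- x$coefficients
  tab[, -1] <- signif(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.logistic_fit <- function(object, ...) object$coefficients

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$glm)
  else predict(object$glm, newdata = as.data.frame(newdata), type = "response")
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param nested,full [fit_logistic()] results on the same samples, the
#'   nested model's predictors a subset of the full model's.
#' @return List with `statistic` (`2 * (ll_full - ll_nested)`), `df`
#'   (predictor-count difference) and `p` (chi-square upper tail).
#' @export
lr_test <- function(nested, full) {
  if (nested$n != full$n) stop_("models fitted on different sample counts")
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-8)
    stop_("full model log-likelihood below nested model's: fitting inconsistency")
  stat <- max(stat, 0)
  df <- nrow(full$coefficients) - nrow(nested$coefficients)
  if (df < 0) stop_("'full' has fewer predictors than 'nested'")
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Tie-corrected Mann-Whitney AUC
#'
#' Probability that a random case outranks a random control, with ties counted
#' half; equals the rank-statistic form of the ROC area.
#'
#' @param scores Numeric predictions.
#' @param y Binary case indicator (0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_("both classes required for AUC")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated discrimination of a logistic classifier
#'
#' Stratified k-fold cross-validation: a logistic model is fitted on each
#' training split and out-of-fold predicted probabilities are pooled; the
#' reported AUC is the tie-corrected Mann-Whitney statistic over the pooled
#' probabilities ("through the overall results", not per-fold averaging).
#'
#' @param features `data.frame`, matrix or single numeric vector of
#'   predictors.
#' @param y Binary case indicator (0/1) or phenotype labels.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed (mandatory for reproducibility).
#' @return Object of class `discrimination_result`: `$auc`, `$probs` (pooled
#'   out-of-fold probabilities), `$folds`, `$y`, `$seed`.
#' @export
cv_auc <- function(features, y, k = 10, seed) {
  if (missing(seed)) stop_("a fold-assignment seed is required")
  if (is.null(dim(features))) features <- data.frame(score = features)
  features <- as.data.frame(features)
  if (is.character(y) || is.factor(y)) y <- pheno01(as.character(y))
  keep <- !is.na(y) & stats::complete.cases(features)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  folds <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  probs <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(unique(y[test])) < 2 || length(unique(y[!test])) < 2)
      stop_("fold %d contains a single class: stratification failure", f)
    dat <- cbind(.y = y, features)
    fit <- glm(.y ~ ., data = dat[!test, , drop = FALSE], family = binomial(),
               control = list(epsilon = 1e-10, maxit = 100))
    probs[test] <- predict(fit, newdata = dat[test, , drop = FALSE],
                           type = "response")
  }
  structure(list(auc = auc_mann_whitney(probs, y), probs = probs, folds = folds,
                 y = y, seed = seed),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("discrimination_result: pooled %d-fold CV AUC = %.4f (seed %d)\n",
              max(x$folds), x$auc, x$seed))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Welch two-sample t-test of genotype-score separation
#'
#' Tests whether cases carry systematically more risk alleles than controls.
#'
#' @param scores Numeric genotype scores.
#' @param y Binary case indicator (0/1) or phenotype labels.
#' @return List with `statistic` (t) and `p`.
#' @export
score_separation_test <- function(scores, y) {
  if (is.character(y) || is.factor(y)) y <- pheno01(as.character(y))
  keep <- !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  a <- scores[y == 1]; b <- scores[y == 0]
  if (!length(a) || !length(b)) stop_("both groups must be non-empty")
  if (sd(a) == 0 && sd(b) == 0)
    stop_("zero variance in both groups: t statistic undefined")
  tt <- t.test(a, b)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}
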