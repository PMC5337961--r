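# Net reclassification improvement (categorical and continuous) and
# integrated discrimination improvement, with asymptotic inference.
#
# All internal arithmetic is in proportions; percent rendering (x100, two
# decimals) happens only at report time. Two renderings of the component
# report exist in the wild — half-up rounding and two-decimal truncation — and
# both are carried in the result's $report.

category_of <- function(p, cutoffs) {
  # left-closed right-open bins [0, c1), [c1, c2), ..., [ck, 1]
  findInterval(p, c(0, cutoffs), rightmost.closed = FALSE) # p = c1 -> bin 2
}

category_labels <- function(cutoffs) {
  pct <- function(x) sprintf("%g%%", 100 * x)
  k <- length(cutoffs)
  c(sprintf("<%s", pct(cutoffs[1])),
    if (k > 1) sprintf("%s to <%s", pct(cutoffs[-k]), pct(cutoffs[-1])),
    sprintf(">=%s", pct(cutoffs[k])))
}

#' Construct a reclassification count table
#'
#' @param counts Square matrix, rows = old risk category, columns = new risk
#'   category.
#' @param group `"cases"` or `"controls"`.
#' @param labels Optional category labels.
#' @return Object of class `reclass_table`.
#' @export
reclass_table <- function(counts, group = c("cases", "controls"), labels = NULL) {
  group <- match.arg(group)
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop_("reclassification matrix must be square")
  if (any(counts < 0)) stop_("negative reclassification counts")
  if (!is.null(labels)) dimnames(counts) <- list(old = labels, new = labels)
  structure(list(counts = counts, group = group, n = sum(counts)),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("reclass_table (%s, n = %d):\n", x$group, x$n))
  print(x$counts)
  invisible(x)
}

#' Read a printed reclassification count matrix
#'
#' Reads a square headerless CSV of old-by-new category counts, as printed in
#' published reclassification tables, into a [reclass_table()].
#'
#' @param path CSV file, one row per old category.
#' @param group `"cases"` or `"controls"`.
#' @param cutoffs Cutpoints used only to label categories (default
#'   `c(0.2, 0.4, 0.6)`).
#' @return A [reclass_table()].
#' @export
read_reclass_counts <- function(path, group, cutoffs = c(0.2, 0.4, 0.6)) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  reclass_table(m, group, labels = category_labels(cutoffs))
}

#' Cross-tabulate predicted risks before and after adding biomarkers
#'
#' Bins predicted probabilities into left-closed right-open risk categories
#' (`[0, c1), [c1, c2), ..., [ck, 1]`; a probability equal to a cutoff falls
#' in the upper category) and cross-tabulates old versus new category
#' separately for cases and controls.
#'
#' @param p_old,p_new Per-sample predicted probabilities in `[0, 1]` under the
#'   old and new model.
#' @param y Binary case indicator (0/1) or phenotype labels.
#' @param cutoffs Strictly increasing interior cutpoints (default
#'   `c(0.2, 0.4, 0.6)`).
#' @return List with elements `cases` and `controls`, each a
#'   [reclass_table()].
#' @export
build_reclass_tables <- function(p_old, p_new, y, cutoffs = c(0.2, 0.4, 0.6)) {
  if (is.character(y) || is.factor(y)) y <- pheno01(as.character(y))
  if (length(p_old) != length(p_new) || length(p_old) != length(y))
    stop_("p_old, p_new and y must have equal length")
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1, na.rm = TRUE))
    stop_("probabilities must lie in [0, 1]")
  if (is.unsorted(cutoffs, strictly = TRUE)) stop_("cutoffs must be strictly increasing")
  keep <- !is.na(y)
  p_old <- p_old[keep]; p_new <- p_new[keep]; y <- y[keep]
  k <- length(cutoffs) + 1
  labs <- category_labels(cutoffs)
  co <- category_of(p_old, cutoffs)
  cn <- category_of(p_new, cutoffs)
  tab <- function(sel) {
    m <- table(factor(co[sel], levels = seq_len(k)),
               factor(cn[sel], levels = seq_len(k)))
    matrix(as.integer(m), k, k)
  }
  list(cases = reclass_table(tab(y == 1), "cases", labs),
       controls = reclass_table(tab(y == 0), "controls", labs))
}

# component NRI machinery shared by the categorical and continuous paths:
# per-group up/down counts -> components, asymptotic SEs, CI, Z p-value
nri_from_updown <- function(up_case, down_case, n_case,
                            up_ctrl, down_ctrl, n_ctrl, kind) {
  if (n_case == 0 || n_ctrl == 0) stop_("zero-size group: NRI undefined")
  pu1 <- up_case / n_case; pd1 <- down_case / n_case
  pu0 <- up_ctrl / n_ctrl; pd0 <- down_ctrl / n_ctrl
  event <- pu1 - pd1
  nonevent <- pd0 - pu0
  total <- event + nonevent
  var_case <- ((pu1 + pd1) - (pu1 - pd1)^2) / n_case
  var_ctrl <- ((pu0 + pd0) - (pd0 - pu0)^2) / n_ctrl
  se_event <- sqrt(var_case); se_nonevent <- sqrt(var_ctrl)
  se <- sqrt(var_case + var_ctrl)
  zq <- qnorm(0.975)
  zstat <- if (se > 0) total / se else NA_real_
  res <- list(
    kind = kind,
    event = event, nonevent = nonevent, total = total,
    se_event = se_event, se_nonevent = se_nonevent, se = se,
    ci_event = event + c(-1, 1) * zq * se_event,
    ci_nonevent = nonevent + c(-1, 1) * zq * se_nonevent,
    ci = total + c(-1, 1) * zq * se,
    z = zstat,
    p = if (is.na(zstat)) NA_real_ else 2 * pnorm(-abs(zstat)),
    up = c(cases = up_case, controls = up_ctrl),
    down = c(cases = down_case, controls = down_ctrl),
    n = c(cases = n_case, controls = n_ctrl))
  res$report <- nri_report(res)
  class(res) <- "reclassification_result"
  res
}

pct_round <- function(x, digits = 2) round(100 * x, digits)
pct_trunc <- function(x, digits = 2) trunc(100 * x * 10^digits) / 10^digits

# both percent renderings: half-up rounded components and their sum, plus the
# table-style two-decimal truncated components and their difference
nri_report <- function(res) {
  list(
    rounded = c(event = pct_round(res$event), nonevent = pct_round(res$nonevent),
                total = pct_round(res$total)),
    rounded_component_sum = pct_round(res$event) + pct_round(res$nonevent),
    truncated = c(event = pct_trunc(res$event), nonevent = pct_trunc(res$nonevent)),
    truncated_component_sum = pct_trunc(res$event) + pct_trunc(res$nonevent),
    ci = pct_round(res$ci))
}

#' @export
print.reclassification_result <- function(x, ...) {
  if (x$kind == "idi") {
    cat(sprintf("IDI = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], P = %.3g\n",
                x$idi, x$se, x$ci[1], x$ci[2], x$p))
    return(invisible(x))
  }
  cat(sprintf("%s NRI = %.2f%% (95%% CI %.2f%% to %.2f%%), P = %.3g\n",
              x$kind, 100 * x$total, 100 * x$ci[1], 100 * x$ci[2], x$p))
  cat(sprintf("  events:     up %d / down %d of %d -> %+.2f%%\n",
              x$up[["cases"]], x$down[["cases"]], x$n[["cases"]], 100 * x$event))
  cat(sprintf("  non-events: up %d / down %d of %d -> %+.2f%%\n",
              x$up[["controls"]], x$down[["controls"]], x$n[["controls"]],
              100 * x$nonevent))
  invisible(x)
}

#' Categorical net reclassification improvement
#'
#' Event NRI = (up - down) / n among cases, non-event NRI = (down - up) / n
#' among controls, total = sum. The asymptotic SE is
#' `sqrt(sum_g [ (p_up,g + p_down,g) - (p_up,g - p_down,g)^2 ] / n_g)` with the
#' per-group net movement inside the square; the 95% CI is `total +/- 1.96 SE`
#' and the p-value is two-sided normal on `Z = total / SE`.
#'
#' @param cases,controls [reclass_table()] objects sharing category structure.
#' @return Object of class `reclassification_result` with components, SEs,
#'   CIs, Z p-value, up/down counts, and a `$report` carrying the percent
#'   renderings.
#' @export
nri_categorical <- function(cases, controls) {
  if (!inherits(cases, "reclass_table") || !inherits(controls, "reclass_table"))
    stop_("inputs must be reclass_table objects")
  if (!identical(dim(cases$counts), dim(controls$counts)))
    stop_("tables differ in category structure")
  up <- function(m) sum(m[upper.tri(m)])
  down <- function(m) sum(m[lower.tri(m)])
  nri_from_updown(up(cases$counts), down(cases$counts), cases$n,
                  up(controls$counts), down(controls$counts), controls$n,
                  kind = "categorical")
}

#' Continuous (category-free) net reclassification improvement
#'
#' Any probability increase counts as upward movement, any decrease as
#' downward (exact ties neither); components and inference follow the
#' categorical formulas with these up/down proportions.
#'
#' @param p_old,p_new Paired per-sample probabilities.
#' @param y Binary case indicator (0/1) or phenotype labels.
#' @return A `reclassification_result` (see [nri_categorical()]).
#' @export
nri_continuous <- function(p_old, p_new, y) {
  if (is.character(y) || is.factor(y)) y <- pheno01(as.character(y))
  keep <- !is.na(y)
  p_old <- p_old[keep]; p_new <- p_new[keep]; y <- y[keep]
  d <- p_new - p_old
  nri_from_updown(sum(d > 0 & y == 1), sum(d < 0 & y == 1), sum(y == 1),
                  sum(d > 0 & y == 0), sum(d < 0 & y == 0), sum(y == 0),
                  kind = "continuous")
}

#' Integrated discrimination improvement
#'
#' `IDI = mean(delta p | cases) - mean(delta p | controls)` with
#' `delta p = p_new - p_old`; `SE = sqrt(se_cases^2 + se_controls^2)` where
#' `se_g = sd(delta p in g) / sqrt(n_g)`.
#'
#' @param p_old,p_new Paired per-sample probabilities.
#' @param y Binary case indicator (0/1) or phenotype labels.
#' @return A `reclassification_result` with `$idi`, `$se`, `$ci`, `$p`.
#' @export
idi <- function(p_old, p_new, y) {
  if (is.character(y) || is.factor(y)) y <- pheno01(as.character(y))
  keep <- !is.na(y)
  p_old <- p_old[keep]; p_new <- p_new[keep]; y <- y[keep]
  d <- p_new - p_old
  d1 <- d[y == 1]; d0 <- d[y == 0]
  if (!length(d1) || !length(d0)) stop_("zero-size group: IDI undefined")
  est <- mean(d1) - mean(d0)
  se <- sqrt(sd(d1)^2 / length(d1) + sd(d0)^2 / length(d0))
  zq <- qnorm(0.975)
  zstat <- if (se > 0) est / se else NA_real_
  structure(list(kind = "idi", idi = est, se = se,
                 ci = est + c(-1, 1) * zq * se, z = zstat,
                 p = if (is.na(zstat)) NA_real_ else 2 * pnorm(-abs(zstat)),
                 n = c(cases = length(d1), controls = length(d0))),
            class = "reclassification_result")
}
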