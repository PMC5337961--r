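# Scaled PWM scoring and allele-disruption calls.
#
# Scoring scheme: the raw match score of a width-w sequence is the sum over
# positions of the base probability, S = sum_i probs[seq_i, i]; it is min-max
# scaled per matrix to [0, 1] using the attainable bounds s_min (column minima)
# and s_max (column maxima). A scaled score of 1 is a consensus match. The
# "matched" call compares the better allele's best scaled score against a
# match threshold (default 0.85).

check_seq <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(b %in% BASES))
    stop_("sequence contains non-ACGT base(s): %s; supply resolved context",
          paste(unique(setdiff(b, BASES)), collapse = ","))
  b
}

#' Scaled PWM match score of a sequence
#'
#' @param pwm A [pwm()].
#' @param seq Base string of exactly the motif width, ACGT only.
#' @return Scaled score in `[0, 1]`: `(S - s_min) / (s_max - s_min)` with
#'   `S = sum_i probs[seq_i, i]`.
#' @export
scaled_pwm_score <- function(pwm, seq) {
  b <- check_seq(seq)
  w <- pwm_width(pwm)
  if (length(b) != w) stop_("sequence length %d != motif width %d", length(b), w)
  s <- sum(pwm$probs[cbind(match(b, BASES), seq_len(w))])
  (s - pwm$s_min) / (pwm$s_max - pwm$s_min)
}

# reverse complement of a PWM (reverse columns, complement rows)
pwm_revcomp <- function(p) {
  pwm(paste0(p$name, "_rc"), p$probs[4:1, rev(seq_len(pwm_width(p))), drop = FALSE],
      target_genes = p$target_genes)
}

#' Score allele-specific disruption of a motif at a SNP
#'
#' Scans every motif-width window covering the SNP, on both strands (minus
#' strand = reverse complement of the window), scoring the window with the
#' reference and with the alternate allele substituted at the SNP. The best
#' placement maximizes `max(score_ref, score_alt)`; ties break toward the
#' smaller offset, then the plus strand. The pair is "matched" when that
#' maximum reaches `match_thresh`, and "strong" when additionally
#' `|score_ref - score_alt| >= effect_thresh`.
#'
#' The SNP must sit at `snp_pos` of `context` and carry the `ref` base there
#' (validated). A context with `>= w - 1` bases on each side of the SNP (total
#' `>= 2w - 1`) exposes all `w` placements; shorter flanks restrict the scan to
#' the windows that fit, and a context with no complete window covering the
#' SNP is an error.
#'
#' @param pwm A [pwm()].
#' @param context Reference sequence containing the SNP.
#' @param snp_pos 1-based index of the SNP within `context`.
#' @param ref,alt SNP alleles (single base).
#' @param match_thresh Scaled-score match threshold (default 0.85).
#' @param effect_thresh `|allele_diff|` cutoff behind the strong/weak label
#'   (default 0.4; a package default, configurable).
#' @return One-row `data.frame`: `motif`, `strand`, `offset` (SNP index within
#'   the best window, 0-based), `score_ref`, `score_alt`, `allele_diff`
#'   (`score_ref - score_alt`), `matched`, `effect`.
#' @export
score_allele_disruption <- function(pwm, context, snp_pos, ref, alt,
                                    match_thresh = 0.85, effect_thresh = 0.4) {
  b <- check_seq(context)
  w <- pwm_width(pwm)
  L <- length(b)
  if (snp_pos < 1 || snp_pos > L) stop_("snp_pos %d outside context (length %d)", snp_pos, L)
  if (!is_snp_allele(ref) || !is_snp_allele(alt) || ref == alt)
    stop_("ref/alt must be distinct single ACGT bases")
  if (b[snp_pos] != ref)
    stop_("context has '%s' at snp_pos %d, expected ref '%s'", b[snp_pos], snp_pos, ref)
  starts <- (snp_pos - w + 1):snp_pos
  starts <- starts[starts >= 1 & starts + w - 1 <= L]
  if (!length(starts))
    stop_("context too short: need >= %d bases covering the SNP (ideally %d, i.e. %d per flank)",
          w, 2 * w - 1, w - 1)

  best <- NULL
  # descending starts = ascending SNP offsets, so ties keep the smaller offset
  for (st in rev(starts)) {
    k <- snp_pos - st                      # 0-based SNP offset within window
    win_ref <- b[st:(st + w - 1)]
    win_alt <- win_ref
    win_alt[k + 1] <- alt
    for (strand in c("+", "-")) {
      if (strand == "+") {
        sr <- sum(pwm$probs[cbind(match(win_ref, BASES), seq_len(w))])
        sa <- sum(pwm$probs[cbind(match(win_alt, BASES), seq_len(w))])
      } else {
        rr <- match(chartr("ACGT", "TGCA", rev(win_ref)), BASES)
        ra <- match(chartr("ACGT", "TGCA", rev(win_alt)), BASES)
        sr <- sum(pwm$probs[cbind(rr, seq_len(w))])
        sa <- sum(pwm$probs[cbind(ra, seq_len(w))])
      }
      sr <- (sr - pwm$s_min) / (pwm$s_max - pwm$s_min)
      sa <- (sa - pwm$s_min) / (pwm$s_max - pwm$s_min)
      cand <- list(offset = k, strand = strand, score_ref = sr, score_alt = sa,
                   top = max(sr, sa))
      if (is.null(best) || cand$top > best$top + 1e-12) best <- cand
      # ties: smaller offset first, then plus strand — scan order guarantees it
    }
  }
  matched <- best$top >= match_thresh
  diff <- best$score_ref - best$score_alt
  data.frame(motif = pwm$name, strand = best$strand, offset = best$offset,
             score_ref = best$score_ref, score_alt = best$score_alt,
             allele_diff = diff, matched = matched,
             effect = if (matched && abs(diff) >= effect_thresh) "strong" else "weak",
             stringsAsFactors = FALSE)
}

#' Scan many SNP contexts against a PWM set
#'
#' @param contexts `data.frame` with columns `id`, `context`, `snp_pos`,
#'   `ref`, `alt` (one row per SNP).
#' @param pwms List of [pwm()] objects.
#' @param match_thresh,effect_thresh Passed to [score_allele_disruption()].
#' @return `data.frame` of disruption results, one row per (SNP, motif), with
#'   a leading `id` column.
#' @export
scan_motif_disruptions <- function(contexts, pwms, match_thresh = 0.85,
                                   effect_thresh = 0.4) {
  need <- c("id", "context", "snp_pos", "ref", "alt")
  if (!all(need %in% names(contexts)))
    stop_("contexts needs columns: %s", paste(need, collapse = ", "))
  rows <- vector("list", nrow(contexts) * length(pwms))
  k <- 0L
  for (i in seq_len(nrow(contexts))) {
    for (p in pwms) {
      k <- k + 1L
      r <- score_allele_disruption(p, contexts$context[i], contexts$snp_pos[i],
                                   contexts$ref[i], contexts$alt[i],
                                   match_thresh, effect_thresh)
      rows[[k]] <- cbind(data.frame(id = contexts$id[i], stringsAsFactors = FALSE), r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep matched, strong-effect disruption calls
#'
#' @param results Disruption rows ([scan_motif_disruptions()] or rbind-ed
#'   [score_allele_disruption()] output).
#' @param effect_thresh `|allele_diff|` cutoff (default 0.4).
#' @return The rows with `matched` true and `|allele_diff| >= effect_thresh`,
#'   with `effect` set to `"strong"`.
#' @export
filter_strong <- function(results, effect_thresh = 0.4) {
  if (nrow(results) == 0) return(results)
  keep <- results$matched & abs(results$allele_diff) >= effect_thresh
  out <- results[keep, , drop = FALSE]
  if (nrow(out)) out$effect <- "strong"
  rownames(out) <- NULL
  out
}
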