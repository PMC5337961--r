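# Prioritization filters: exon damaging rule, TSS/disease-gene rule, and the
# three-condition regulatory rule for SNPs in histone-marked distal elements.

DAMAGING_CALLS <- c("possibly_damaging", "probably_damaging", "damaging")
BENIGN_CALLS <- c("tolerated", "benign")
PREDICTOR_COLS <- c("sift", "polyphen2", "provean", "fathmm")

normalize_call <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ -]+", "_", x)
  x[x %in% c("na", "")] <- NA
  x
}

#' Read a missense predictor-call table
#'
#' @param path TSV with header columns `snp`, `gene`, `aa_change`, and one
#'   column per predictor (`SIFT`, `PolyPhen2`, `PROVEAN`, `FATHMM`).
#' @return `data.frame` with normalized lower-case call vocabulary.
#' @export
read_predictor_calls <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("snp", PREDICTOR_COLS) %in% names(d)))
    stop_("predictor table needs columns snp, %s", paste(PREDICTOR_COLS, collapse = ", "))
  for (p in PREDICTOR_COLS) d[[p]] <- normalize_call(d[[p]])
  d
}

#' Flag missense SNPs called damaging by at least one predictor
#'
#' A SNP is flagged when at least one of the four predictor calls is in
#' `{possibly_damaging, probably_damaging, damaging}` (case-insensitive); `NA`
#' never counts toward the rule.
#'
#' @param table Predictor-call table ([read_predictor_calls()] or equivalent
#'   `data.frame` with `snp` plus the four predictor columns).
#' @return Character vector of flagged SNP ids (input order).
#' @export
flag_damaging_missense <- function(table) {
  names(table) <- tolower(names(table))
  if (!all(c("snp", PREDICTOR_COLS) %in% names(table)))
    stop_("table needs columns snp, %s", paste(PREDICTOR_COLS, collapse = ", "))
  calls <- sapply(PREDICTOR_COLS, function(p) normalize_call(table[[p]]))
  calls <- matrix(calls, nrow = nrow(table),
                  dimnames = list(NULL, PREDICTOR_COLS))
  known <- is.na(calls) | calls %in% c(DAMAGING_CALLS, BENIGN_CALLS)
  if (!all(known)) {
    bad <- which(!apply(known, 1, all))[1]
    stop_("unknown predictor call '%s' in row %d (snp %s)",
          calls[!known][1], bad, table$snp[bad])
  }
  hit <- apply(calls, 1, function(z) any(!is.na(z) & z %in% DAMAGING_CALLS))
  table$snp[hit]
}

#' Genes expressed above an FPKM floor in a tissue
#'
#' @param expr Expression table ([read_expression()]): columns `gene`,
#'   `tissue`, `fpkm`.
#' @param tissue Tissue tag.
#' @param fpkm_min Expression floor; genes with FPKM strictly greater are kept
#'   (default 1, the usual "FPKM > 1" expressed-gene rule).
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(expr, tissue, fpkm_min = 1) {
  if (nrow(expr) == 0) return(character())
  avail <- unique(expr$tissue)
  if (!tissue %in% avail)
    stop_("tissue '%s' absent from expression table; available: %s", tissue,
          paste(avail, collapse = ", "))
  sub <- expr[expr$tissue == tissue, , drop = FALSE]
  unique(sub$gene[sub$fpkm > fpkm_min])
}

#' Default curated disease-gene list for the TSS rule
#'
#' The curated type-2-diabetes gene list used as packaged default by
#' [prioritize_tss()]; callers can supply their own.
#' @return Character vector of gene symbols.
#' @export
t2d_gene_list <- function() {
  c("CDKAL1", "ADIPOQ", "WFS1", "NOTCH2", "MAEA", "THADA", "PROX1",
    "IGF2BP2", "PPARG", "ADAM30", "GCKR")
}

new_putative_risk_set <- function(df, stratum) {
  rownames(df) <- NULL
  structure(df, stratum = stratum, class = c("putative_risk_set", "data.frame"))
}

#' @export
print.putative_risk_set <- function(x, ...) {
  cat(sprintf("putative_risk_set (%s stratum): %d SNP(s)\n",
              attr(x, "stratum"), nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Three-condition regulatory prioritization of histone-stratum SNPs
#'
#' A SNP in the histone stratum is retained when all three conditions hold:
#' (1) it overlaps at least one histone-mark interval and its context matches
#' at least one motif; (2) at least one of its motif matches survives the
#' strong-disruption filter; (3) at least one strongly-disrupted TF has a
#' target gene in the expressed set. Provenance records the motifs and genes
#' satisfying condition 3 and a per-condition flag set for auditing.
#'
#' @param annotations A [classify_region()] result.
#' @param disruptions Disruption rows for the candidate SNPs
#'   ([scan_motif_disruptions()] output; may be pre-filtered or full — the
#'   strong filter is re-applied internally).
#' @param tf_targets `data.frame` with columns `tf`, `gene` (TF to target-gene
#'   edges). Motif names in `disruptions` are matched against `tf`.
#' @param expressed Character vector of expressed gene ids
#'   ([expressed_genes()], possibly unioned over tissues).
#' @param effect_thresh Strong-effect `|allele_diff|` cutoff (default 0.4).
#' @return A `putative_risk_set` with columns `id`, `cond_mark_motif`,
#'   `cond_strong`, `cond_expressed_target`, `motifs`, `genes`.
#' @export
prioritize_regulatory <- function(annotations, disruptions, tf_targets,
                                  expressed, effect_thresh = 0.4) {
  in_mark <- unique(annotations$marks$id)
  strong <- filter_strong(disruptions, effect_thresh)
  matched_ids <- unique(disruptions$id[disruptions$matched])

  missing_tf <- setdiff(unique(strong$motif), tf_targets$tf)
  if (length(missing_tf))
    message(sprintf("TF(s) with no target-gene edges (condition 3 unsatisfiable): %s",
                    paste(missing_tf, collapse = ", ")))

  rows <- list()
  for (id in in_mark) {
    c1 <- id %in% matched_ids
    s <- strong[strong$id == id, , drop = FALSE]
    c2 <- nrow(s) > 0
    genes_hit <- character(); motifs_hit <- character()
    if (c2) {
      for (tf in unique(s$motif)) {
        tg <- intersect(tf_targets$gene[tf_targets$tf == tf], expressed)
        if (length(tg)) {
          motifs_hit <- c(motifs_hit, tf)
          genes_hit <- union(genes_hit, tg)
        }
      }
    }
    c3 <- length(motifs_hit) > 0
    if (c1 && c2 && c3) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, cond_mark_motif = c1, cond_strong = c2,
        cond_expressed_target = c3,
        motifs = paste(motifs_hit, collapse = ","),
        genes = paste(sort(genes_hit), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), cond_mark_motif = logical(),
               cond_strong = logical(), cond_expressed_target = logical(),
               motifs = character(), genes = character(), stringsAsFactors = FALSE)
  new_putative_risk_set(out, "histone")
}

#' TSS-stratum prioritization against a curated disease-gene list
#'
#' Keeps TSS-window SNPs with at least one strong motif disruption whose TSS
#' gene belongs to the curated list.
#'
#' @param annotations A [classify_region()] result (TSS windows labeled by
#'   gene).
#' @param disruptions Disruption rows for the candidate SNPs.
#' @param gene_list Curated disease-gene set (default [t2d_gene_list()]).
#' @param effect_thresh Strong-effect cutoff (default 0.4).
#' @return A `putative_risk_set` with columns `id`, `tss_genes`, `motifs`.
#' @export
prioritize_tss <- function(annotations, disruptions, gene_list = t2d_gene_list(),
                           effect_thresh = 0.4) {
  v <- annotations$variants
  strong <- filter_strong(disruptions, effect_thresh)
  rows <- list()
  for (i in which(v$in_tss)) {
    genes <- intersect(v$tss_genes[[i]], gene_list)
    if (!length(genes)) next
    s <- strong[strong$id == v$id[i], , drop = FALSE]
    if (nrow(s) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = v$id[i], tss_genes = paste(sort(genes), collapse = ","),
      motifs = paste(unique(s$motif), collapse = ","), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), tss_genes = character(), motifs = character(),
               stringsAsFactors = FALSE)
  new_putative_risk_set(out, "tss")
}
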