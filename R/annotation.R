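# Region classification of proxy SNPs and histone-mark co-occurrence.

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end))
}

variants_to_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1))
}

# indices of intervals overlapped by each variant (list over variants)
overlap_hits <- function(variants, intervals) {
  if (nrow(variants) == 0 || is.null(intervals) || nrow(intervals) == 0)
    return(rep(list(integer()), nrow(variants)))
  hits <- GenomicRanges::findOverlaps(variants_to_granges(variants),
                                      intervals_to_granges(intervals))
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(variants))))
}

#' Build TSS windows around transcription start sites
#'
#' Each window spans `flank_bp` on both sides of the start site in 1-based
#' closed coordinates (`pos - flank_bp .. pos + flank_bp`), converted to BED
#' half-open internally. Windows are strand-agnostic: proximal regulatory
#' elements sit on either side of a start site; strand is kept for reporting
#' only. Windows running below position 1 are truncated there with a message.
#'
#' @param tss `data.frame` with columns `gene`, `chrom`, `pos` (1-based TSS),
#'   and optionally `strand`.
#' @param flank_bp Flank in bp (default 2000).
#' @return A [genomic_intervals()] table labeled by gene.
#' @export
build_tss_windows <- function(tss, flank_bp = 2000) {
  need <- c("gene", "chrom", "pos")
  if (!all(need %in% names(tss))) stop_("tss needs columns: %s", paste(need, collapse = ", "))
  start0 <- tss$pos - flank_bp - 1   # BED start of 1-based (pos - flank)
  trunc <- start0 < 0
  if (any(trunc)) {
    message(sprintf("truncated %d TSS window(s) at position 1", sum(trunc)))
    start0[trunc] <- 0
  }
  genomic_intervals(tss$chrom, start0, tss$pos + flank_bp, label = tss$gene)
}

#' Classify variants by genomic region
#'
#' Flags every variant for coding-exon, UTR and TSS-window membership and
#' records all (mark, tissue) histone-interval memberships. Flags are purely
#' interval-overlap derived and not mutually exclusive, except that a position
#' covered by both a coding-exon and a UTR interval is counted as coding
#' (conflict logged).
#'
#' @param variants Variant table ([variant_table()]).
#' @param exons,utrs,tss [genomic_intervals()] tables (any may be `NULL` or
#'   empty). TSS intervals should carry gene ids in `label`.
#' @param marks [genomic_intervals()] table of histone-mark intervals with
#'   `label` = mark name and `tissue` set.
#' @return Object of class `region_annotation`: `$variants` with logical flag
#'   columns and a `tss_genes` list-column, `$marks` long table
#'   (`id`, `mark`, `tissue`), `$mark_universe`, and `$summary` per-stratum
#'   counts.
#' @export
classify_region <- function(variants, exons = NULL, utrs = NULL, tss = NULL,
                            marks = NULL) {
  ex_hits <- overlap_hits(variants, exons)
  utr_hits <- overlap_hits(variants, utrs)
  tss_hits <- overlap_hits(variants, tss)
  mk_hits <- overlap_hits(variants, marks)

  in_exon <- lengths(ex_hits) > 0
  in_utr <- lengths(utr_hits) > 0
  conflict <- in_exon & in_utr
  if (any(conflict)) {
    message(sprintf("%d variant(s) in both coding-exon and UTR intervals; coding takes precedence",
                    sum(conflict)))
    in_utr[conflict] <- FALSE
  }
  tss_genes <- lapply(tss_hits, function(i)
    unique(tss$label[i]) %||% character())

  ann <- variants
  ann$in_coding_exon <- in_exon
  ann$in_utr <- in_utr
  ann$in_tss <- lengths(tss_hits) > 0
  ann$tss_genes <- I(tss_genes)

  mark_rows <- if (!is.null(marks) && nrow(marks) > 0) {
    idx <- rep(seq_len(nrow(variants)), lengths(mk_hits))
    sub <- unlist(mk_hits, use.names = FALSE)
    mr <- unique(data.frame(id = variants$id[idx], mark = marks$label[sub],
                            tissue = marks$tissue[sub], stringsAsFactors = FALSE))
    rownames(mr) <- NULL
    mr
  } else {
    data.frame(id = character(), mark = character(), tissue = character(),
               stringsAsFactors = FALSE)
  }
  universe <- if (!is.null(marks) && nrow(marks) > 0)
    unique(data.frame(mark = marks$label, tissue = marks$tissue,
                      stringsAsFactors = FALSE))
  else data.frame(mark = character(), tissue = character(), stringsAsFactors = FALSE)

  hit_chroms <- unique(c(exons$chrom, utrs$chrom, tss$chrom, marks$chrom))
  off_panel <- sum(!variants$chrom %in% hit_chroms)

  summary <- c(n_variants = nrow(variants),
               coding_exon = sum(ann$in_coding_exon),
               utr = sum(ann$in_utr),
               tss = sum(ann$in_tss),
               histone = length(unique(mark_rows$id)),
               no_annotated_chrom = off_panel)
  structure(list(variants = ann, marks = mark_rows, mark_universe = universe,
                 summary = summary),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("region_annotation: %d variants | coding exon %d, UTR %d, TSS %d, histone %d\n",
              s[["n_variants"]], s[["coding_exon"]], s[["utr"]], s[["tss"]],
              s[["histone"]]))
  invisible(x)
}

ann_tissues <- function(ann) unique(ann$mark_universe$tissue)

#' Histone-mark co-occurrence counts
#'
#' For one tissue, counts SNPs occupying the overlap of each pair of histone
#' marks: entry (i, j) is the number of SNPs lying in intervals of both mark i
#' and mark j (each SNP counted once per pair regardless of how many intervals
#' it hits); the diagonal is the per-mark SNP count.
#'
#' @param annotations A [classify_region()] result.
#' @param tissue Tissue tag.
#' @return Object of class `cooccurrence_matrix`: symmetric integer matrix with
#'   mark names as dimnames and a `tissue` attribute.
#' @export
mark_cooccurrence <- function(annotations, tissue) {
  avail <- ann_tissues(annotations)
  if (!tissue %in% avail)
    stop_("unknown tissue '%s'; available: %s", tissue,
          paste(avail, collapse = ", "))
  marks <- sort(unique(annotations$mark_universe$mark[
    annotations$mark_universe$tissue == tissue]))
  m <- annotations$marks[annotations$marks$tissue == tissue, , drop = FALSE]
  # SNP x mark membership matrix
  mem <- table(factor(m$id, levels = unique(m$id)),
               factor(m$mark, levels = marks)) > 0
  counts <- if (nrow(mem)) crossprod(mem * 1L) else
    matrix(0L, length(marks), length(marks), dimnames = list(marks, marks))
  storage.mode(counts) <- "integer"
  structure(counts, tissue = tissue, class = c("cooccurrence_matrix", class(counts)))
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("SNP co-occurrence across histone marks (%s):\n", attr(x, "tissue")))
  print(unclass(x))
  invisible(x)
}

# ids of SNPs lying in >= min_marks distinct marks in one tissue
overlapped_snps <- function(annotations, tissue, min_marks) {
  m <- annotations$marks[annotations$marks$tissue == tissue, , drop = FALSE]
  k <- tapply(m$mark, m$id, function(z) length(unique(z)))
  names(k)[k >= min_marks]
}

#' High-confidence SNPs shared across two tissues
#'
#' A SNP counts as "overlapped" in a tissue when it lies in at least
#' `min_marks` distinct histone marks there; the intersection keeps SNPs
#' overlapped in both tissues.
#'
#' @param annotations A [classify_region()] result.
#' @param tissues Character vector of exactly two tissue tags.
#' @param min_marks Minimum distinct marks per tissue (default 2).
#' @return Character vector of variant ids.
#' @export
tissue_intersection <- function(annotations, tissues, min_marks = 2) {
  if (length(tissues) != 2) stop_("exactly two tissues required, got %d", length(tissues))
  avail <- ann_tissues(annotations)
  missing <- setdiff(tissues, avail)
  if (length(missing))
    stop_("unknown tissue(s) %s; available: %s", paste(missing, collapse = ", "),
          paste(avail, collapse = ", "))
  intersect(overlapped_snps(annotations, tissues[1], min_marks),
            overlapped_snps(annotations, tissues[2], min_marks))
}
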