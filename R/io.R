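# Readers/writers for the external formats the pipeline touches.
#
# Coordinate conventions, fixed at the I/O boundary and nowhere else:
#   * variants are 1-based (VCF convention)
#   * intervals are 0-based half-open (BED convention)
# A SNP at 1-based position p overlaps interval [start, end) iff start <= p-1 < end.

#' Construct a variant table
#'
#' Builds and validates the package's canonical variant representation: one
#' biallelic SNP per row with a 1-based position and single-base ACGT alleles.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (bp).
#' @param id SNP identifiers (e.g. rsIDs).
#' @param ref,alt Reference and alternate alleles (uppercase, single base).
#' @return A `data.frame` with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
variant_table <- function(chrom, pos, id, ref, alt) {
  chrom <- as.character(chrom); id <- as.character(id)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop_("variant positions must be >= 1")
  if (any(ref == alt)) stop_("ref and alt alleles must differ")
  bad <- !(is_snp_allele(ref) & is_snp_allele(alt))
  if (any(bad)) stop_("non-SNP alleles at: %s", paste(id[bad], collapse = ", "))
  data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' @param codes Integer matrix, samples x variants, each entry the count of the
#'   alternate allele in `{0, 1, 2, NA}` (NA = missing call).
#' @param variants Variant table ([variant_table()]), one row per column of
#'   `codes`.
#' @param phenotype Character vector over samples with values in
#'   `{"case", "control", "unknown"}`, named by sample id or in row order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, variants, phenotype) {
  codes <- as.matrix(codes)
  if (ncol(codes) != nrow(variants))
    stop_("codes has %d columns but variants has %d rows", ncol(codes), nrow(variants))
  if (is.null(rownames(codes))) stop_("codes must carry sample ids as rownames")
  colnames(codes) <- variants$id
  if (!is.null(names(phenotype))) phenotype <- phenotype[rownames(codes)]
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(codes))
    stop_("phenotype length %d != %d samples", length(phenotype), nrow(codes))
  phenotype[is.na(phenotype)] <- "unknown"
  bad <- setdiff(unique(phenotype), c("case", "control", "unknown"))
  if (length(bad)) stop_("unknown phenotype labels: %s", paste(bad, collapse = ", "))
  ok <- is.na(codes) | codes %in% c(0, 1, 2)
  if (!all(ok)) stop_("genotype codes must be 0, 1, 2 or NA")
  storage.mode(codes) <- "double"
  structure(list(samples = rownames(codes), variants = variants,
                 codes = codes, phenotype = setNames(phenotype, rownames(codes))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(factor(x$phenotype, levels = c("case", "control", "unknown")))
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d cases, %d controls, %d unknown)\n",
              length(x$samples), nrow(x$variants), tab[["case"]], tab[["control"]],
              tab[["unknown"]]))
  cat(sprintf("missingness: %.3f\n", mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

read_phenotypes <- function(path) {
  ph <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ph) < 2) stop_("phenotype file must have 2 tab-separated columns")
  # tolerate a header line
  if (!tolower(ph[1, 2]) %in% c("case", "control", "unknown")) ph <- ph[-1, , drop = FALSE]
  lab <- tolower(ph[[2]])
  bad <- !lab %in% c("case", "control", "unknown")
  if (any(bad)) stop_("bad phenotype label(s): %s", paste(unique(ph[[2]][bad]), collapse = ", "))
  setNames(lab, as.character(ph[[1]]))
}

#' Read genotypes with phenotypes into a genotype matrix
#'
#' Supports VCF (via \pkg{vcfR}) and the package's plain `matrix-tsv` layout
#' (columns `chrom`, `pos`, `id`, `ref`, `alt`, then one column per sample).
#' VCF records are split into biallelic SNPs: multi-allelic sites become one
#' variant per alternate allele and indel alleles are skipped with a message.
#' Optionally, a numeric per-call FORMAT field can be used as a call-confidence
#' score; calls with score above `score_max` are set missing, mirroring the
#' usual "treat low-confidence calls as no-calls" genotyping QC.
#'
#' @param path Genotype file.
#' @param format `"vcf"` or `"matrix"`.
#' @param phenotype_path 2-column TSV (`sample_id`, `case|control`). Every
#'   sample listed here must exist in the genotype file; genotyped samples
#'   without a phenotype are kept with label `"unknown"`.
#' @param score_field Optional FORMAT key holding a per-call confidence score
#'   (VCF only).
#' @param score_max Calls with score strictly above this are set missing
#'   (default 0.5).
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("vcf", "matrix"), phenotype_path,
                                 score_field = NULL, score_max = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("no such file: %s", path)
  pheno <- read_phenotypes(phenotype_path)
  gm <- if (format == "vcf") {
    read_gm_vcf(path, score_field, score_max)
  } else {
    read_gm_matrix(path)
  }
  missing_samples <- setdiff(names(pheno), gm$samples)
  if (length(missing_samples))
    stop_("phenotype sample(s) absent from genotypes: %s",
          paste(missing_samples, collapse = ", "))
  phen <- setNames(rep("unknown", length(gm$samples)), gm$samples)
  phen[names(pheno)] <- pheno
  genotype_matrix(gm$codes, gm$variants, phen)
}

read_gm_vcf <- function(path, score_field, score_max) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  score <- if (!is.null(score_field))
    vcfR::extract.gt(vcf, element = score_field, as.numeric = TRUE) else NULL

  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  out_codes <- list(); out_var <- list()
  n_indel <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    for (k in seq_along(alts[[i]])) {
      alt <- toupper(alts[[i]][k])
      if (!(is_snp_allele(ref) && is_snp_allele(alt))) { n_indel <- n_indel + 1L; next }
      g <- gt[i, ]
      codes <- vapply(strsplit(g, "[/|]"), function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a == as.character(k))
      }, numeric(1))
      if (!is.null(score)) codes[!is.na(score[i, ]) & score[i, ] > score_max] <- NA
      id <- fix[i, "ID"]
      if (is.na(id) || id == ".") id <- sprintf("%s:%s", fix[i, "CHROM"], fix[i, "POS"])
      if (length(alts[[i]]) > 1) id <- paste0(id, "_", alt)
      out_var[[length(out_var) + 1L]] <-
        list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
             id = id, ref = ref, alt = alt)
      out_codes[[length(out_codes) + 1L]] <- codes
    }
  }
  if (n_indel > 0) message(sprintf("skipped %d non-SNP allele(s)", n_indel))
  if (!length(out_var)) stop_("no biallelic SNPs found in %s", path)
  v <- do.call(rbind.data.frame, c(out_var, stringsAsFactors = FALSE))
  variants <- variant_table(v$chrom, v$pos, v$id, v$ref, v$alt)
  codes <- do.call(cbind, out_codes)
  rownames(codes) <- colnames(gt)
  dedup_variants(codes, variants)
}

# de-duplicate by (chrom, pos, ref, alt), keeping the first record
dedup_variants <- function(codes, variants) {
  key <- with(variants, paste(chrom, pos, ref, alt))
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("dropped %d duplicate variant record(s): %s", sum(dup),
                    paste(unique(variants$id[dup]), collapse = ", ")))
    codes <- codes[, !dup, drop = FALSE]
    variants <- variants[!dup, , drop = FALSE]
  }
  list(codes = codes, variants = variants, samples = rownames(codes))
}

read_gm_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(d))) stop_("matrix-tsv needs columns: %s", paste(need, collapse = ", "))
  variants <- variant_table(d$chrom, d$pos, d$id, d$ref, d$alt)
  samp <- setdiff(names(d), need)
  codes <- t(as.matrix(d[, samp, drop = FALSE]))
  colnames(codes) <- variants$id
  dedup_variants(codes, variants)
}

#' Write a genotype matrix as matrix-tsv
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file; [read_genotype_matrix()] with `format = "matrix"`
#'   reproduces the codes exactly.
#' @export
write_genotype_matrix <- function(gm, path) {
  d <- cbind(gm$variants, as.data.frame(t(gm$codes), check.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the phenotype labels of a genotype matrix as 2-column TSV
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @export
write_phenotypes <- function(gm, path) {
  write.table(data.frame(sample = names(gm$phenotype), phenotype = gm$phenotype),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genomic-interval table (BED semantics)
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends.
#' @param label Feature names (mark, gene, exon id).
#' @param tissue Optional tissue tag.
#' @return `data.frame` with class `genomic_intervals` prepended.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_,
                              tissue = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop_("interval starts must be >= 0")
  if (any(start >= end)) stop_("interval start >= end at row(s) %s",
                               paste(which(start >= end), collapse = ", "))
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = as.character(label), tissue = as.character(tissue),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

empty_intervals <- function() {
  genomic_intervals(character(), numeric(), numeric(), character(), character())
}

#' Read a BED file into genomic intervals
#'
#' Half-open 0-based intervals: a SNP at 1-based position `p` overlaps
#' `[start, end)` iff `start <= p - 1 < end`.
#'
#' @param path BED3+ file.
#' @param tissue Optional tissue tag applied to all rows.
#' @param label Optional feature label overriding column 4.
#' @return A [genomic_intervals()] table.
#' @export
read_intervals <- function(path, tissue = NA_character_, label = NULL) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  if (file.size(path) == 0) {
    warn_("empty BED file: %s", path)
    return(empty_intervals())
  }
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(d) < 3) stop_("BED file needs >= 3 columns: %s", path)
  start <- as.numeric(d[[2]]); end <- as.numeric(d[[3]])
  bad <- which(!(start < end))
  if (length(bad)) stop_("start >= end on line(s) %s of %s",
                         paste(bad, collapse = ", "), path)
  lab <- if (!is.null(label)) label else if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_
  genomic_intervals(d[[1]], start, end, lab, tissue)
}

#' Write genomic intervals as BED
#' @param intervals A [genomic_intervals()] table.
#' @param path Output file.
#' @export
write_intervals <- function(intervals, path) {
  d <- intervals[, c("chrom", "start", "end", "label")]
  d$start <- format(d$start, scientific = FALSE, trim = TRUE)
  d$end <- format(d$end, scientific = FALSE, trim = TRUE)
  d$label[is.na(d$label)] <- "."
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Does a 1-based SNP position fall in an interval?
#'
#' The half-open rule in one place, used by annotation and tests.
#' @param pos 1-based position(s).
#' @param start,end 0-based half-open interval bounds.
#' @return Logical vector.
#' @export
pos_in_interval <- function(pos, start, end) start <= (pos - 1) & (pos - 1) < end

#' Construct a position weight matrix
#'
#' @param name Motif/TF identifier.
#' @param probs 4 x w matrix of column-stochastic base probabilities, rows in
#'   A, C, G, T order.
#' @param target_genes Optional character vector of genes the TF regulates.
#' @return An object of class `pwm` carrying the attainable score bounds
#'   `s_min` (sum of column minima) and `s_max` (sum of column maxima).
#' @export
pwm <- function(name, probs, target_genes = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop_("PWM '%s' must have 4 rows (A,C,G,T)", name)
  rownames(probs) <- BASES
  if (any(probs < 0)) stop_("PWM '%s' has negative probabilities", name)
  csum <- colSums(probs)
  if (any(abs(csum - 1) > 1e-9))
    stop_("PWM '%s': columns must sum to 1 (max deviation %.2e)", name,
          max(abs(csum - 1)))
  s_min <- sum(apply(probs, 2, min))
  s_max <- sum(apply(probs, 2, max))
  if (!(s_min < s_max)) stop_("PWM '%s' is degenerate (s_min == s_max)", name)
  structure(list(name = name, probs = probs, s_min = s_min, s_max = s_max,
                 target_genes = target_genes),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, score range [%.3f, %.3f]\n",
              x$name, ncol(x$probs), x$s_min, x$s_max))
  invisible(x)
}

pwm_width <- function(p) ncol(p$probs)

counts_to_probs <- function(counts, pseudocount) {
  counts <- as.matrix(counts)
  sweep(counts + 0.25 * pseudocount, 2, colSums(counts) + pseudocount, "/")
}

#' Read a JASPAR-style PFM file into a list of PWMs
#'
#' Parses the JASPAR 2016 text layout: a `>identifier name` header followed by
#' four rows of counts in A, C, G, T order (with or without brackets). Counts
#' are converted to column probabilities with an equal-background pseudocount:
#' `p = (c + 0.25 * s) / (N + s)` for column total `N` and pseudocount `s`.
#'
#' @param path PFM text file.
#' @param pseudocount Non-negative pseudocount `s` (default 1).
#' @return List of [pwm()] objects named by motif identifier.
#' @export
read_pwm_set <- function(path, pseudocount = 1) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  if (pseudocount < 0) stop_("pseudocount must be >= 0")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_("no '>' motif headers in %s", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i]
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[(from + 1):to]
    if (length(block) != 4)
      stop_("motif at line %d has %d count rows, expected 4", from, length(block))
    name <- sub("^>\\s*", "", lines[from])
    name <- gsub("\\s+", "_", trimws(name))
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1)
      stop_("ragged count matrix for motif '%s' (widths %s)", name,
            paste(widths, collapse = ","))
    counts <- do.call(rbind, rows)
    if (any(counts < 0)) stop_("negative count in motif '%s'", name)
    out[[name]] <- pwm(name, counts_to_probs(counts, pseudocount))
  }
  out
}

#' Read an expression table (gene, tissue, FPKM)
#' @param path TSV with header columns `gene`, `tissue`, `fpkm`.
#' @return Validated `data.frame`.
#' @export
read_expression <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("gene", "tissue", "fpkm")
  if (!all(need %in% names(d))) stop_("expression table needs columns: %s",
                                      paste(need, collapse = ", "))
  if (any(d$fpkm < 0)) stop_("negative FPKM values")
  if (anyDuplicated(d[, c("gene", "tissue")]))
    stop_("duplicated (gene, tissue) rows in %s", path)
  d[, need]
}

#' Read a TF to target-gene edge list
#' @param path TSV with header columns `tf`, `gene`.
#' @return `data.frame` with columns `tf`, `gene`.
#' @export
read_tf_targets <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("tf", "gene") %in% names(d)))
    stop_("TF target table needs columns tf, gene")
  d[, c("tf", "gene")]
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
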