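# Two-locus linkage disequilibrium and proxy-SNP search.
#
# r2 = D^2 / (pA (1-pA) pB (1-pB)) with D = pAB - pA pB, where "A"/"B" denote
# the allele coded 1 at each locus. r2 is invariant under allele relabeling.

new_hap_freqs <- function(pAB, pAb, paB, pab, n) {
  pAB <- unname(pAB); pAb <- unname(pAb); paB <- unname(paB); pab <- unname(pab)
  pA <- pAB + pAb
  pB <- pAB + paB
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  mono <- denom <= 0
  r2 <- if (mono) NA_real_ else unname(D^2 / denom)
  structure(list(pAB = pAB, pAb = pAb, paB = paB, pab = pab,
                 pA = pA, pB = pB, D = D, r2 = r2,
                 monomorphic = mono, n = n),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  if (x$monomorphic) {
    cat(sprintf("hap_freqs (n=%d): monomorphic locus, r2 undefined\n", x$n))
  } else {
    cat(sprintf("hap_freqs (n=%d): pA=%.4f pB=%.4f D=%.4f r2=%.4f\n",
                x$n, x$pA, x$pB, x$D, x$r2))
  }
  invisible(x)
}

#' Haplotype frequencies and r-squared from phased haplotypes
#'
#' Direct counting over chromosome copies. Entries are 0/1 allele codes; the
#' allele coded 1 plays the role of "A"/"B" in the haplotype-frequency symbols,
#' a labeling choice that r-squared does not depend on.
#'
#' @param h1,h2 Equal-length binary vectors, one entry per chromosome copy.
#' @return A `hap_freqs` object with fields `pAB`, `pAb`, `paB`, `pab`, `pA`,
#'   `pB`, `D`, `r2`. A monomorphic locus yields `r2 = NA` with
#'   `monomorphic = TRUE` (flagged, not silently zero).
#' @export
haplotype_freqs_phased <- function(h1, h2) {
  if (length(h1) != length(h2)) stop_("haplotype vectors differ in length")
  keep <- !(is.na(h1) | is.na(h2))
  h1 <- h1[keep]; h2 <- h2[keep]
  if (!length(h1)) stop_("no complete haplotype pairs")
  if (!all(h1 %in% c(0, 1)) || !all(h2 %in% c(0, 1)))
    stop_("haplotype vectors must be binary 0/1")
  n <- length(h1)
  new_hap_freqs(pAB = mean(h1 == 1 & h2 == 1),
                pAb = mean(h1 == 1 & h2 == 0),
                paB = mean(h1 == 0 & h2 == 1),
                pab = mean(h1 == 0 & h2 == 0), n = n)
}

#' Haplotype frequencies by EM from unphased genotypes
#'
#' Maximum-likelihood two-locus haplotype frequencies from diploid genotype
#' codes, resolving the double-heterozygote phase ambiguity by
#' expectation-maximization. Initialization is at linkage equilibrium
#' (`pAB = pA * pB`); the allele frequencies are preserved at their sample
#' values throughout, so EM effectively maximizes the multinomial likelihood
#' over the single free parameter `pAB`.
#'
#' @param g1,g2 Genotype codes in `{0, 1, 2, NA}` over the same samples;
#'   samples missing at either locus are dropped.
#' @param tol Convergence threshold on the max absolute change in haplotype
#'   frequencies (default 1e-8).
#' @param max_iter Iteration cap (default 1000). Non-convergence raises an
#'   error of class `snprisk_em_error` carrying the last iterate in
#'   `$last_freqs`.
#' @return A `hap_freqs` object (`n` = number of complete sample pairs).
#' @export
haplotype_freqs_em <- function(g1, g2, tol = 1e-8, max_iter = 1000) {
  if (length(g1) != length(g2)) stop_("genotype vectors differ in length")
  keep <- !(is.na(g1) | is.na(g2))
  g1 <- g1[keep]; g2 <- g2[keep]
  if (!length(g1)) stop_("no complete genotype pairs")
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2))
    stop_("genotype codes must be 0, 1 or 2")
  n <- length(g1)
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[g1[i] + 1, g2[i] + 1] <- cnt[g1[i] + 1, g2[i] + 1] + 1

  # haplotype counts fully determined outside the double-het cell (g1=1, g2=1)
  # hap order: AB, Ab, aB, ab ("A" = allele 1 at locus 1, "B" = allele 1 at locus 2)
  fixed <- c(
    AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  )
  ndh <- cnt[2, 2]
  tot <- 2 * n

  pA <- (2 * sum(cnt[3, ]) + sum(cnt[2, ])) / tot
  pB <- (2 * sum(cnt[, 3]) + sum(cnt[, 2])) / tot
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))

  if (ndh == 0) {
    p <- fixed / tot
    return(new_hap_freqs(p[1], p[2], p[3], p[4], n))
  }
  for (it in seq_len(max_iter)) {
    cis <- p[1] * p[4]
    trans <- p[2] * p[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    newp <- (fixed + ndh * c(w, 1 - w, 1 - w, w)) / tot
    delta <- max(abs(newp - p))
    p <- newp
    if (delta < tol) return(new_hap_freqs(p[1], p[2], p[3], p[4], n))
  }
  cond <- structure(
    class = c("snprisk_em_error", "error", "condition"),
    list(message = sprintf("EM did not converge in %d iterations", max_iter),
         call = sys.call(-1), last_freqs = p))
  stop(cond)
}

# log-likelihood of the 3x3 genotype table under haplotype frequencies p
# (used by the grid-search oracle in tests; exported for reuse there)
#' Multinomial log-likelihood of a two-locus genotype sample
#'
#' Log-likelihood of paired genotype codes under Hardy-Weinberg random pairing
#' of haplotypes with frequencies `(pAB, pAb, paB, pab)`. The double
#' heterozygote sums over both phases. Used as the objective for grid-search
#' cross-checks of the EM fit.
#'
#' @param g1,g2 Genotype codes in `{0, 1, 2}` (no missing).
#' @param p Numeric length-4 vector `(pAB, pAb, paB, pab)`.
#' @return Log-likelihood value.
#' @export
genotype_loglik <- function(g1, g2, p) {
  stopifnot(length(p) == 4)
  probs <- matrix(0, 3, 3)
  probs[3, 3] <- p[1]^2
  probs[3, 2] <- 2 * p[1] * p[2]
  probs[3, 1] <- p[2]^2
  probs[2, 3] <- 2 * p[1] * p[3]
  probs[2, 2] <- 2 * p[1] * p[4] + 2 * p[2] * p[3]
  probs[2, 1] <- 2 * p[2] * p[4]
  probs[1, 3] <- p[3]^2
  probs[1, 2] <- 2 * p[3] * p[4]
  probs[1, 1] <- p[4]^2
  cnt <- tabulate(3 * g1 + g2 + 1, nbins = 9)    # cell (g1, g2) -> 3 g1 + g2 + 1
  pr <- probs[cbind(rep(1:3, each = 3), rep(1:3, 3))]
  sum(cnt * log(pmax(pr, .Machine$double.xmin)))
}

#' Haplotype panel container
#'
#' @param haplotypes Integer matrix of 0/1 allele codes, one row per chromosome
#'   copy (2 per individual, consecutive rows), one column per variant.
#' @param variants Variant table ([variant_table()]).
#' @return Object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haplotypes, variants) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != nrow(variants))
    stop_("haplotype matrix has %d columns but variants has %d rows",
          ncol(haplotypes), nrow(variants))
  if (nrow(haplotypes) %% 2 != 0) stop_("odd number of haplotype rows")
  if (!all(haplotypes %in% c(0L, 1L))) stop_("haplotypes must be 0/1")
  colnames(haplotypes) <- variants$id
  structure(list(haplotypes = haplotypes, variants = variants),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d individuals) x %d SNPs\n",
              nrow(x$haplotypes), nrow(x$haplotypes) / 2, nrow(x$variants)))
  invisible(x)
}

#' Write a haplotype panel as phased VCF
#' @param panel A [haplotype_panel()].
#' @param path Output file (plain-text VCF v4.2, GT phased `a|b`).
#' @export
write_vcf <- function(panel, path) {
  h <- panel$haplotypes
  n_ind <- nrow(h) / 2
  ids <- sprintf("IND%04d", seq_len(n_ind))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  v <- panel$variants
  gt <- matrix(paste(h[seq(1, nrow(h), 2), , drop = FALSE],
                     h[seq(2, nrow(h), 2), , drop = FALSE], sep = "|"),
               nrow = n_ind)
  for (j in seq_len(nrow(v))) {
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#' @param path Phased VCF (all GT entries `a|b`).
#' @return A [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(!grepl("^[01]\\|[01]$", gt)))
    stop_("panel VCF must be fully phased biallelic (GT 'a|b')")
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  n_ind <- ncol(gt)
  h <- matrix(0L, 2 * n_ind, nrow(gt))
  h[seq(1, 2 * n_ind, 2), ] <- t(a1)
  h[seq(2, 2 * n_ind, 2), ] <- t(a2)
  variants <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                            fix[, "ID"], fix[, "REF"], fix[, "ALT"])
  haplotype_panel(h, variants)
}

panel_variants <- function(panel) {
  if (inherits(panel, "haplotype_panel") || inherits(panel, "genotype_matrix"))
    return(panel$variants)
  stop_("panel must be a haplotype_panel or genotype_matrix")
}

panel_r2 <- function(panel, i, j) {
  if (inherits(panel, "haplotype_panel")) {
    haplotype_freqs_phased(panel$haplotypes[, i], panel$haplotypes[, j])
  } else {
    haplotype_freqs_em(panel$codes[, i], panel$codes[, j])
  }
}

#' Find proxy SNPs in high LD with a tag SNP
#'
#' Scans a window centered on the tag: a "window of W bp around the tag" is
#' read as +/- W/2 on the tag's chromosome. r-squared comes from phased
#' counting when the panel is a [haplotype_panel()], from the EM fit when it is
#' an unphased [genotype_matrix()]. Monomorphic panel SNPs are skipped with a
#' logged count.
#'
#' @param tag Tag SNP identifier (must be present in the panel).
#' @param panel A [haplotype_panel()] or [genotype_matrix()].
#' @param window_bp Total window width in bp (default 1e6, i.e. +/- 500 kb).
#' @param r2_min Inclusive r-squared threshold (default 0.5).
#' @return `data.frame` (class `proxy_hits`) with columns `tag_id`, `proxy_id`,
#'   `chrom`, `pos`, `r2`, `distance`, sorted by descending `r2`, ties by
#'   position. The tag itself is excluded.
#' @export
find_proxies <- function(tag, panel, window_bp = 1e6, r2_min = 0.5) {
  v <- panel_variants(panel)
  ti <- match(tag, v$id)
  if (is.na(ti)) stop_("tag SNP '%s' not found in panel", tag)
  half <- window_bp / 2
  cand <- which(v$chrom == v$chrom[ti] & abs(v$pos - v$pos[ti]) <= half &
                  seq_len(nrow(v)) != ti)
  n_mono <- 0L
  rows <- list()
  for (j in cand) {
    hf <- panel_r2(panel, ti, j)
    if (hf$monomorphic) { n_mono <- n_mono + 1L; next }
    if (hf$r2 >= r2_min) {
      rows[[length(rows) + 1L]] <- data.frame(
        tag_id = tag, proxy_id = v$id[j], chrom = v$chrom[j], pos = v$pos[j],
        r2 = hf$r2, distance = abs(v$pos[j] - v$pos[ti]),
        stringsAsFactors = FALSE)
    }
  }
  if (n_mono > 0) message(sprintf("skipped %d monomorphic panel SNP(s)", n_mono))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag_id = character(), proxy_id = character(), chrom = character(),
               pos = integer(), r2 = numeric(), distance = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(-out$r2, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("proxy_hits", "data.frame")
  out
}
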