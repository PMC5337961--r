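# Shared in-code fixtures for the test suite.

# the 2-column toy motif: column 1 favors A (0.7), column 2 favors C (0.7)
toy_pwm <- function() {
  pwm("toy", matrix(c(0.7, 0.1, 0.1, 0.1,
                      0.1, 0.7, 0.1, 0.1), nrow = 4))
}

# small genotype matrix with explicit codes (rows = samples)
toy_gm <- function(codes, phenotype, freqs = NULL) {
  codes <- as.matrix(codes)
  rownames(codes) <- sprintf("S%02d", seq_len(nrow(codes)))
  v <- variant_table(chrom = "chr1",
                     pos = 1000 * seq_len(ncol(codes)),
                     id = sprintf("v%02d", seq_len(ncol(codes))),
                     ref = "A", alt = "G")
  genotype_matrix(codes, v, phenotype)
}

# phased haplotype pair from AB/Ab/aB/ab counts
haps_from_counts <- function(AB, Ab, aB, ab) {
  list(h1 = rep(c(1, 1, 0, 0), c(AB, Ab, aB, ab)),
       h2 = rep(c(1, 0, 1, 0), c(AB, Ab, aB, ab)))
}

# random unphased two-locus sample of n diploids drawn from haplotype
# frequencies implied by (pA, pB, pAB)
random_two_locus <- function(n, pA, pB, pAB) {
  p4 <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
  stopifnot(all(p4 >= 0))
  z1 <- sample.int(4, n, replace = TRUE, prob = p4)
  z2 <- sample.int(4, n, replace = TRUE, prob = p4)
  a1 <- as.integer(z1 %in% c(1, 2)); b1 <- as.integer(z1 %in% c(1, 3))
  a2 <- as.integer(z2 %in% c(1, 2)); b2 <- as.integer(z2 %in% c(1, 3))
  list(g1 = a1 + a2, g2 = b1 + b2)
}

# grid-search likelihood oracle for the EM fit: maximizes the multinomial
# likelihood over pAB with allele frequencies at their sample values
# (coarse pass then a fine local refinement)
grid_r2_oracle <- function(g1, g2, step = 1e-4, fine = 1e-7) {
  fA <- mean(g1) / 2; fB <- mean(g2) / 2
  lo <- max(0, fA + fB - 1); hi <- min(fA, fB)
  ll_of <- function(x) vapply(x, function(p)
    genotype_loglik(g1, g2, c(p, fA - p, fB - p, 1 - fA - fB + p)), numeric(1))
  grid <- seq(lo, hi, by = step)
  best <- grid[which.max(ll_of(grid))]
  grid2 <- seq(max(lo, best - 2 * step), min(hi, best + 2 * step), by = fine)
  ll2 <- ll_of(grid2)
  pAB <- grid2[which.max(ll2)]
  D <- pAB - fA * fB
  denom <- fA * (1 - fA) * fB * (1 - fB)
  list(pAB = pAB, r2 = D^2 / denom, loglik = max(ll2))
}

# brute-force AUC: concordant-pair counting with half-credit ties
brute_auc <- function(scores, y) {
  cs <- scores[y == 1]; ct <- scores[y == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

table4_tables <- function() {
  ext <- system.file("extdata", package = "snprisk")
  list(cases = read_reclass_counts(file.path(ext, "table4_reclass_cases.csv"), "cases"),
       controls = read_reclass_counts(file.path(ext, "table4_reclass_controls.csv"), "controls"))
}
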