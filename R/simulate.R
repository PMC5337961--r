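# Deterministic synthetic-data generators: LD-blocked haplotype panels,
# additive-logit case/control cohorts, and a regulatory landscape (histone
# marks with controlled overlap, planted motif-disruption sites, TF->target
# edges, expression tables) with known ground truth.
#
# Every generator is a pure function of the configuration, seed included:
# each one seeds the RNG from cfg$seed (plus a fixed per-generator offset so
# the three stages draw independent streams) and restores the caller's RNG
# state on exit.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic generators. Cohort
#' defaults mirror a typical GWAS case/control study of just under 2000 cases
#' and 3000 controls.
#'
#' @param seed Mandatory integer seed; all generator output is a pure function
#'   of the configuration including this seed.
#' @param n_cases,n_controls Cohort quotas (defaults 1989 / 3000).
#' @param n_snps Number of panel SNPs.
#' @param block_len SNPs per LD block (blocks are independent of each other).
#' @param mutation_prob Per-site founder-copy mutation probability inside a
#'   block; 0 gives r-squared 1 within blocks, larger values decay LD.
#' @param freq Target allele frequencies of the coded allele, recycled over
#'   blocks (all in (0, 1)).
#' @param or_per_snp Per-allele odds ratios, recycled over SNPs (all > 0).
#' @param intercept Baseline log-odds of disease.
#' @param panel_haplotypes Number of chromosome copies in the panel (even).
#' @param spacing_bp Distance between adjacent panel SNPs (bp).
#' @param n_true,n_decoy_nomotif,n_decoy_unexpressed,n_outside_mark Landscape
#'   composition: SNPs planted to pass all three regulatory conditions; in-mark
#'   SNPs whose context disrupts no motif strongly; in-mark SNPs with a strong
#'   disruption of a TF whose targets are not expressed; SNPs with a strong
#'   disruption but outside every mark.
#' @param pwm_width Width of planted motifs (>= 5).
#' @param pwm_conc Dirichlet concentration of background (non-planted) motif
#'   columns; smaller values give higher information content.
#' @param n_background_pwms Extra random motifs without target-gene edges.
#' @param marks,tissues Histone mark and tissue names for the landscape.
#' @param mark_n,mark_len Intervals per mark and interval length (bp).
#' @param mark_overlap Fraction of each non-reference mark's intervals placed
#'   on intervals of the first mark (pairwise overlap control, in [0, 1]).
#' @param n_genes,expressed_fraction Expression-table size and the fraction of
#'   free genes with FPKM > 1.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = 1989, n_controls = 3000,
                       n_snps = 20, block_len = 5, mutation_prob = 0.02,
                       freq = c(0.2, 0.3, 0.4, 0.5),
                       or_per_snp = 1, intercept = -0.5,
                       panel_haplotypes = 2000, spacing_bp = 500,
                       n_true = 3, n_decoy_nomotif = 4,
                       n_decoy_unexpressed = 2, n_outside_mark = 2,
                       pwm_width = 7, pwm_conc = 1, n_background_pwms = 2,
                       marks = c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3"),
                       tissues = c("islet", "pancreas"),
                       mark_n = 12, mark_len = 400, mark_overlap = 0.5,
                       n_genes = 60, expressed_fraction = 0.5) {
  if (missing(seed)) stop_("a seed is mandatory")
  if (any(freq <= 0 | freq >= 1)) stop_("allele frequencies must lie in (0, 1)")
  if (any(or_per_snp <= 0)) stop_("odds ratios must be > 0")
  if (mutation_prob < 0 || mutation_prob >= 0.5)
    stop_("mutation_prob must lie in [0, 0.5)")
  if (mark_overlap < 0 || mark_overlap > 1)
    stop_("mark_overlap must lie in [0, 1]: impossible overlap geometry")
  if (expressed_fraction < 0 || expressed_fraction > 1)
    stop_("expressed_fraction must lie in [0, 1]")
  if (pwm_width < 5) stop_("pwm_width must be >= 5 (two anchor columns)")
  if (panel_haplotypes %% 2 != 0) stop_("panel_haplotypes must be even")
  if (n_outside_mark > 0 && n_true == 0)
    stop_("n_outside_mark > 0 requires at least one true planted motif")
  cfg <- list(seed = as.integer(seed), n_cases = n_cases, n_controls = n_controls,
              n_snps = n_snps, block_len = block_len,
              mutation_prob = mutation_prob, freq = freq,
              or_per_snp = or_per_snp, intercept = intercept,
              panel_haplotypes = panel_haplotypes, spacing_bp = spacing_bp,
              n_true = n_true, n_decoy_nomotif = n_decoy_nomotif,
              n_decoy_unexpressed = n_decoy_unexpressed,
              n_outside_mark = n_outside_mark,
              pwm_width = pwm_width, pwm_conc = pwm_conc,
              n_background_pwms = n_background_pwms,
              marks = marks, tissues = tissues, mark_n = mark_n,
              mark_len = mark_len, mark_overlap = mark_overlap,
              n_genes = n_genes, expressed_fraction = expressed_fraction)
  class(cfg) <- "sim_config"
  cfg
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Simulate an LD-blocked haplotype panel
#'
#' Haplotypes are generated blockwise: within a block every haplotype copies a
#' biallelic block founder (carrier with probability tuned so that the
#' post-mutation allele frequency hits the block's target) and each site then
#' mutates independently with `mutation_prob`. Blocks are mutually
#' independent, so r-squared is high within blocks (exactly 1 when
#' `mutation_prob = 0`) and zero in expectation across blocks.
#'
#' @param cfg A [sim_config()].
#' @return A [haplotype_panel()].
#' @export
simulate_haplotype_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_snps
    H <- cfg$panel_haplotypes
    n_blocks <- ceiling(m / cfg$block_len)
    targets <- rep_len(cfg$freq, n_blocks)
    mu <- cfg$mutation_prob
    h <- matrix(0L, H, m)
    for (b in seq_len(n_blocks)) {
      cols <- ((b - 1) * cfg$block_len + 1):min(b * cfg$block_len, m)
      # founder-carrier probability giving the target frequency after mutation
      f <- (targets[b] - mu) / (1 - 2 * mu)
      f <- min(max(f, 0.01), 0.99)
      z <- rbinom(H, 1, f)
      for (j in cols) {
        flip <- rbinom(H, 1, mu)
        h[, j] <- as.integer(xor(z, flip))
      }
    }
    refalt <- t(vapply(seq_len(m), function(j) sample(BASES, 2), character(2)))
    variants <- variant_table(chrom = "chr1",
                              pos = 10000 + (seq_len(m) - 1) * cfg$spacing_bp,
                              id = sprintf("snp%04d", seq_len(m)),
                              ref = refalt[, 1], alt = refalt[, 2])
    haplotype_panel(h, variants)
  })
}

#' Simulate a case/control cohort from a haplotype panel
#'
#' Individuals are formed by random pairing of panel haplotypes (sampling with
#' replacement); disease status is Bernoulli with probability
#' `plogis(intercept + sum(log(OR_s) * g_s))` over the additive genotype
#' codes. Rejection sampling continues until both the case and control quotas
#' are met, with a hard cap of 1e7 draws.
#'
#' @param panel A [haplotype_panel()].
#' @param cfg The [sim_config()] (its `or_per_snp` is recycled over panel
#'   SNPs).
#' @return A [genotype_matrix()] with `n_cases + n_controls` samples.
#' @export
simulate_case_control <- function(panel, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- nrow(panel$variants)
  beta <- log(rep_len(cfg$or_per_snp, m))
  H <- nrow(panel$haplotypes)
  with_seed(cfg$seed + 1L, {
    # feasibility check on the expected case rate at typical genotypes
    gbar <- 2 * colMeans(panel$haplotypes)
    p_typical <- stats::plogis(cfg$intercept + sum(beta * gbar))
    if (p_typical < 1e-4)
      stop_("expected case rate %.2g < 1e-4: cases unreachable with this intercept",
            p_typical)
    cases <- list(); ctrls <- list()
    n_case <- 0L; n_ctrl <- 0L
    drawn <- 0L
    batch <- 5000L
    while ((n_case < cfg$n_cases || n_ctrl < cfg$n_controls) && drawn < 1e7) {
      i1 <- sample.int(H, batch, replace = TRUE)
      i2 <- sample.int(H, batch, replace = TRUE)
      g <- panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE]
      p <- stats::plogis(cfg$intercept + as.vector(g %*% beta))
      is_case <- runif(batch) < p
      drawn <- drawn + batch
      need_case <- cfg$n_cases - n_case
      if (need_case > 0 && any(is_case)) {
        take <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
        cases[[length(cases) + 1L]] <- g[take, , drop = FALSE]
        n_case <- n_case + length(take)
      }
      need_ctrl <- cfg$n_controls - n_ctrl
      if (need_ctrl > 0 && any(!is_case)) {
        take <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
        ctrls[[length(ctrls) + 1L]] <- g[take, , drop = FALSE]
        n_ctrl <- n_ctrl + length(take)
      }
    }
    if (n_case < cfg$n_cases || n_ctrl < cfg$n_controls)
      stop_("draw cap (1e7) reached before filling quotas (%d/%d cases, %d/%d controls)",
            n_case, cfg$n_cases, n_ctrl, cfg$n_controls)
    codes <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
    rownames(codes) <- sprintf("S%05d", seq_len(nrow(codes)))
    genotype_matrix(codes, panel$variants,
                    c(rep("case", cfg$n_cases), rep("control", cfg$n_controls)))
  })
}

# random background PWM: Dirichlet(conc) columns; smaller conc -> sharper
# columns (higher information content)
random_pwm <- function(name, width, conc) {
  probs <- vapply(seq_len(width), function(j) {
    g <- stats::rgamma(4, shape = conc)
    g / sum(g)
  }, numeric(4))
  pwm(name, probs)
}

# planted motif: two near-deterministic anchor columns over a near-uniform
# background. Anchor 1 (consensus 'A') sits at the column the SNP aligns to;
# anchor 2 ('C' for TFs with expressed targets, 'G' for decoy TFs) sits two
# columns right and keeps motifs of the two TF classes from matching each
# other's planted sites.
planted_pwm <- function(name, width, anchor2_base) {
  a1 <- ceiling(width / 2)
  a2 <- a1 + 2
  probs <- vapply(seq_len(width), function(j) {
    p <- 0.25 + runif(4, -0.01, 0.01)
    p / sum(p)
  }, numeric(4))
  sharp <- function(base) {
    p <- rep(0.01, 4)
    p[match(base, BASES)] <- 0.97
    p
  }
  probs[, a1] <- sharp("A")
  probs[, a2] <- sharp(anchor2_base)
  # keep the background consensus two columns left of anchor 1 away from 'G':
  # it lands at genomic position SNP-2 in planted contexts, where a 'G' would
  # let another planted motif's minus-strand anchor pair line up by accident
  lean <- probs[, a1 - 2]
  ord <- order(lean, decreasing = TRUE)
  if (BASES[ord[1]] == "G") {
    lean[ord[1:2]] <- lean[ord[2:1]]
    probs[, a1 - 2] <- lean
  }
  list(pwm = pwm(name, probs), anchor1 = a1)
}

consensus_seq <- function(p) BASES[apply(p$probs, 2, which.max)]

# context of length 2w-1 with the SNP at the center, carrying the motif
# consensus aligned so the SNP sits on anchor column a1
planted_context <- function(p, a1) {
  w <- pwm_width(p)
  ctx <- sample(BASES, 2 * w - 1, replace = TRUE)
  start <- w - a1 + 1
  ctx[start:(start + w - 1)] <- consensus_seq(p)
  list(context = paste(ctx, collapse = ""), snp_pos = w,
       ref = "A", alt = "T")   # anchor1 consensus vs its rarest competitor
}

random_context <- function(w) {
  ctx <- sample(BASES, 2 * w - 1, replace = TRUE)
  # C/G alleles never match the planted anchor-1 consensus ('A', or 'T' read
  # from the minus strand); fixing SNP-2 and SNP+2 to 'C' also rules out a
  # chance anchor-pair alignment through the SNP sitting on anchor 2
  ctx[w] <- "C"
  ctx[w - 2] <- "C"
  ctx[w + 2] <- "C"
  list(context = paste(ctx, collapse = ""), snp_pos = w, ref = "C", alt = "G")
}

#' Simulate a regulatory landscape with planted ground truth
#'
#' Generates histone-mark intervals for two tissues with controlled pairwise
#' overlap, planted transcription-factor motifs, SNP sequence contexts,
#' TF-to-target edges and a per-tissue expression table, such that the
#' three-condition regulatory prioritization has a known answer:
#'
#' * `n_true` SNPs lie in marks, their contexts carry a planted consensus
#'   whose alternate allele destroys the high-information anchor column
#'   (a strong, matched disruption by construction), and the disrupted TF
#'   targets an expressed gene — these and only these should be returned;
#' * `n_decoy_nomotif` SNPs lie in marks but disrupt nothing strongly;
#' * `n_decoy_unexpressed` SNPs lie in marks with a strong disruption of a TF
#'   whose only target is kept below the expression floor in every tissue;
#' * `n_outside_mark` SNPs carry a strong disruption of an expressed-target TF
#'   but sit outside every mark interval.
#'
#' Background motifs (no target edges) and free genes fill out the landscape.
#'
#' @param cfg A [sim_config()].
#' @return List with `variants`, `contexts`, `pwms`, `tf_targets`, `marks`
#'   ([genomic_intervals()]), `expression`, `truth` (ids of the planted true
#'   SNPs), and `classes` (per-SNP planted class).
#' @export
simulate_regulatory_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 2L, {
    w <- cfg$pwm_width
    n_true <- cfg$n_true; n_unexp <- cfg$n_decoy_unexpressed
    n_nomot <- cfg$n_decoy_nomotif; n_out <- cfg$n_outside_mark
    n_snp <- n_true + n_unexp + n_nomot + n_out
    classes <- c(rep("true", n_true), rep("decoy_unexpressed", n_unexp),
                 rep("decoy_nomotif", n_nomot), rep("outside_mark", n_out))

    # motifs: one expressed-target TF per true SNP, one decoy TF per
    # unexpressed decoy, plus untargeted background motifs
    pwms <- list(); anchors <- list()
    for (i in seq_len(n_true)) {
      p <- planted_pwm(sprintf("TF_true%02d", i), w, "C")
      pwms[[p$pwm$name]] <- p$pwm; anchors[[p$pwm$name]] <- p$anchor1
    }
    for (i in seq_len(n_unexp)) {
      p <- planted_pwm(sprintf("TF_unexpr%02d", i), w, "G")
      pwms[[p$pwm$name]] <- p$pwm; anchors[[p$pwm$name]] <- p$anchor1
    }
    for (i in seq_len(cfg$n_background_pwms)) {
      p <- random_pwm(sprintf("TF_bg%02d", i), w, cfg$pwm_conc)
      pwms[[p$name]] <- p
    }

    # SNP contexts per planted class
    ctx <- vector("list", n_snp)
    k <- 0
    for (i in seq_len(n_true)) {
      nm <- sprintf("TF_true%02d", i)
      k <- k + 1; ctx[[k]] <- planted_context(pwms[[nm]], anchors[[nm]])
    }
    for (i in seq_len(n_unexp)) {
      nm <- sprintf("TF_unexpr%02d", i)
      k <- k + 1; ctx[[k]] <- planted_context(pwms[[nm]], anchors[[nm]])
    }
    for (i in seq_len(n_nomot)) { k <- k + 1; ctx[[k]] <- random_context(w) }
    for (i in seq_len(n_out)) {
      nm <- sprintf("TF_true%02d", 1 + (i - 1) %% n_true)
      k <- k + 1; ctx[[k]] <- planted_context(pwms[[nm]], anchors[[nm]])
    }

    pos <- 50000 + (seq_len(n_snp) - 1) * 2000
    ids <- sprintf("rs%05d", seq_len(n_snp))
    variants <- variant_table(rep("chr1", n_snp), pos, ids,
                              vapply(ctx, `[[`, character(1), "ref"),
                              vapply(ctx, `[[`, character(1), "alt"))
    contexts <- data.frame(id = ids,
                           context = vapply(ctx, `[[`, character(1), "context"),
                           snp_pos = vapply(ctx, `[[`, numeric(1), "snp_pos"),
                           ref = variants$ref, alt = variants$alt,
                           stringsAsFactors = FALSE)

    # mark intervals: cover every in-mark SNP with the first two marks in each
    # tissue, then scatter intervals with the configured pairwise overlap
    in_mark_pos <- pos[classes != "outside_mark"]
    rows <- list()
    far <- 2e6   # scatter region, disjoint from the SNPs
    for (ti in cfg$tissues) {
      anchor_starts <- far + seq_len(cfg$mark_n) * (4 * cfg$mark_len)
      for (mi in seq_along(cfg$marks)) {
        mk <- cfg$marks[mi]
        starts <- if (mi == 1) anchor_starts else {
          reuse <- runif(cfg$mark_n) < cfg$mark_overlap
          fresh <- far + cfg$mark_n * 8 * cfg$mark_len +
            (mi * cfg$mark_n + seq_len(cfg$mark_n)) * (4 * cfg$mark_len)
          ifelse(reuse, sample(anchor_starts, cfg$mark_n, replace = TRUE), fresh)
        }
        rows[[length(rows) + 1L]] <- genomic_intervals(
          "chr1", starts, starts + cfg$mark_len, label = mk, tissue = ti)
        if (mi <= 2 && length(in_mark_pos)) {
          rows[[length(rows) + 1L]] <- genomic_intervals(
            "chr1", in_mark_pos - 50, in_mark_pos + 50, label = mk, tissue = ti)
        }
      }
    }
    marks <- do.call(rbind, rows)
    class(marks) <- c("genomic_intervals", "data.frame")

    # expression: one expressed target per true TF, one suppressed target per
    # decoy TF, free genes expressed with the configured fraction
    gene_true <- sprintf("GENE_T%02d", seq_len(n_true))
    gene_unexp <- sprintf("GENE_U%02d", seq_len(n_unexp))
    n_free <- max(cfg$n_genes - n_true - n_unexp, 0)
    gene_free <- sprintf("GENE_F%03d", seq_len(n_free))
    expr <- list()
    for (ti in cfg$tissues) {
      on <- runif(n_free) < cfg$expressed_fraction
      expr[[ti]] <- data.frame(
        gene = c(gene_true, gene_unexp, gene_free),
        tissue = ti,
        fpkm = c(1 + stats::rexp(n_true, 0.5),
                 runif(n_unexp, 0, 0.9),
                 ifelse(on, 1 + stats::rexp(n_free, 0.5), runif(n_free, 0, 1))),
        stringsAsFactors = FALSE)
    }
    expression <- do.call(rbind, expr)
    rownames(expression) <- NULL

    tf_targets <- rbind(
      data.frame(tf = sprintf("TF_true%02d", seq_len(n_true)),
                 gene = gene_true, stringsAsFactors = FALSE),
      data.frame(tf = sprintf("TF_unexpr%02d", seq_len(n_unexp)),
                 gene = gene_unexp, stringsAsFactors = FALSE))
    for (nm in names(pwms))
      pwms[[nm]]$target_genes <- tf_targets$gene[tf_targets$tf == nm]

    list(variants = variants, contexts = contexts, pwms = pwms,
         tf_targets = tf_targets, marks = marks, expression = expression,
         truth = ids[classes == "true"], classes = setNames(classes, ids),
         cfg = cfg)
  })
}
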