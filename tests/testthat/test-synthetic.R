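test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, freq = 1.2), "frequencies")
  expect_error(sim_config(seed = 1, or_per_snp = -2), "odds ratios")
  expect_error(sim_config(seed = 1, mark_overlap = 1.5), "overlap")
  expect_error(sim_config(seed = 1, pwm_width = 4), "pwm_width")
})

test_that("generators are deterministic functions of the configuration", {
  cfg <- sim_config(seed = 55, n_snps = 10, panel_haplotypes = 100,
                    n_cases = 30, n_controls = 40)
  p1 <- simulate_haplotype_panel(cfg)
  p2 <- simulate_haplotype_panel(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  f1 <- file.path(tempdir(), "p1.vcf"); f2 <- file.path(tempdir(), "p2.vcf")
  write_vcf(p1, f1); write_vcf(p2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical emission
  g1 <- simulate_case_control(p1, cfg)
  g2 <- simulate_case_control(p2, cfg)
  expect_identical(g1$codes, g2$codes)
  L1 <- simulate_regulatory_landscape(cfg)
  L2 <- simulate_regulatory_landscape(cfg)
  expect_identical(L1$contexts, L2$contexts)
  expect_identical(L1$expression, L2$expression)
})

test_that("zero mutation probability gives r2 = 1 within blocks", {
  cfg <- sim_config(seed = 8, n_snps = 6, block_len = 3, mutation_prob = 0,
                    panel_haplotypes = 200)
  panel <- simulate_haplotype_panel(cfg)
  h <- panel$haplotypes
  for (pair in list(c(1, 2), c(2, 3), c(4, 5), c(5, 6))) {
    hf <- haplotype_freqs_phased(h[, pair[1]], h[, pair[2]])
    expect_equal(hf$r2, 1)
  }
})

test_that("panel allele frequencies hit their targets at 2n = 10000", {
  cfg <- sim_config(seed = 12, n_snps = 8, block_len = 2,
                    freq = c(0.2, 0.3, 0.4, 0.5), mutation_prob = 0.02,
                    panel_haplotypes = 10000)
  panel <- simulate_haplotype_panel(cfg)
  freqs <- colMeans(panel$haplotypes)
  targets <- rep(rep(c(0.2, 0.3, 0.4, 0.5), length.out = 4), each = 2)
  expect_true(all(abs(freqs - targets) < 0.03))
})

test_that("null cohorts have matched allele frequencies across groups", {
  cfg <- sim_config(seed = 21, n_snps = 6, or_per_snp = 1,
                    n_cases = 500, n_controls = 500, panel_haplotypes = 1000)
  panel <- simulate_haplotype_panel(cfg)
  gm <- simulate_case_control(panel, cfg)
  f_case <- colMeans(gm$codes[gm$phenotype == "case", ]) / 2
  f_ctrl <- colMeans(gm$codes[gm$phenotype == "control", ]) / 2
  expect_true(all(abs(f_case - f_ctrl) < 0.06))
})

test_that("an unreachable case rate is a configuration error", {
  cfg <- sim_config(seed = 2, n_snps = 4, intercept = -30,
                    n_cases = 10, n_controls = 10, panel_haplotypes = 100)
  panel <- simulate_haplotype_panel(cfg)
  expect_error(simulate_case_control(panel, cfg), "case rate")
})

test_that("planted consensus sites give matched, positive-diff disruptions", {
  L <- simulate_regulatory_landscape(sim_config(seed = 33))
  for (i in seq_along(L$truth)) {
    id <- L$truth[i]
    row <- L$contexts[L$contexts$id == id, ]
    p <- L$pwms[[sprintf("TF_true%02d", i)]]
    r <- score_allele_disruption(p, row$context, row$snp_pos, row$ref, row$alt)
    expect_true(r$matched)
    expect_equal(r$score_ref, 1)
    expect_gt(r$allele_diff, 0.4)
  }
})

test_that("zero mark overlap yields zero off-diagonal co-occurrence in the scatter", {
  cfg <- sim_config(seed = 44, mark_overlap = 0, n_true = 0,
                    n_decoy_nomotif = 0, n_decoy_unexpressed = 0,
                    n_outside_mark = 0)
  L <- simulate_regulatory_landscape(cfg)
  # probe SNPs at every scatter-interval midpoint
  mk <- L$marks[L$marks$tissue == "islet", ]
  mid <- floor((mk$start + mk$end) / 2) + 1
  v <- variant_table("chr1", mid, sprintf("probe%03d", seq_along(mid)),
                     "A", "G")
  ann <- classify_region(v, marks = L$marks)
  cm <- unclass(mark_cooccurrence(ann, "islet"))
  expect_true(all(cm[upper.tri(cm)] == 0))
  expect_true(all(diag(cm) > 0))
})

test_that("expressed fraction of free genes follows the configured binomial", {
  cfg <- sim_config(seed = 66, n_genes = 1000, expressed_fraction = 0.5,
                    n_true = 0, n_decoy_unexpressed = 0,
                    n_decoy_nomotif = 1, n_outside_mark = 0)
  L <- simulate_regulatory_landscape(cfg)
  n_exp <- length(expressed_genes(L$expression, "islet"))
  expect_true(abs(n_exp - 500) <= 40)
})

test_that("end-to-end pipeline recovers exactly the planted regulatory SNPs", {
  for (s in c(3, 14, 159)) {
    L <- simulate_regulatory_landscape(sim_config(seed = s))
    ann <- classify_region(L$variants, marks = L$marks)
    dis <- suppressMessages(scan_motif_disruptions(L$contexts, L$pwms))
    expr <- union(expressed_genes(L$expression, "islet"),
                  expressed_genes(L$expression, "pancreas"))
    got <- suppressMessages(
      prioritize_regulatory(ann, dis, L$tf_targets, expr))$id
    expect_setequal(got, L$truth)
  }
})
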