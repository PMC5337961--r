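test_that("the >=1-damaging rule flags exactly the six suspected missense SNPs", {
  tab <- read_predictor_calls(
    system.file("extdata", "table1_missense_calls.tsv", package = "snprisk"))
  expect_equal(nrow(tab), 17)
  flagged <- flag_damaging_missense(tab)
  expect_setequal(flagged, c("rs2228603", "rs58542926", "rs17240268",
                             "rs13266634", "rs1260326", "rs1051334"))
})

test_that("damaging rule edge cases: all tolerated, NA handling, bad vocabulary", {
  base <- data.frame(snp = "s1", gene = "g", aa_change = "A1B",
                     sift = "Tolerated", polyphen2 = "benign",
                     provean = "Tolerated", fathmm = "Tolerated",
                     stringsAsFactors = FALSE)
  expect_length(flag_damaging_missense(base), 0)
  three_na <- base
  three_na[, c("sift", "polyphen2", "provean")] <- NA
  three_na$fathmm <- "Damaging"
  expect_equal(flag_damaging_missense(three_na), "s1")
  all_na <- base; all_na[, 4:7] <- NA
  expect_length(flag_damaging_missense(all_na), 0)
  bad <- base; bad$sift <- "sketchy"
  expect_error(flag_damaging_missense(bad), "s1")
})

test_that("expressed-gene rule is strictly greater than the FPKM floor", {
  expr <- data.frame(gene = c("g1", "g2", "g3"), tissue = "islet",
                     fpkm = c(1.5, 1.0, 0.2))
  expect_identical(expressed_genes(expr, "islet", 1), "g1")
  expect_error(expressed_genes(expr, "liver"), "absent")
  expect_length(expressed_genes(expr[0, ], "islet"), 0)
  expect_setequal(expressed_genes(expr, "islet", 0.1), c("g1", "g2", "g3"))
})

toy_prior_inputs <- function() {
  v <- variant_table("chr1", c(100, 200, 300), c("sA", "sB", "sC"),
                     rep("A", 3), rep("G", 3))
  marks <- genomic_intervals("chr1", 0, 250, "H3K4me1", "islet")  # covers sA, sB
  ann <- classify_region(v, marks = marks)
  dis <- data.frame(
    id = c("sA", "sB", "sC"), motif = c("TF1", "TF2", "TF1"), strand = "+",
    offset = 0, score_ref = 1, score_alt = c(0.4, 0.4, 0.4),
    allele_diff = 0.6, matched = TRUE, effect = "weak",
    stringsAsFactors = FALSE)
  tf <- data.frame(tf = c("TF1", "TF2"), gene = c("GEXP", "GOFF"),
                   stringsAsFactors = FALSE)
  list(ann = ann, dis = dis, tf = tf)
}

test_that("three-condition regulatory prioritization retains the all-conditions SNP", {
  x <- toy_prior_inputs()
  out <- prioritize_regulatory(x$ann, x$dis, x$tf, expressed = "GEXP")
  # sA: in mark + strong TF1 + TF1 targets expressed GEXP
  # sB: in mark + strong TF2 but GOFF not expressed; sC: not in any mark
  expect_identical(out$id, "sA")
  expect_true(all(out$cond_mark_motif & out$cond_strong & out$cond_expressed_target))
  expect_equal(out$genes, "GEXP")

  # expressed target below the floor -> excluded
  out2 <- prioritize_regulatory(x$ann, x$dis, x$tf, expressed = character())
  expect_equal(nrow(out2), 0)
  # empty disruptions -> empty set
  out3 <- prioritize_regulatory(x$ann, x$dis[0, ], x$tf, expressed = "GEXP")
  expect_equal(nrow(out3), 0)
  # TF missing from the edge list is logged, not an error
  expect_message(
    prioritize_regulatory(x$ann, x$dis, x$tf[x$tf$tf != "TF2", ], "GEXP"),
    "TF2")
})

test_that("regulatory set shrinks as thresholds tighten and audits its conditions", {
  for (s in 1:3) {
    L <- simulate_regulatory_landscape(sim_config(seed = 200 + s))
    ann <- classify_region(L$variants, marks = L$marks)
    dis <- suppressMessages(scan_motif_disruptions(L$contexts, L$pwms))
    expr <- expressed_genes(L$expression, "islet")
    base <- suppressMessages(prioritize_regulatory(ann, dis, L$tf_targets, expr))
    tighter <- suppressMessages(
      prioritize_regulatory(ann, dis, L$tf_targets, expr, effect_thresh = 0.6))
    expect_true(all(tighter$id %in% base$id))
    # output is a subset of SNPs overlapping at least one mark
    expect_true(all(base$id %in% unique(ann$marks$id)))
    # audit: re-evaluate each condition independently
    strong <- filter_strong(dis, 0.4)
    for (id in base$id) {
      expect_true(id %in% unique(ann$marks$id))
      expect_true(any(dis$matched[dis$id == id]))
      tfs <- strong$motif[strong$id == id]
      expect_true(length(intersect(
        L$tf_targets$gene[L$tf_targets$tf %in% tfs], expr)) > 0)
    }
  }
})

test_that("TSS prioritization requires a listed gene and a strong disruption", {
  v <- variant_table("chr1", c(100, 200, 300), c("tssA", "tssB", "free"),
                     rep("A", 3), rep("G", 3))
  tss <- rbind(genomic_intervals("chr1", 50, 150, "WFS1"),
               genomic_intervals("chr1", 150, 250, "NOGENE"))
  ann <- classify_region(v, tss = tss)
  dis <- data.frame(
    id = c("tssA", "tssB", "free"), motif = "TF1", strand = "+", offset = 0,
    score_ref = 1, score_alt = 0.4, allele_diff = 0.6, matched = TRUE,
    effect = "weak", stringsAsFactors = FALSE)
  out <- prioritize_tss(ann, dis)
  expect_identical(out$id, "tssA")          # WFS1 is on the curated list
  expect_equal(out$tss_genes, "WFS1")
  # strong disruption but outside any TSS window -> excluded from this stratum
  expect_false("free" %in% out$id)
  # no strong disruption -> excluded
  dis0 <- dis; dis0$matched <- FALSE
  expect_equal(nrow(prioritize_tss(ann, dis0)), 0)
})

test_that("the packaged curated gene list matches its fixture file", {
  f <- system.file("extdata", "t2d_genes.txt", package = "snprisk")
  expect_setequal(readLines(f), t2d_gene_list())
})
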