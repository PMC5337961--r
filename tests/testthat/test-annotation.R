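test_that("TSS windows span +/- flank with boundary and truncation rules", {
  tss <- data.frame(gene = c("G1", "G2"), chrom = "chr1",
                    pos = c(10000, 500), strand = "+")
  win <- suppressMessages(build_tss_windows(tss, flank_bp = 2000))
  # 1-based closed 8000..12000 -> BED [7999, 12000)
  expect_true(pos_in_interval(8000, win$start[1], win$end[1]))
  expect_false(pos_in_interval(7999, win$start[1], win$end[1]))
  expect_true(pos_in_interval(12000, win$start[1], win$end[1]))
  expect_false(pos_in_interval(12001, win$start[1], win$end[1]))
  # truncation at position 1
  expect_equal(win$start[2], 0)
  expect_true(pos_in_interval(1, win$start[2], win$end[2]))
  expect_true(pos_in_interval(2500, win$start[2], win$end[2]))
  expect_message(build_tss_windows(tss, 2000), "truncated")
})

make_ann_inputs <- function() {
  v <- variant_table("chr1", c(150, 5000, 9000, 99999), sprintf("s%d", 1:4),
                     rep("A", 4), rep("G", 4))
  exons <- genomic_intervals("chr1", 100, 200, "exon1")
  utrs <- genomic_intervals("chr1", 120, 260, "utr1")
  tss <- genomic_intervals("chr1", 4000, 6000, "GENEX")
  marks <- rbind(
    genomic_intervals("chr1", 8900, 9100, "H3K4me3", "pancreas"),
    genomic_intervals("chr1", 8800, 9200, "H3K4me1", "pancreas"),
    genomic_intervals("chr1", 4500, 5500, "H3K27ac", "islet"))
  list(v = v, exons = exons, utrs = utrs, tss = tss, marks = marks)
}

test_that("region classification assigns all applicable flags", {
  x <- make_ann_inputs()
  ann <- suppressMessages(
    classify_region(x$v, x$exons, x$utrs, x$tss, x$marks))
  a <- ann$variants
  expect_true(a$in_coding_exon[1])
  expect_false(a$in_utr[1])      # coding takes precedence over the UTR overlap
  expect_true(a$in_tss[2])
  expect_equal(a$tss_genes[[2]], "GENEX")
  # multi-membership: s2 in TSS and in an islet mark
  expect_true("s2" %in% ann$marks$id[ann$marks$tissue == "islet"])
  expect_setequal(ann$marks$mark[ann$marks$id == "s3"], c("H3K4me3", "H3K4me1"))
  # chromosome absent from every interval set -> all-false flags
  expect_false(any(a$in_coding_exon[4], a$in_utr[4], a$in_tss[4]))
  expect_equal(unname(ann$summary[["coding_exon"]]), 1)
})

test_that("classification is order-independent and empty input gives empty output", {
  x <- make_ann_inputs()
  a1 <- suppressMessages(classify_region(x$v, x$exons, x$utrs, x$tss, x$marks))
  perm <- c(3, 1, 4, 2)
  a2 <- suppressMessages(
    classify_region(x$v[perm, ], x$exons, x$utrs, x$tss, x$marks[c(3, 1, 2), ]))
  v2 <- a2$variants[match(a1$variants$id, a2$variants$id), ]
  expect_equal(v2$in_coding_exon, a1$variants$in_coding_exon)
  expect_equal(v2$in_tss, a1$variants$in_tss)
  m1 <- a1$marks[order(a1$marks$id, a1$marks$mark, a1$marks$tissue), ]
  m2 <- a2$marks[order(a2$marks$id, a2$marks$mark, a2$marks$tissue), ]
  expect_equal(unname(as.matrix(m1)), unname(as.matrix(m2)))

  empty <- classify_region(x$v[0, ], x$exons, x$utrs, x$tss, x$marks)
  expect_equal(nrow(empty$variants), 0)
})

test_that("mark co-occurrence counts SNPs in pairwise mark overlaps", {
  # 3 SNPs in H3K4me1, 2 of which also in H3K27ac
  v <- variant_table("chr1", c(100, 200, 300), c("a", "b", "c"),
                     rep("A", 3), rep("G", 3))
  marks <- rbind(
    genomic_intervals("chr1", 0, 1000, "H3K4me1", "islet"),
    genomic_intervals("chr1", 50, 250, "H3K27ac", "islet"),
    genomic_intervals("chr1", 60, 110, "H3K27ac", "islet"))  # duplicate cover of 'a'
  ann <- classify_region(v, marks = marks)
  cm <- mark_cooccurrence(ann, "islet")
  expect_equal(cm["H3K4me1", "H3K4me1"], 3L)
  expect_equal(cm["H3K27ac", "H3K27ac"], 2L)
  expect_equal(cm["H3K4me1", "H3K27ac"], 2L)  # once per SNP despite 2 intervals
  expect_identical(unclass(cm)[, ], t(unclass(cm)[, ]))
  expect_error(mark_cooccurrence(ann, "liver"), "available")
})

test_that("co-occurrence symmetry and diagonal dominance hold on random landscapes", {
  for (s in 1:5) {
    L <- simulate_regulatory_landscape(sim_config(seed = 100 + s))
    ann <- classify_region(L$variants, marks = L$marks)
    for (ti in c("islet", "pancreas")) {
      cm <- unclass(mark_cooccurrence(ann, ti))
      expect_identical(cm, t(cm))
      for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm)))
        expect_lte(cm[i, j], min(cm[i, i], cm[j, j]))
      # diagonal equals per-mark SNP counts from the annotation
      m <- ann$marks[ann$marks$tissue == ti, ]
      for (mk in rownames(cm))
        expect_equal(cm[mk, mk], length(unique(m$id[m$mark == mk])))
    }
  }
})

test_that("tissue intersection requires >= min_marks in both tissues", {
  v <- variant_table("chr1", c(100, 200, 300), c("both", "one", "none"),
                     rep("A", 3), rep("G", 3))
  iv <- function(lo, hi, mk, ti) genomic_intervals("chr1", lo, hi, mk, ti)
  marks <- rbind(
    iv(0, 150, "m1", "islet"), iv(0, 150, "m2", "islet"),
    iv(0, 150, "m1", "pancreas"), iv(0, 150, "m2", "pancreas"),
    iv(150, 250, "m1", "islet"), iv(150, 250, "m2", "islet"),
    iv(150, 250, "m1", "pancreas"),
    iv(250, 350, "m1", "islet"))
  ann <- classify_region(v, marks = marks)
  hit <- tissue_intersection(ann, c("islet", "pancreas"))
  expect_identical(hit, "both")   # 'one' has a single pancreas mark, 'none' islet only
  # subset property
  expect_true(all(hit %in% overlapped_snps(ann, "islet", 2)))
  expect_true(all(hit %in% overlapped_snps(ann, "pancreas", 2)))
  expect_error(tissue_intersection(ann, "islet"), "two tissues")
  # disjoint memberships -> empty
  marks2 <- rbind(iv(0, 150, "m1", "islet"), iv(0, 150, "m2", "islet"))
  ann2 <- classify_region(v, marks = marks2)
  expect_error(tissue_intersection(ann2, c("islet", "pancreas")), "unknown tissue")
})
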