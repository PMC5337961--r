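test_that("risk alleles follow the higher-frequency-in-cases rule", {
  # 5 cases, 5 controls; v1 alt enriched in cases, v2 alt enriched in controls,
  # v3 tied, v4 monomorphic
  codes <- cbind(
    v1 = c(2, 2, 1, 1, 0, 1, 0, 0, 1, 0),
    v2 = c(0, 1, 0, 0, 1, 2, 1, 1, 2, 0),
    v3 = c(1, 1, 0, 2, 0, 1, 1, 0, 2, 0),
    v4 = rep(0, 10))
  gm <- toy_gm(codes, rep(c("case", "control"), each = 5))
  rm <- suppressWarnings(suppressMessages(assign_risk_alleles(gm)))
  expect_equal(rm$risk_allele[rm$id == "v01"], "alt")
  expect_equal(rm$risk_allele[rm$id == "v02"], "ref")
  expect_equal(rm$status[rm$id == "v03"], "tie")
  expect_equal(rm$status[rm$id == "v04"], "monomorphic")
  # control risk-allele frequency for the flipped SNP counts the ref allele
  expect_equal(rm$control_risk_freq[rm$id == "v02"], 1 - mean(codes[6:10, "v2"]) / 2)
})

test_that("genotype score sums risk alleles with mean imputation of missing calls", {
  codes <- cbind(v1 = c(2, 0), v2 = c(1, 0), v3 = c(0, NA))
  gm <- toy_gm(codes, c("case", "control"))
  rm <- data.frame(id = c("v01", "v02", "v03"), risk_allele = "alt",
                   control_risk_freq = c(0.5, 0.5, 0.3), status = "ok",
                   stringsAsFactors = FALSE)
  sc <- genotype_score(gm, rm)
  expect_equal(unname(sc["S01"]), 3)        # counts (2,1,0)
  expect_equal(unname(sc["S02"]), 0.6)      # 0 + 0 + imputed 2 x 0.3
  expect_true(all(sc >= 0 & sc <= 2 * 3))
  # all-missing sample dropped with a warning
  codes2 <- cbind(v1 = c(2, NA), v2 = c(1, NA), v3 = c(0, NA))
  gm2 <- toy_gm(codes2, c("case", "control"))
  expect_warning(sc2 <- genotype_score(gm2, rm), "all scored genotypes missing")
  expect_length(sc2, 1)
  expect_error(genotype_score(gm, rm[0, ], ), "no scorable")
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  x <- rep(c(1, 0, 1, 0), c(60, 40, 40, 60))
  y <- rep(c(1, 1, 0, 0), c(60, 40, 40, 60))
  fit <- fit_logistic(data.frame(x = x), y)
  expect_equal(fit$coefficients$or[2], (60 * 60) / (40 * 40), tolerance = 1e-6)
  # balanced table -> OR 1; independent x -> p near 1
  xb <- rep(c(1, 0, 1, 0), c(50, 50, 50, 50))
  fb <- fit_logistic(data.frame(x = xb), y)
  expect_equal(fb$coefficients$or[2], 1, tolerance = 1e-8)
  expect_gt(fb$coefficients$p[2], 0.95)
  # CI straddles the point estimate
  expect_true(fit$coefficients$or_lo[2] < fit$coefficients$or[2])
  expect_true(fit$coefficients$or_hi[2] > fit$coefficients$or[2])
  expect_lte(fit$loglik, 0)
})

test_that("logistic fits match random 2x2 cross-product odds ratios", {
  set.seed(3)
  for (i in 1:20) {
    n <- matrix(sample(20:100, 4), 2)   # cells: case x1/x0, control x1/x0
    x <- rep(c(1, 0, 1, 0), c(n[1, 1], n[1, 2], n[2, 1], n[2, 2]))
    y <- rep(c(1, 1, 0, 0), c(n[1, 1], n[1, 2], n[2, 1], n[2, 2]))
    fit <- fit_logistic(data.frame(x = x), y)
    or <- (n[1, 1] * n[2, 2]) / (n[1, 2] * n[2, 1])
    expect_equal(fit$coefficients$or[2], or, tolerance = 1e-6)
  }
})

test_that("degenerate logistic designs raise informative errors", {
  y <- rep(c(1, 0), each = 10)
  expect_error(fit_logistic(data.frame(x = rep(1, 20)), y), "constant")
  expect_error(fit_logistic(data.frame(x = y), y), "separation")
})

test_that("likelihood-ratio test matches the chi-square oracle", {
  set.seed(7)
  n <- 400
  x1 <- rbinom(n, 2, 0.3); x2 <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x1))
  nested <- fit_logistic(data.frame(x1 = x1), y)
  full <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
  lt <- lr_test(nested, full)
  expect_equal(lt$df, 1)
  expect_equal(lt$statistic, 2 * (full$loglik - nested$loglik))
  expect_equal(lt$p, pchisq(lt$statistic, 1, lower.tail = FALSE))
  # df = 1, statistic 3.841 -> p = 0.05 (quantile oracle)
  expect_equal(pchisq(qchisq(0.95, 1), 1, lower.tail = FALSE), 0.05)
  expect_equal(round(qchisq(0.95, 1), 3), 3.841)
  # full = nested -> statistic 0, p 1
  lt0 <- lr_test(nested, nested)
  expect_equal(lt0$statistic, 0)
  expect_equal(lt0$p, 1)
})

test_that("null predictors give approximately uniform LR-test p-values", {
  set.seed(19)
  ps <- replicate(40, {
    n <- 150
    x1 <- rbinom(n, 2, 0.3); noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + 0.4 * x1))
    lr_test(fit_logistic(data.frame(x1 = x1), y),
            fit_logistic(data.frame(x1 = x1, z = noise), y))$p
  })
  expect_gt(mean(ps < 0.5), 0.25)   # loose uniformity checks
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("pooled CV AUC matches brute-force concordant-pair counting", {
  # worked toy example: cases {0.9, 0.4}, controls {0.8, 0.1}
  expect_equal(auc_mann_whitney(c(0.9, 0.4, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)     # separated
  expect_equal(auc_mann_whitney(rep(3, 6), rep(c(1, 0), 3)), 0.5)     # all tied
  set.seed(13)
  for (i in 1:10) {
    n <- 60
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mann_whitney(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("cv_auc pools out-of-fold probabilities and is seed-reproducible", {
  set.seed(101)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  a <- cv_auc(x, y, k = 5, seed = 42)
  b <- cv_auc(x, y, k = 5, seed = 42)
  expect_identical(a$auc, b$auc)
  expect_equal(a$auc, auc_mann_whitney(a$probs, y), tolerance = 1e-12)
  expect_equal(brute_auc(a$probs, y), a$auc, tolerance = 1e-12)
  expect_true(a$auc > 0.5)
  expect_error(cv_auc(x, y, k = 5), "seed")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(23)
  s <- rnorm(80); y <- rbinom(80, 1, 0.5)
  a <- auc_mann_whitney(s, y)
  expect_equal(auc_mann_whitney(exp(s), y), a)
  expect_equal(auc_mann_whitney(3 * s + 7, y), a)
  expect_equal(auc_mann_whitney(rank(s), y), a)
})

test_that("Welch separation test matches the closed form and its edge cases", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  r <- score_separation_test(c(a, b), c(1, 1, 1, 0, 0, 0))
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(r$statistic, (mean(a) - mean(b)) / se)
  # identical distributions -> t = 0, p = 1
  r0 <- score_separation_test(c(a, a), c(1, 1, 1, 0, 0, 0))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # extreme separation -> p near 0
  r1 <- score_separation_test(c(a, a + 100), c(0, 0, 0, 1, 1, 1))
  expect_lt(r1$p, 1e-6)
  expect_error(score_separation_test(rep(1, 6), c(1, 1, 1, 0, 0, 0)),
               "zero variance")
})
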