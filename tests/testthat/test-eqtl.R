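make_scan_fixture <- function(n = 120, n_snps = 4, n_genes = 6, seed = 1,
                              n_cov = 2) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n))
  dosage <- matrix(rbinom(n_snps * n, 2, 0.3), n_snps, n,
                   dimnames = list(paste0("snp", seq_len(n_snps)), samples))
  covs <- matrix(rnorm(n * n_cov), n, n_cov,
                 dimnames = list(samples, paste0("c", seq_len(n_cov))))
  em <- matrix(rnorm(n_genes * n), n_genes, n,
               dimnames = list(paste0("g", seq_len(n_genes)), samples))
  em[1, ] <- em[1, ] + 0.5 * dosage[1, ] + 0.3 * covs[, 1]
  list(dosage = dosage, em = em, covs = covs)
}

test_that("snp_qc applies every filter with per-SNP reasons", {
  set.seed(2)
  d <- matrix(rbinom(4 * 200, 2, rep(c(0.005, 0.3, 0.3, 0.3), 200)),
              4, 200, dimnames = list(paste0("snp", 1:4), NULL))
  d[2, 1:10] <- NA                      # call rate 0.95
  r2 <- c(snp1 = 0.9, snp2 = 0.9, snp3 = 0.1, snp4 = 0.9)
  out <- snp_qc(d, r2 = r2)
  expect_identical(out$report$kept, c(FALSE, FALSE, FALSE, TRUE))
  expect_match(out$report$fail_reasons[1], "maf")
  expect_match(out$report$fail_reasons[2], "call_rate")
  expect_match(out$report$fail_reasons[3], "imputation_r2")
  expect_identical(rownames(out$dosage), "snp4")
})

test_that("HWE chi-square matches the closed-form oracle", {
  expect_equal(hwe_pvalue(c(25, 50, 25)), 1)  # exact equilibrium: X2 = 0
  counts <- c(40, 20, 40)
  n <- 100; p <- 0.5
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((counts - expd)^2 / expd)
  expect_equal(hwe_pvalue(counts), pchisq(x2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(hwe_pvalue(counts), 1e-5)   # this SNP fails QC
  gc <- rbind(snpA = c(25, 50, 25), snpB = c(40, 20, 40))
  d <- matrix(rbinom(2 * 200, 2, 0.5), 2, 200,
              dimnames = list(c("snpA", "snpB"), NULL))
  out <- snp_qc(d, genotype_counts = gc)
  expect_identical(out$report$kept, c(TRUE, FALSE))
})

test_that("an exact linear relation is recovered exactly", {
  set.seed(3)
  dosage <- matrix(rbinom(60, 2, 0.4), 1, 60,
                   dimnames = list("snp1", paste0("s", 1:60)))
  em <- matrix(2 * dosage[1, ], 1, 60,
               dimnames = list("g1", colnames(dosage)))
  rec <- fit_eqtl(dosage, em)
  expect_equal(rec$beta, 2, tolerance = 1e-10)
  expect_lt(rec$se, 1e-8)
})

test_that("fit_eqtl equals lm() on every pair (normal-equations oracle)", {
  fx <- make_scan_fixture(seed = 4)
  rec <- fit_eqtl(fx$dosage, fx$em, covariates = fx$covs)
  for (i in sample(nrow(rec), 10)) {
    r <- rec[i, ]
    fit <- lm(fx$em[r$gene, ] ~ fx$dosage[r$snp, ] + fx$covs)
    cf <- summary(fit)$coefficients[2, ]
    expect_equal(r$beta, unname(cf["Estimate"]), tolerance = 1e-10)
    expect_equal(r$se, unname(cf["Std. Error"]), tolerance = 1e-10)
    expect_equal(r$p, unname(cf["Pr(>|t|)"]), tolerance = 1e-10)
  }
  expect_error(fit_eqtl(fx$dosage[, 1:10], fx$em[, 1:10]), "at least 30")
  expect_error(fit_eqtl(fx$dosage, fx$em,
                        covariates = cbind(fx$covs, fx$covs[, 1])),
               "full rank")
})

test_that("null pairs give calibrated type-I error and uniform p", {
  set.seed(5)
  n <- 150
  dosage <- matrix(rbinom(60 * n, 2, 0.25), 60, n,
                   dimnames = list(paste0("snp", 1:60), paste0("s", 1:n)))
  em <- matrix(rnorm(60 * n), 60, n,
               dimnames = list(paste0("g", 1:60), paste0("s", 1:n)))
  rec <- fit_eqtl(dosage, em)            # 3600 independent null pairs
  rate <- mean(rec$p < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  expect_gt(ks.test(rec$p, "punif")$p.value, 1e-4)
})

test_that("a simulated trans effect is recovered with correct power", {
  # beta = 0.4, MAF 0.2, n = 300, noise SD 1: the dosage effect should be
  # estimated within 3 SE
  set.seed(6)
  n <- 300
  g <- rbinom(n, 2, 0.2)
  y <- 0.4 * g + rnorm(n)
  dosage <- matrix(g, 1, n, dimnames = list("snp1", paste0("s", 1:n)))
  em <- matrix(y, 1, n, dimnames = list("g1", colnames(dosage)))
  rec <- fit_eqtl(dosage, em)
  expect_lt(abs(rec$beta - 0.4), 3 * rec$se)
})

test_that("cis/trans classification honours the inclusive 1-Mb window", {
  gene <- data.frame(id = "g", chrom = "chr1", start = 5e6, end = 5.002e6)
  snp_at <- function(chrom, pos)
    data.frame(id = "s", chrom = chrom, start = pos, end = pos)
  expect_identical(classify_cis_trans(snp_at("chr1", 5e6 - 1e6), gene), "cis")
  expect_identical(classify_cis_trans(snp_at("chr1", 5e6 - 1e6 - 1), gene),
                   "trans")
  expect_identical(classify_cis_trans(snp_at("chr1", 5.002e6 + 1e6), gene),
                   "cis")
  expect_identical(classify_cis_trans(snp_at("chr2", 5e6), gene), "trans")
  expect_identical(classify_cis_trans(snp_at(NA, 5e6), gene), "unclassified")

  # brute force over random placements
  set.seed(7)
  genes <- data.frame(id = paste0("g", 1:20), chrom = paste0("chr", 1:4),
                      start = round(runif(20, 1, 2e8)))
  genes$end <- genes$start + 2000
  snps <- data.frame(id = paste0("s", 1:1000),
                     chrom = sample(paste0("chr", 1:4), 1000, TRUE),
                     start = round(runif(1000, 1, 2e8)))
  snps$end <- snps$start
  gi <- sample(20, 1000, TRUE)
  got <- classify_cis_trans(snps, genes[gi, ])
  want <- vapply(seq_len(1000), function(i) {
    g <- genes[gi[i], ]
    if (snps$chrom[i] == g$chrom &&
        snps$start[i] >= g$start - 1e6 && snps$start[i] <= g$end + 1e6)
      "cis" else "trans"
  }, character(1))
  expect_identical(got, want)
})

test_that("conditional scan removes mediated signals, keeps independent ones", {
  set.seed(8)
  n <- 300
  causal <- rbinom(n, 2, 0.3)
  # correlated proxy with pairwise r^2 about 0.55
  proxy <- ifelse(runif(n) < 0.75, causal, rbinom(n, 2, 0.3))
  indep <- rbinom(n, 2, 0.3)
  samples <- paste0("s", 1:n)
  dosage <- rbind(causal = causal, proxy = proxy, indep = indep)
  colnames(dosage) <- samples

  p_cond <- beta_raw <- beta_cond_indep <- se_raw <- numeric(0)
  for (rep in 1:10) {
    y <- 0.4 * causal + rnorm(n)
    em <- matrix(y, 1, n, dimnames = list("g1", samples))
    raw <- fit_eqtl(dosage["proxy", , drop = FALSE], em)
    cond <- conditional_scan(dosage, em, lead_snp = "proxy",
                             conditioning_snp = "causal")
    p_cond <- c(p_cond, cond$p)
    ci <- conditional_scan(dosage, em, lead_snp = "proxy",
                           conditioning_snp = "indep")
    beta_raw <- c(beta_raw, raw$beta)
    se_raw <- c(se_raw, raw$se)
    beta_cond_indep <- c(beta_cond_indep, ci$beta)
  }
  expect_gte(mean(p_cond > 0.05), 0.9)
  expect_true(all(abs(beta_cond_indep - beta_raw) < se_raw))

  em <- matrix(rnorm(n), 1, n, dimnames = list("g1", samples))
  dup <- rbind(dosage, causal2 = causal)
  colnames(dup) <- samples
  expect_warning(cc <- conditional_scan(dup, em, lead_snp = "causal",
                                        conditioning_snp = "causal2"),
                 "collinear")
  expect_true(cc$collinear)
  expect_true(is.na(cc$beta))
})

test_that("trans_set_enrichment reproduces the 2x2 bookkeeping and Fisher p", {
  # 28 target genes of which 15 hit, 7862 background of which 1833 hit
  rec <- data.frame(gene = paste0("g", 1:7890),
                    p = c(rep(0.001, 15), rep(0.5, 13),
                          rep(0.001, 1833), rep(0.5, 7862 - 1833)))
  res <- trans_set_enrichment(rec, paste0("g", 1:28), p_cut = 0.01)
  expect_identical(unname(res$table[1, ]), c(15L, 13L))
  expect_identical(unname(res$table[2, ]), c(1833L, 6029L))
  expect_equal(unname(res$proportions["target"]), 15 / 28)
  expect_equal(unname(res$proportions["background"]), 1833 / 7862)
  expect_equal(res$p, oracle_fisher(res$table), tolerance = 1e-10)
  expect_equal(res$p, 5.2e-4, tolerance = 0.01)  # the published comparison

  # equal proportions give odds ratio 1
  rec2 <- data.frame(gene = paste0("g", 1:100),
                     p = rep(c(0.001, 0.5), 50))
  res2 <- trans_set_enrichment(rec2, paste0("g", 1:10), p_cut = 0.01)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)

  # extreme table reaches the minimal attainable tail
  rec3 <- data.frame(gene = paste0("g", 1:30),
                     p = c(rep(1e-4, 5), rep(0.9, 25)))
  res3 <- trans_set_enrichment(rec3, paste0("g", 1:5), p_cut = 0.01)
  expect_equal(res3$p, 1 / choose(30, 5), tolerance = 1e-12)
  expect_error(trans_set_enrichment(rec3, character(0)), "empty")
})

test_that("a module-level trans SNP hits a majority of module genes", {
  # the per-gene effect of a trans SNP acting on the module eigengene is
  # loading * beta; at beta = 0.4, MAF 0.2, n = 300 the noncentrality is
  # 3.92 * loading, so a majority of genes reach p < 0.01 only when
  # loadings are moderately strong — hence [0.5, 0.9] here
  st <- generate_paired_study(sim_config(
    n_genes = 500, module_sizes = c(120, 80),
    preserved_flags = c(TRUE, FALSE), loading_range = c(0.5, 0.9),
    n_samples_ref = 300, n_samples_test = 40,
    n_snps = 10, maf_range = c(0.2, 0.2),
    trans_effect = list(snp_index = 3, module_index = 1, beta = 0.4),
    covariate_spec = NULL, seed = 21))
  rec <- fit_eqtl(st$dosage, st$ref_expr)
  mod_genes <- names(st$truth$module)[st$truth$module == 1]
  hit <- rec[rec$snp == "snp003", ]
  rownames(hit) <- hit$gene
  expect_gt(mean(hit[mod_genes, "p"] < 0.01), 0.5)
  enr <- trans_set_enrichment(hit, mod_genes, p_cut = 0.01)
  expect_lt(enr$p, 0.01)
})

test_that("eQTL scan classifies and flags records end to end", {
  st <- generate_paired_study(sim_config(
    n_genes = 60, module_sizes = 20, preserved_flags = TRUE,
    n_samples_ref = 200, n_samples_test = 30, n_snps = 6,
    cis_effects = list(list(snp_index = 1, gene_index = 5, beta = 0.8)),
    covariate_spec = list(n_covariates = 2, effect_sds = 0.1), seed = 10))
  rec <- fit_eqtl(st$dosage, st$ref_expr, covariates = st$covariates,
                  snp_positions = st$snp_positions,
                  gene_positions = st$gene_positions)
  hit <- rec[rec$snp == "snp001" & rec$gene == "RG0005", ]
  expect_identical(hit$class, "cis")
  expect_lt(hit$p, 1e-6)
  expect_lt(abs(hit$beta - 0.8), 3 * hit$se)
})
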