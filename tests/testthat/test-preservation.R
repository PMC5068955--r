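paired_fix <- function(seed = 1, preserved = c(TRUE, FALSE)) {
  generate_paired_study(sim_config(
    n_genes = 400, module_sizes = c(80, 60), preserved_flags = preserved,
    loading_range = c(0.5, 0.9), n_samples_ref = 150, n_samples_test = 80,
    covariate_spec = NULL, seed = seed))
}

test_that("projection onto identical data reproduces the reference kME", {
  fix <- make_block_expr(c(30, 25), n_background = 25, n_samples = 40,
                         loading = 0.8, seed = 2)
  ms_ref <- module_summary(fix$expr, fix$labels)
  ms_copy <- project_assignment(fix$expr, fix$labels)
  expect_equal(ms_copy$kme, ms_ref$kme, tolerance = 1e-10)
})

test_that("preserved modules keep kME structure, non-preserved do not", {
  cors_pres <- cors_null <- numeric(0)
  for (s in 1:5) {
    st <- paired_fix(seed = s)
    ma <- st$truth$module
    ms_ref <- module_summary(st$ref_expr, ma)
    ms_test <- project_assignment(st$test_expr, ma, pairs = st$ortholog_map)
    g1 <- names(ma)[ma == 1]; g2 <- names(ma)[ma == 2]
    cors_pres <- c(cors_pres, cor(ms_ref$kme[g1, "1"], ms_test$kme[g1, "1"]))
    cors_null <- c(cors_null, cor(ms_ref$kme[g2, "2"], ms_test$kme[g2, "2"]))
  }
  expect_true(all(cors_pres > 0.5))
  # null correlations scatter around zero
  expect_lt(abs(mean(cors_null)), 2 * sd(cors_null) / sqrt(5) + 0.15)
})

test_that("consistency_fraction trivial identities and zero handling", {
  k <- setNames(c(0.5, -0.3, 0.2, -0.8), paste0("g", 1:4))
  expect_equal(consistency_fraction(k, k)$fraction, 1)
  expect_equal(consistency_fraction(k, -k)$fraction, 0)
  kz <- k; kz["g1"] <- 0
  expect_equal(consistency_fraction(kz, kz)$fraction, 0.75)  # zeros inconsistent
  expect_error(consistency_fraction(k, k, genes = character(0)), "empty")
})

test_that("random-sign consistency lands in the binomial band", {
  set.seed(5)
  n_univ <- 2000; size <- 200
  a <- setNames(rnorm(n_univ), paste0("g", seq_len(n_univ)))
  b <- setNames(rnorm(n_univ), names(a))
  p_match <- mean(sign(a) == sign(b))       # genome-wide sign table
  genes <- sample(names(a), size)
  cf <- consistency_fraction(a, b, genes)
  band <- qbinom(c(0.005, 0.995), size, p_match) / size
  expect_gte(cf$fraction, band[1])
  expect_lte(cf$fraction, band[2])
})

test_that("permutation p-value matches the exact hypergeometric tail", {
  # universe of 1000 genes, 600 concordant; a module of 50 fully
  # concordant genes. Under label permutation the random module's
  # concordant count is Hypergeom(N = 1000, K = 600, n = 50), so
  # p = P[X > 49] up to Monte-Carlo error.
  n_univ <- 1000; n_conc <- 600; size <- 50
  sgn_ref <- setNames(rep(1, n_univ), paste0("g", seq_len(n_univ)))
  sgn_test <- sgn_ref
  sgn_test[(n_conc + 1):n_univ] <- -1
  labels <- setNames(rep(0L, n_univ), names(sgn_ref))
  labels[1:size] <- 1L                       # all concordant by construction
  res <- permutation_pvalue(sgn_ref, sgn_test, labels, n_perm = 10000,
                            seed = 42)
  expect_equal(res$fraction, 1)
  # a fully-consistent module can never be strictly exceeded, so the
  # distributional check needs a non-saturated module:
  labels2 <- labels
  labels2[1:size] <- 0L
  labels2[c(1:40, 601:610)] <- 1L            # 40 of 50 concordant
  res2 <- permutation_pvalue(sgn_ref, sgn_test, labels2, n_perm = 10000,
                             seed = 42)
  expect_equal(res2$fraction, 0.8)
  p_or <- oracle_hyper_tail(41, n_conc, n_univ, 50)
  mc_sd <- sqrt(p_or * (1 - p_or) / 10000)
  expect_lt(abs(res2$p - p_or), 3 * mc_sd)
  # fully-consistent module: no random module can strictly exceed it
  expect_equal(res$p, 0)
  expect_match(res$p_note, "< 1e-04")
})

test_that("an observed fraction below the universe rate gives p near 1", {
  set.seed(8)
  n_univ <- 500
  sgn_ref <- setNames(sample(c(-1, 1), n_univ, TRUE), paste0("g", 1:n_univ))
  sgn_test <- sgn_ref                         # universe fully concordant
  sgn_test[1:60] <- -sgn_ref[1:60]            # except the module
  labels <- setNames(rep(0L, n_univ), names(sgn_ref))
  labels[1:60] <- 1L
  res <- permutation_pvalue(sgn_ref, sgn_test, labels, n_perm = 2000, seed = 1)
  expect_gt(res$p, 0.99)
})

test_that("permutation test is deterministic and smoothing behaves", {
  set.seed(3)
  sgn_a <- setNames(sample(c(-1, 1), 300, TRUE), paste0("g", 1:300))
  sgn_b <- setNames(sample(c(-1, 1), 300, TRUE), names(sgn_a))
  labels <- setNames(rep(0L, 300), names(sgn_a)); labels[1:50] <- 1L
  r1 <- permutation_pvalue(sgn_a, sgn_b, labels, n_perm = 500, seed = 7)
  r2 <- permutation_pvalue(sgn_a, sgn_b, labels, n_perm = 500, seed = 7)
  expect_identical(r1, r2)
  rs <- permutation_pvalue(sgn_a, sgn_b, labels, n_perm = 500, seed = 7,
                           smooth = TRUE)
  expect_equal(rs$p, (1 + r1$p * 500) / 501, tolerance = 1e-12)
  expect_warning(permutation_pvalue(sgn_a, sgn_b, labels, n_perm = 50,
                                    seed = 1), "coarse")
})

test_that("joint negation of both species' kME leaves fractions unchanged", {
  st <- paired_fix(seed = 3)
  ma <- st$truth$module
  ms_ref <- module_summary(st$ref_expr, ma)
  ms_test <- project_assignment(st$test_expr, ma, pairs = st$ortholog_map)
  g <- names(ma)[ma == 1]
  a <- ms_ref$kme[g, "1"]; b <- ms_test$kme[g, "1"]
  expect_identical(consistency_fraction(a, b)$fraction,
                   consistency_fraction(-a, -b)$fraction)
})

test_that("preservation_report flags planted preserved modules only", {
  st <- paired_fix(seed = 4)
  ma <- st$truth$module
  ms_ref <- module_summary(st$ref_expr, ma)
  ms_test <- project_assignment(st$test_expr, ma, pairs = st$ortholog_map)
  pres <- preservation_report(ms_ref, ms_test, ma, n_perm = 2000, seed = 4)
  expect_identical(pres$preserved, c(TRUE, FALSE))
  expect_gt(pres$fraction[1], pres$fraction[2])
})

test_that("composite statistics separate preserved from non-preserved", {
  st <- paired_fix(seed = 6)
  ma <- st$truth$module
  test_aligned <- st$test_expr
  rownames(test_aligned) <- st$ortholog_map$ref_gene
  # self-preservation: test data = copy of ref -> huge Z
  comp_self <- composite_preservation(st$ref_expr, st$ref_expr, ma,
                                      n_perm = 50, seed = 1)
  expect_gt(comp_self$z_summary[comp_self$module == 1], 10)
  comp <- composite_preservation(st$ref_expr, test_aligned, ma,
                                 n_perm = 50, seed = 1)
  z1 <- comp$z_summary[comp$module == 1]
  z2 <- comp$z_summary[comp$module == 2]
  expect_gt(z1, z2)
  expect_lt(abs(z2), 3)
  expect_identical(comp$median_rank[comp$module == 1], 1)
})
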