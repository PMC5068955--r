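#' Configuration for a synthetic paired-species study
#'
#' The generator plants a latent-factor module structure shared between a
#' large "reference" expression panel and a smaller "test" panel (emulating
#' a human cohort of several hundred macrophage samples paired with a few
#' dozen inbred mouse strains). Each module m has a latent eigengene signal
#' e_m; member gene g is lambda_g * e_m + sqrt(1 - lambda_g^2) * noise.
#' Preserved modules reuse the same loadings (same signs) in the test
#' species with fresh latent signals; non-preserved modules become pure
#' noise there. Optional genetic effects add beta * dosage either to a
#' module eigengene (trans) or to single genes (cis).
#'
#' @param n_genes number of orthologous genes.
#' @param n_samples_ref,n_samples_test panel sizes.
#' @param module_sizes integer vector of planted module sizes.
#' @param preserved_flags logical vector, one per module; NULL (default)
#'   marks the first 60% of modules preserved (rounded up), i.e. 6 of the
#'   default 10.
#' @param loading_range interval in (0, 1] for per-gene loadings.
#' @param noise_sd residual SD.
#' @param n_probes_per_gene length-2 integer range; each gene gets a
#'   uniform number of probes in this range.
#' @param n_outlier_samples extra reference samples offset on every gene.
#' @param outlier_offset offset in units of expression SD (default 8).
#' @param n_snps number of simulated SNPs.
#' @param maf_range minor-allele-frequency interval.
#' @param dosage_blur if TRUE, add uniform noise in [-0.2, 0.2] to hard
#'   genotypes (clipped to [0, 2]) to emulate imputation; off by default.
#' @param trans_effect NULL or list(snp_index, module_index, beta): dosage
#'   effect on a module eigengene in the reference panel.
#' @param cis_effects list of list(snp_index, gene_index, beta): per-gene
#'   dosage effects in the reference panel.
#' @param covariate_spec list(n_covariates, effect_sds): standard-normal
#'   covariates added to all genes with N(0, effect_sd) coefficients.
#' @param flip_fraction fraction of a preserved module's loadings whose
#'   sign is flipped in the test species (partial-preservation knob).
#' @param seed integer seed; the whole study is deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_ref = 300,
                       n_samples_test = 80,
                       module_sizes = c(250, 200, 180, 150, 120, 100, 90, 80, 70, 60),
                       preserved_flags = NULL,
                       loading_range = c(0.3, 0.9),
                       noise_sd = 1,
                       n_probes_per_gene = c(1L, 3L),
                       n_outlier_samples = 0L,
                       outlier_offset = 8,
                       n_snps = 20L,
                       maf_range = c(0.05, 0.5),
                       dosage_blur = FALSE,
                       trans_effect = NULL,
                       cis_effects = list(),
                       covariate_spec = list(n_covariates = 2L, effect_sds = 0.1),
                       flip_fraction = 0,
                       seed = 1L) {
  if (is.null(preserved_flags)) {
    preserved_flags <- rep(FALSE, length(module_sizes))
    preserved_flags[seq_len(ceiling(0.6 * length(module_sizes)))] <- TRUE
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_ref = as.integer(n_samples_ref),
              n_samples_test = as.integer(n_samples_test),
              module_sizes = as.integer(module_sizes),
              preserved_flags = as.logical(preserved_flags),
              loading_range = as.numeric(loading_range),
              noise_sd = as.numeric(noise_sd),
              n_probes_per_gene = as.integer(n_probes_per_gene),
              n_outlier_samples = as.integer(n_outlier_samples),
              outlier_offset = as.numeric(outlier_offset),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              dosage_blur = isTRUE(dosage_blur),
              trans_effect = trans_effect,
              cis_effects = cis_effects,
              covariate_spec = covariate_spec,
              flip_fraction = as.numeric(flip_fraction),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (length(cfg$preserved_flags) != length(cfg$module_sizes))
    stop("preserved_flags must match module_sizes in length")
  if (any(cfg$module_sizes < 2L))
    stop("module sizes must be at least 2")
  if (cfg$loading_range[1] <= 0 || cfg$loading_range[2] > 1 ||
      cfg$loading_range[1] > cfg$loading_range[2])
    stop("loading_range must lie in (0, 1]")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must lie in (0, 0.5]")
  if (!is.null(cfg$trans_effect)) {
    if (cfg$trans_effect$module_index > length(cfg$module_sizes))
      stop("trans_effect module index out of range")
    if (cfg$trans_effect$snp_index > cfg$n_snps)
      stop("trans_effect snp index out of range")
  }
  for (ce in cfg$cis_effects) {
    if (ce$gene_index > cfg$n_genes) stop("cis_effect gene index out of range")
    if (ce$snp_index > cfg$n_snps) stop("cis_effect snp index out of range")
  }
  invisible(cfg)
}

# Genes laid on 20 chromosomes, 1 Mb apart, 2 kb long; cis SNPs sit 50 kb
# from their target gene's start, other SNPs at random gene-free offsets.
sim_positions <- function(cfg) {
  n <- cfg$n_genes
  chrom <- paste0("chr", ((seq_len(n) - 1L) %/% ceiling(n / 20)) + 1L)
  start <- ((seq_len(n) - 1L) %% ceiling(n / 20)) * 1e6 + 1e5
  gene_pos <- data.frame(id = sprintf("RG%04d", seq_len(n)),
                         chrom = chrom, start = start, end = start + 2e3,
                         stringsAsFactors = FALSE)
  snp_id <- sprintf("snp%03d", seq_len(cfg$n_snps))
  snp_chrom <- sample(unique(chrom), cfg$n_snps, replace = TRUE)
  snp_pos <- round(stats::runif(cfg$n_snps, 1, max(start) + 2e6))
  for (ce in cfg$cis_effects) {
    snp_chrom[ce$snp_index] <- gene_pos$chrom[ce$gene_index]
    snp_pos[ce$snp_index] <- gene_pos$start[ce$gene_index] + 5e4
  }
  if (!is.null(cfg$trans_effect)) {
    # place the trans SNP on its own far coordinate
    i <- cfg$trans_effect$snp_index
    snp_chrom[i] <- "chr21"
    snp_pos[i] <- 5e7
  }
  list(genes = gene_pos,
       snps = data.frame(id = snp_id, chrom = snp_chrom,
                         start = snp_pos, end = snp_pos,
                         stringsAsFactors = FALSE))
}

#' Generate a synthetic paired-species coexpression study
#'
#' @param config a [sim_config()].
#' @return list with components `ref_probes`, `test_probes` (each a list
#'   of `intensity` probe x sample matrix and `probe2gene` map),
#'   `ref_expr`, `test_expr` (gene-level matrices, pre-probe convenience),
#'   `ortholog_map`, `dosage` (SNP x reference-sample matrix), `maf`,
#'   `gene_positions`, `snp_positions`, `covariates`
#'   (reference-sample x covariate matrix), and `truth` (gene -> module
#'   map, preserved flags, loadings, eQTL truth, outlier sample IDs).
#' @export
generate_paired_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  n_ref <- config$n_samples_ref + config$n_outlier_samples
  n_test <- config$n_samples_test
  k <- length(config$module_sizes)

  ref_genes <- sprintf("RG%04d", seq_len(n))
  test_genes <- sprintf("TG%04d", seq_len(n))
  ref_samples <- sprintf("H%03d", seq_len(n_ref))
  test_samples <- sprintf("M%03d", seq_len(n_test))

  module <- integer(n)
  idx <- 1L
  for (m in seq_len(k)) {
    module[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }

  loading <- numeric(n)
  in_mod <- module > 0L
  loading[in_mod] <- stats::runif(sum(in_mod), config$loading_range[1],
                                  config$loading_range[2])

  # dosages, shared design: reference samples get genotypes
  maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(stats::rbinom(config$n_snps * n_ref, 2L, rep(maf, n_ref)),
                   nrow = config$n_snps)
  if (config$dosage_blur) {
    dosage <- dosage + stats::runif(length(dosage), -0.2, 0.2)
    dosage <- pmin(pmax(dosage, 0), 2)
  }

  # latent eigengene signals (reference)
  E_ref <- matrix(stats::rnorm(k * n_ref), k, n_ref)
  if (!is.null(config$trans_effect)) {
    te <- config$trans_effect
    E_ref[te$module_index, ] <- E_ref[te$module_index, ] +
      te$beta * dosage[te$snp_index, ]
  }

  make_panel <- function(E, n_samp, loadings) {
    X <- matrix(stats::rnorm(n * n_samp, sd = config$noise_sd), n, n_samp)
    for (m in seq_len(k)) {
      g <- which(module == m)
      lam <- loadings[g]
      X[g, ] <- lam %o% E[m, ] +
        sqrt(1 - lam^2) * matrix(stats::rnorm(length(g) * n_samp,
                                              sd = config$noise_sd),
                                 length(g), n_samp)
    }
    X
  }

  ref <- make_panel(E_ref, n_ref, loading)
  for (ce in config$cis_effects) {
    ref[ce$gene_index, ] <- ref[ce$gene_index, ] +
      ce$beta * dosage[ce$snp_index, ]
  }

  # covariates added linearly to all reference genes
  cs <- config$covariate_spec
  n_cov <- if (is.null(cs)) 0L else as.integer(cs$n_covariates)
  covariates <- NULL
  if (n_cov > 0L) {
    covariates <- matrix(stats::rnorm(n_ref * n_cov), n_ref, n_cov,
                         dimnames = list(ref_samples,
                                         paste0("cov", seq_len(n_cov))))
    effect_sds <- rep_len(cs$effect_sds, n_cov)
    coefs <- matrix(stats::rnorm(n * n_cov, sd = rep(effect_sds, each = n)),
                    n, n_cov)
    ref <- ref + coefs %*% t(covariates)
  }

  # outlier samples: constant offset on all genes (appended last)
  outlier_ids <- character(0)
  if (config$n_outlier_samples > 0L) {
    o <- (config$n_samples_ref + 1L):n_ref
    ref[, o] <- ref[, o] + config$outlier_offset * config$noise_sd
    outlier_ids <- ref_samples[o]
  }

  # test species: preserved modules reuse loadings (optionally sign-flipped
  # in a fraction of genes), non-preserved modules collapse to noise
  test_loading <- loading
  for (m in seq_len(k)) {
    g <- which(module == m)
    if (!config$preserved_flags[m]) {
      test_loading[g] <- 0
    } else if (config$flip_fraction > 0) {
      nf <- round(config$flip_fraction * length(g))
      if (nf > 0) {
        f <- sample(g, nf)
        test_loading[f] <- -test_loading[f]
      }
    }
  }
  E_test <- matrix(stats::rnorm(k * n_test), k, n_test)
  test <- make_panel(E_test, n_test, abs(test_loading))
  neg <- which(test_loading < 0)
  if (length(neg)) # flipping the whole row flips the structured part; the
    test[neg, ] <- -test[neg, ] # noise term is symmetric, so this is exact

  dimnames(ref) <- list(ref_genes, ref_samples)
  dimnames(test) <- list(test_genes, test_samples)
  attr(ref, "species") <- "reference"
  attr(test, "species") <- "test"

  pos <- sim_positions(config)
  rownames(dosage) <- pos$snps$id
  colnames(dosage) <- ref_samples

  eqtl_truth <- list()
  if (!is.null(config$trans_effect)) {
    te <- config$trans_effect
    eqtl_truth[[length(eqtl_truth) + 1L]] <-
      list(snp = pos$snps$id[te$snp_index], kind = "trans",
           module = te$module_index,
           genes = ref_genes[module == te$module_index], beta = te$beta)
  }
  for (ce in config$cis_effects) {
    eqtl_truth[[length(eqtl_truth) + 1L]] <-
      list(snp = pos$snps$id[ce$snp_index], kind = "cis",
           genes = ref_genes[ce$gene_index], beta = ce$beta)
  }

  truth <- list(module = stats::setNames(module, ref_genes),
                preserved = config$preserved_flags,
                loading = stats::setNames(loading, ref_genes),
                eqtl = eqtl_truth,
                outlier_samples = outlier_ids)

  list(ref_probes = sim_probes(ref, "RP", config$n_probes_per_gene),
       test_probes = sim_probes(test, "TP", config$n_probes_per_gene),
       ref_expr = ref,
       test_expr = test,
       ortholog_map = data.frame(ref_gene = ref_genes, test_gene = test_genes,
                                 stringsAsFactors = FALSE),
       dosage = dosage,
       maf = stats::setNames(maf, pos$snps$id),
       gene_positions = pos$genes,
       snp_positions = pos$snps,
       covariates = covariates,
       truth = truth,
       config = config)
}

# Probe-level intensities: gene value + probe-specific offset + probe noise,
# so that max-mean probe collapse is non-trivial.
sim_probes <- function(expr, prefix, n_probes_range = c(1L, 3L),
                       offset_sd = 1, probe_noise_sd = 0.25) {
  n <- nrow(expr)
  k <- sample(seq(n_probes_range[1], n_probes_range[2]), n, replace = TRUE)
  gene_of_probe <- rep(seq_len(n), k)
  offsets <- stats::rnorm(length(gene_of_probe), sd = offset_sd)
  intensity <- expr[gene_of_probe, , drop = FALSE] +
    offsets +
    matrix(stats::rnorm(length(gene_of_probe) * ncol(expr),
                        sd = probe_noise_sd),
           length(gene_of_probe), ncol(expr))
  probe_ids <- sprintf("%s%05d", prefix, seq_along(gene_of_probe))
  rownames(intensity) <- probe_ids
  list(intensity = intensity,
       probe2gene = stats::setNames(rownames(expr)[gene_of_probe], probe_ids))
}

#' Write a synthetic study to disk as standard pipeline inputs
#'
#' Emits expression TSVs (probe- and gene-level), ortholog TSV, dosage TSV,
#' position TSVs, covariate TSV and a truth JSON.
#'
#' @param study result of [generate_paired_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(study$ref_probes$intensity, p("ref_probes.tsv"), "probe")
  write_expression_tsv(study$test_probes$intensity, p("test_probes.tsv"), "probe")
  data.table::fwrite(data.table::data.table(
    probe = names(study$ref_probes$probe2gene),
    gene = unname(study$ref_probes$probe2gene)), p("ref_probe2gene.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    probe = names(study$test_probes$probe2gene),
    gene = unname(study$test_probes$probe2gene)), p("test_probe2gene.tsv"), sep = "\t")
  data.table::fwrite(study$ortholog_map, p("orthologs.tsv"), sep = "\t")
  write_expression_tsv(study$dosage, p("dosage.tsv"), "snp")
  data.table::fwrite(study$gene_positions, p("gene_positions.tsv"), sep = "\t")
  data.table::fwrite(study$snp_positions, p("snp_positions.tsv"), sep = "\t")
  if (!is.null(study$covariates))
    write_expression_tsv(t(study$covariates), p("covariates.tsv"), "covariate")
  truth <- study$truth
  truth$module <- as.list(truth$module)
  truth$loading <- as.list(truth$loading)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
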