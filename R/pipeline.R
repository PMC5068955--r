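#' Default pipeline configuration
#'
#' @param ... overrides for any configuration key.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(seed = 1L,
              sim = list(),           # overrides for sim_config()
              input_dir = NULL,       # if set, read a written study instead
              power = NULL,           # NULL = choose by scale-free fit
              powers = 1:10,
              r2_target = 0.8,
              min_module_size = 50,
              deep_split = 3,
              merge_cut_height = 0.15,
              method = "bicor",
              outlier_z_cut = 3,
              n_perm = 10000,
              p_cut = 1e-4,
              run_eqtl = TRUE,
              run_enrichment = FALSE,
              gmt = NULL,
              eqtl_p_cut = 0.01,
              composite = FALSE,
              composite_n_perm = 200)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full cross-species preservation workflow
#'
#' simulate (or load) -> probe collapse -> ortholog harmonization ->
#' outlier removal -> network + modules (reference species) -> module
#' summaries -> projection + preservation -> optional eQTL scan and
#' gene-set enrichment. All outputs are written under `out_dir` as
#' TSV/JSON and returned invisibly; the run log records the seed and all
#' parameters, and re-running with the same config is byte-identical.
#'
#' @param config list from [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) list with the main intermediate objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  log <- list(seed = config$seed, config = config[setdiff(names(config), "sim")],
              sim = config$sim)

  if (is.null(config$input_dir)) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    study <- generate_paired_study(do.call(sim_config, sim_args))
  } else {
    study <- read_study(config$input_dir)
  }

  ref_col <- collapse_probes(study$ref_probes$intensity,
                             study$ref_probes$probe2gene, "reference")
  test_col <- collapse_probes(study$test_probes$intensity,
                              study$test_probes$probe2gene, "test")
  harm <- harmonize_orthologs(ref_col$expr, test_col$expr, study$ortholog_map)

  outl_ref <- detect_outlier_samples(harm$ref, z_cut = config$outlier_z_cut)
  outl_test <- detect_outlier_samples(harm$test, z_cut = config$outlier_z_cut)
  ref <- harm$ref[, !outl_ref$flagged, drop = FALSE]
  test <- harm$test[, !outl_test$flagged, drop = FALSE]
  attr(ref, "species") <- "reference"; attr(test, "species") <- "test"
  data.table::fwrite(outl_ref, p("outliers_reference.tsv"), sep = "\t")
  data.table::fwrite(outl_test, p("outliers_test.tsv"), sep = "\t")

  cm <- cor_matrix(ref, method = config$method)
  if (is.null(config$power)) {
    st <- pick_soft_threshold(cm, powers = config$powers,
                              r2_target = config$r2_target)
    power <- st$power
    data.table::fwrite(st$table, p("soft_threshold.tsv"), sep = "\t")
  } else power <- config$power
  log$power <- power
  tom <- tom_similarity(adjacency_matrix(cm, power))
  ma <- cut_modules(1 - tom, min_module_size = config$min_module_size,
                    deep_split = config$deep_split)
  ma <- merge_similar_modules(ref, ma, cut_height = config$merge_cut_height,
                              method = config$method)
  ms_ref <- module_summary(ref, ma, method = config$method)
  data.table::fwrite(data.table::data.table(gene = names(ma$labels),
                                            module = ma$labels),
                     p("modules.tsv"), sep = "\t")
  write_expression_tsv(t(ms_ref$eigengenes), p("eigengenes_reference.tsv"),
                       "module")
  write_expression_tsv(ms_ref$kme, p("kme_reference.tsv"), "gene")

  ms_test <- project_assignment(test, ma, pairs = harm$pairs,
                                method = config$method)
  pres <- preservation_report(ms_ref, ms_test, ma, n_perm = config$n_perm,
                              seed = config$seed, p_cut = config$p_cut)
  if (isTRUE(config$composite)) {
    test_aligned <- test
    back <- stats::setNames(harm$pairs$ref_gene, harm$pairs$test_gene)
    rownames(test_aligned) <- unname(back[rownames(test_aligned)])
    comp <- composite_preservation(ref, test_aligned, ma,
                                   beta = power,
                                   n_perm = config$composite_n_perm,
                                   seed = config$seed,
                                   method = config$method)
    pres <- merge(pres, comp[, c("module", "z_summary", "median_rank")],
                  by = "module", all.x = TRUE, sort = TRUE)
    data.table::fwrite(comp, p("composite_preservation.tsv"), sep = "\t")
  }
  data.table::fwrite(pres, p("preservation.tsv"), sep = "\t")
  data.table::fwrite(module_table(ms_ref, pres), p("module_table.tsv"),
                     sep = "\t")

  records <- NULL
  if (isTRUE(config$run_eqtl) && !is.null(study$dosage)) {
    covs <- study$covariates
    records <- fit_eqtl(study$dosage, ref, covariates = covs,
                        snp_positions = study$snp_positions,
                        gene_positions = study$gene_positions)
    data.table::fwrite(records, p("eqtl.tsv"), sep = "\t")
  }

  if (isTRUE(config$run_enrichment) && !is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    enr <- module_enrichment(ms_ref, ms_test, ma, pres, sets)
    if (!is.null(enr)) data.table::fwrite(enr, p("enrichment.tsv"), sep = "\t")
  }

  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(study = study, assignment = ma, ref = ref, test = test,
                 summary_ref = ms_ref, summary_test = ms_test,
                 preservation = pres, eqtl = records, power = power))
}

#' Read a study previously written with [write_study()]
#' @param dir directory produced by [write_study()].
#' @return list shaped like [generate_paired_study()]'s output (without
#'   truth loadings coerced back to vectors).
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  ref_int <- read_expression_tsv(p("ref_probes.tsv"), "reference")
  test_int <- read_expression_tsv(p("test_probes.tsv"), "test")
  r2g <- utils::read.delim(p("ref_probe2gene.tsv"), stringsAsFactors = FALSE)
  t2g <- utils::read.delim(p("test_probe2gene.tsv"), stringsAsFactors = FALSE)
  covs <- if (file.exists(p("covariates.tsv")))
    t(read_covariates_tsv(p("covariates.tsv"))) else NULL
  truth <- if (file.exists(p("truth.json")))
    jsonlite::read_json(p("truth.json"), simplifyVector = TRUE) else NULL
  list(ref_probes = list(intensity = ref_int,
                         probe2gene = stats::setNames(r2g$gene, r2g$probe)),
       test_probes = list(intensity = test_int,
                          probe2gene = stats::setNames(t2g$gene, t2g$probe)),
       ortholog_map = read_ortholog_tsv(p("orthologs.tsv")),
       dosage = if (file.exists(p("dosage.tsv"))) read_dosage_tsv(p("dosage.tsv")),
       gene_positions = if (file.exists(p("gene_positions.tsv")))
         read_positions_tsv(p("gene_positions.tsv")),
       snp_positions = if (file.exists(p("snp_positions.tsv")))
         read_positions_tsv(p("snp_positions.tsv")),
       covariates = covs,
       truth = truth)
}
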