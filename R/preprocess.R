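#' Collapse probe-level intensities to gene level
#'
#' For each gene, the probe with the maximum average intensity across
#' samples represents the gene. Ties are broken by the lexicographically
#' smallest probe ID.
#'
#' @param intensity probe x sample numeric matrix (rownames = probe IDs).
#' @param probe2gene named character vector mapping probe ID -> gene ID;
#'   probes absent from the map are dropped with a warning.
#' @param species species tag for the output matrix.
#' @return list with `expr` (gene x sample matrix) and `report`
#'   (data.frame probe, gene, mean_intensity, chosen).
#' @export
collapse_probes <- function(intensity, probe2gene, species = NA_character_) {
  probes <- rownames(intensity)
  if (is.null(probes)) stop("intensity matrix must have probe rownames")
  if (anyDuplicated(probes)) stop("probe IDs must be unique")
  gene <- unname(probe2gene[probes])
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    warning(sum(unmapped), " probes without gene assignment dropped")
    intensity <- intensity[!unmapped, , drop = FALSE]
    probes <- probes[!unmapped]
    gene <- gene[!unmapped]
  }
  if (!length(probes)) stop("no mapped probes left")
  means <- rowMeans(intensity, na.rm = TRUE)
  ord <- order(gene, -means, probes, method = "radix")
  first <- !duplicated(gene[ord])
  chosen_idx <- ord[first]
  report <- data.frame(probe = probes, gene = gene, mean_intensity = means,
                       chosen = seq_along(probes) %in% chosen_idx,
                       row.names = NULL, stringsAsFactors = FALSE)
  expr <- intensity[chosen_idx, , drop = FALSE]
  rownames(expr) <- gene[chosen_idx]
  expr <- expr[order(rownames(expr)), , drop = FALSE]
  attr(expr, "species") <- species
  list(expr = expr, report = report)
}

#' Restrict two gene-level matrices to one-to-one ortholog pairs
#'
#' Pairs whose genes are missing from either matrix are dropped (logged in
#' the returned report). Many-to-many pairs are resolved by keeping, per
#' gene, the pair that maximizes the combined across-sample mean
#' expression of its two members.
#'
#' @param ref,test gene x sample matrices.
#' @param ortholog_map data.frame with columns ref_gene, test_gene.
#' @return list with aligned `ref`, `test` (row i of each refers to the
#'   same pair), `pairs` (the retained map) and `dropped` (with reasons).
#' @export
harmonize_orthologs <- function(ref, test, ortholog_map) {
  om <- ortholog_map[, c("ref_gene", "test_gene")]
  present <- om$ref_gene %in% rownames(ref) & om$test_gene %in% rownames(test)
  dropped <- om[!present, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "gene absent from matrix"
  om <- om[present, , drop = FALSE]
  if (!nrow(om)) stop("empty ortholog intersection")
  score <- rowMeans(ref[om$ref_gene, , drop = FALSE]) +
    rowMeans(test[om$test_gene, , drop = FALSE])
  ord <- order(-score, om$ref_gene, om$test_gene, method = "radix")
  om <- om[ord, , drop = FALSE]
  keep <- !duplicated(om$ref_gene) & !duplicated(om$test_gene)
  multi <- om[!keep, , drop = FALSE]
  if (nrow(multi)) {
    multi$reason <- "many-to-many, lower combined expression"
    dropped <- rbind(dropped, multi)
  }
  om <- om[keep, , drop = FALSE]
  om <- om[order(om$ref_gene), , drop = FALSE]
  ref_out <- ref[om$ref_gene, , drop = FALSE]
  test_out <- test[om$test_gene, , drop = FALSE]
  attr(ref_out, "species") <- attr(ref, "species")
  attr(test_out, "species") <- attr(test, "species")
  rownames(dropped) <- NULL
  list(ref = ref_out, test = test_out, pairs = om, dropped = dropped)
}

#' Flag outlier samples by mean Euclidean distance
#'
#' Samples are clustered on their Euclidean distance (average linkage; the
#' tree is returned for inspection) and a sample is flagged when its mean
#' distance to all other samples exceeds mean + z_cut * SD of that
#' statistic. The rule is applied once more after removing the first
#' round's flags.
#'
#' @param em gene x sample matrix.
#' @param z_cut z-score threshold (default 3; `Inf` flags nothing).
#' @param iterate number of additional passes after the first (default 1).
#' @return data.frame (sample, mean_distance, round, flagged); the hclust
#'   tree of the first pass is attached as attribute `tree`.
#' @export
detect_outlier_samples <- function(em, z_cut = 3, iterate = 1) {
  if (ncol(em) < 10) stop("need at least 10 samples")
  d <- as.matrix(stats::dist(t(em)))
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  samples <- colnames(em)
  active <- rep(TRUE, ncol(em))
  out <- data.frame(sample = samples,
                    mean_distance = NA_real_,
                    round = NA_integer_,
                    flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(1 + iterate)) {
    idx <- which(active)
    if (length(idx) < 3) break
    md <- rowMeans(d[idx, idx, drop = FALSE]) * length(idx) / (length(idx) - 1)
    mu <- mean(md); s <- stats::sd(md)
    flag <- if (is.finite(z_cut) && s > 0) md > mu + z_cut * s else rep(FALSE, length(md))
    out$mean_distance[idx] <- md
    out$round[idx] <- r
    if (!any(flag)) break
    out$flagged[idx[flag]] <- TRUE
    active[idx[flag]] <- FALSE
  }
  attr(out, "tree") <- tree
  out
}
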