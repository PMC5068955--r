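# Cross-species module preservation. The reference species' module
# assignment is projected unchanged onto the test species; preservation of
# a module is the fraction of its genes whose kME keeps the same sign in
# both species, judged against a label-permutation null.

#' Project a reference module assignment into the test species
#'
#' Eigengenes and kME are computed in the test species using the
#' reference module memberships unchanged. Gene identifiers are mapped
#' through `pairs` (as returned by [harmonize_orthologs()]); if omitted,
#' the two matrices are assumed row-aligned on a shared gene universe.
#'
#' @param test_em gene x sample matrix for the test species.
#' @param ref_assignment `module_assignment` (or named label vector) on
#'   reference gene IDs.
#' @param pairs optional data.frame (ref_gene, test_gene).
#' @param method correlation estimator.
#' @return a `module_summary` for the test species whose kME rows are
#'   named by the REFERENCE gene IDs (so the two species align).
#' @export
project_assignment <- function(test_em, ref_assignment, pairs = NULL,
                               method = c("bicor", "pearson")) {
  method <- match.arg(method)
  labels <- if (inherits(ref_assignment, "module_assignment"))
    ref_assignment$labels else ref_assignment
  if (!is.null(pairs)) {
    map <- stats::setNames(pairs$test_gene, pairs$ref_gene)
    labels <- labels[names(labels) %in% names(map)]
    names(labels) <- unname(map[names(labels)])
  }
  missing <- setdiff(names(labels), rownames(test_em))
  if (length(missing)) {
    warning(length(missing), " genes absent from test data dropped")
    labels <- labels[setdiff(names(labels), missing)]
  }
  ms <- module_summary(test_em, labels, method = method,
                       species = attr(test_em, "species"))
  if (!is.null(pairs)) {
    back <- stats::setNames(pairs$ref_gene, pairs$test_gene)
    rownames(ms$kme) <- unname(back[rownames(ms$kme)])
    names(ms$labels) <- unname(back[names(ms$labels)])
  }
  ms
}

#' Fraction of sign-consistent genes between two kME vectors
#'
#' A gene is consistent iff sign(kme_ref) == sign(kme_test) with both
#' nonzero; exact zeros count as inconsistent.
#'
#' @param kme_ref,kme_test named numeric vectors aligned on gene IDs.
#' @param genes gene IDs to evaluate (default: all shared genes).
#' @return list(n_genes, n_consistent, fraction).
#' @export
consistency_fraction <- function(kme_ref, kme_test, genes = NULL) {
  if (is.null(genes)) genes <- intersect(names(kme_ref), names(kme_test))
  if (!length(genes)) stop("empty gene set")
  a <- kme_ref[genes]; b <- kme_test[genes]
  cons <- sign(a) == sign(b) & a != 0 & b != 0
  list(n_genes = length(genes),
       n_consistent = sum(cons),
       fraction = mean(cons))
}

#' Permutation p-values for per-module sign-consistency
#'
#' The per-gene sign-concordance indicator over the whole harmonized
#' universe is fixed; each of `n_perm` iterations permutes the gene
#' labels once (without replacement), re-partitions the permuted universe
#' into modules of the observed sizes, and records every random module's
#' consistency fraction. The p-value of module m is the proportion of
#' iterations in which the random fraction strictly exceeds the observed
#' one; p = 0 is reported with a `p_note` of "< 1/n_perm".
#'
#' @param kme_ref,kme_test kME vectors over the universe (or their signs),
#'   aligned on the same gene names.
#' @param ma `module_assignment` (or named label vector) over the same
#'   universe.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed integer seed; results are deterministic given it.
#' @param smooth if TRUE, use the add-one estimate (1 + b) / (1 + n_perm)
#'   instead of the raw proportion. Off by default.
#' @return data.frame (module, size, n_consistent, fraction, p, p_note,
#'   n_perm), one row per module.
#' @export
permutation_pvalue <- function(kme_ref, kme_test, ma, n_perm = 10000,
                               seed = 1, smooth = FALSE) {
  if (n_perm < 100) warning("n_perm < 100: p-values are very coarse")
  labels <- if (inherits(ma, "module_assignment")) ma$labels else ma
  genes <- intersect(names(labels), intersect(names(kme_ref), names(kme_test)))
  labels <- labels[genes]
  a <- kme_ref[genes]; b <- kme_test[genes]
  concord <- as.numeric(sign(a) == sign(b) & a != 0 & b != 0)
  mods <- sort(unique(labels[labels > 0]))
  pos <- lapply(mods, function(m) which(labels == m))
  sizes <- lengths(pos)
  observed <- vapply(pos, function(p) mean(concord[p]), numeric(1))

  n <- length(concord)
  exceed <- integer(length(mods))
  set.seed(seed)
  # one joint permutation per iteration re-partitions the universe into
  # modules of the observed sizes; only the first sum(sizes) draws of the
  # permutation are consumed, which is distributionally identical
  tot <- sum(sizes)
  bounds <- cumsum(sizes)
  for (it in seq_len(n_perm)) {
    cs <- cumsum(concord[sample.int(n, tot)])
    frac <- diff(c(0, cs[bounds])) / sizes
    exceed <- exceed + (frac > observed)
  }
  p <- if (smooth) (1 + exceed) / (1 + n_perm) else exceed / n_perm
  data.frame(module = as.integer(mods),
             size = as.integer(sizes),
             n_consistent = as.integer(round(observed * sizes)),
             fraction = observed,
             p = p,
             p_note = ifelse(exceed == 0L, paste0("< ", 1 / n_perm), ""),
             n_perm = n_perm,
             row.names = NULL)
}

#' Universe-wide kME vector, one entry per gene
#'
#' Each gene contributes the kME to its own module; unassigned genes
#' (label 0) contribute the kME to their best-|kME| module in the
#' REFERENCE summary, so the permutation null is defined over the whole
#' harmonized universe. `best_from` supplies that reference choice when
#' extracting the test species' vector (both species must pick the same
#' column per gene).
#'
#' @param ms a `module_summary`.
#' @param ma `module_assignment` or named label vector.
#' @param best_from optional `module_summary` whose |kME| picks the
#'   column for unassigned genes (defaults to `ms` itself).
#' @return named numeric vector over all genes of `ms$kme`.
#' @export
kme_universe <- function(ms, ma, best_from = ms) {
  labels <- if (inherits(ma, "module_assignment")) ma$labels else ma
  genes <- rownames(ms$kme)
  labels <- labels[genes]
  col <- match(as.character(labels), colnames(ms$kme))
  un <- which(is.na(col) | labels == 0)
  if (length(un))
    col[un] <- max.col(abs(best_from$kme[genes[un], , drop = FALSE]),
                       ties.method = "first")
  stats::setNames(ms$kme[cbind(seq_along(genes), col)], genes)
}

#' Full preservation report (consistency, permutation p, preserved flag)
#'
#' Observed consistency per module uses the module's own kME column over
#' its members; the permutation null fixes the universe-wide per-gene
#' concordance indicator from [kme_universe()] and runs one joint
#' permutation per iteration serving all modules.
#'
#' @param ref_ms,test_ms `module_summary` objects on the same gene
#'   universe (use [project_assignment()] for the test species).
#' @param ma the shared `module_assignment`.
#' @param n_perm permutations for the sign test.
#' @param seed seed for the permutation null.
#' @param p_cut preservation call threshold (default 1e-4).
#' @return data.frame with a logical `preserved` column; modules with
#'   p < p_cut (p = 0 meaning "< 1/n_perm") are flagged.
#' @export
preservation_report <- function(ref_ms, test_ms, ma, n_perm = 10000,
                                seed = 1, p_cut = 1e-4) {
  labels <- if (inherits(ma, "module_assignment")) ma$labels else ma
  u_ref <- kme_universe(ref_ms, labels)
  u_test <- kme_universe(test_ms, labels, best_from = ref_ms)
  out <- permutation_pvalue(u_ref, u_test, labels, n_perm = n_perm,
                            seed = seed)
  out$preserved <- out$p < p_cut
  out
}

#' Composite preservation statistics (Z-summary, median rank)
#'
#' For each module, four statistics are computed in the test data:
#' meanCor (mean off-diagonal intramodule correlation), meanAdj (mean
#' intramodule adjacency at power `beta`), cor_kME (correlation of
#' reference vs test kME over members) and cor_cor (correlation of the
#' vectorized intramodule correlation matrices). Each is standardized
#' against `n_perm` random same-size gene sets:
#' Z = (observed - mean_null) / sd_null. Z-density averages the first
#' two, Z-connectivity the last two, and Z-summary their mean. The
#' median rank is the median over the four statistics of the module's
#' rank (1 = best) among all modules.
#'
#' @param ref_em,test_em gene x sample matrices on the same universe
#'   (aligned gene IDs).
#' @param ma `module_assignment` (or named labels) over that universe.
#' @param beta soft-threshold power for meanAdj (default 5).
#' @param n_perm random gene sets per module (default 200).
#' @param seed seed.
#' @param method correlation estimator.
#' @return data.frame (module, size, z_density, z_connectivity,
#'   z_summary, median_rank) plus the observed statistics.
#' @export
composite_preservation <- function(ref_em, test_em, ma, beta = 5,
                                   n_perm = 200, seed = 1,
                                   method = c("bicor", "pearson")) {
  method <- match.arg(method)
  labels <- if (inherits(ma, "module_assignment")) ma$labels else ma
  genes <- intersect(names(labels), intersect(rownames(ref_em), rownames(test_em)))
  labels <- labels[genes]
  ref_em <- ref_em[genes, , drop = FALSE]
  test_em <- test_em[genes, , drop = FALSE]
  mods <- sort(unique(labels[labels > 0]))

  cm_test <- cor_matrix(test_em, method = method)
  cm_ref <- cor_matrix(ref_em, method = method)

  stat4 <- function(g) {
    ct <- cm_test[g, g]; cr <- cm_ref[g, g]
    lt <- lower.tri(ct)
    me_t <- eigengene(test_em, g); me_r <- eigengene(ref_em, g)
    kt <- cor_cross(test_em[g, , drop = FALSE], t(cbind(me_t$me)), method)[, 1]
    kr <- cor_cross(ref_em[g, , drop = FALSE], t(cbind(me_r$me)), method)[, 1]
    c(meanCor = mean(ct[lt]),
      meanAdj = mean(abs(ct[lt])^beta),
      cor_kME = stats::cor(kr, kt),
      cor_cor = stats::cor(cr[lt], ct[lt]))
  }

  obs <- t(vapply(mods, function(m) stat4(names(labels)[labels == m]),
                  numeric(4)))
  set.seed(seed)
  out <- NULL
  for (j in seq_along(mods)) {
    size <- sum(labels == mods[j])
    nullmat <- t(vapply(seq_len(n_perm), function(it)
      stat4(sample(genes, size)), numeric(4)))
    mu <- colMeans(nullmat)
    sdv <- apply(nullmat, 2L, stats::sd)
    if (any(sdv == 0)) warning("permutation SD = 0 for module ", mods[j])
    z <- (obs[j, ] - mu) / ifelse(sdv == 0, NA_real_, sdv)
    out <- rbind(out, data.frame(module = as.integer(mods[j]), size = size,
                                 meanCor = obs[j, 1], meanAdj = obs[j, 2],
                                 cor_kME = obs[j, 3], cor_cor = obs[j, 4],
                                 z_meanCor = z[1], z_meanAdj = z[2],
                                 z_cor_kME = z[3], z_cor_cor = z[4]))
  }
  out$z_density <- rowMeans(out[, c("z_meanCor", "z_meanAdj")])
  out$z_connectivity <- rowMeans(out[, c("z_cor_kME", "z_cor_cor")])
  out$z_summary <- (out$z_density + out$z_connectivity) / 2
  ranks <- apply(-out[, c("meanCor", "meanAdj", "cor_kME", "cor_cor")], 2L, rank)
  out$median_rank <- apply(as.matrix(ranks), 1L, stats::median)
  rownames(out) <- NULL
  out
}
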