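#' Hypergeometric gene-set over-representation
#'
#' For each set S in the collection, the upper-tail hypergeometric
#' probability of observing at least the given overlap between `query`
#' and S within the universe, with Benjamini-Hochberg FDR over all sets
#' tested. Fold enrichment is observed / expected overlap. The EASE-style
#' variant (overlap reduced by one before the tail, floored at zero) is
#' available behind `ease`.
#'
#' @param query character vector of genes (must lie in `universe`).
#' @param sets named list of character vectors (restricted to the
#'   universe before testing).
#' @param universe background gene universe.
#' @param ease if TRUE, apply the overlap-minus-one correction.
#' @return data.frame (set, set_size, overlap, expected, fold, p, fdr,
#'   genes) ordered by p.
#' @export
hypergeom_enrichment <- function(query, sets, universe, ease = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes outside the universe")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- intersect(query, s)
    k <- length(ov)
    expd <- n_q * length(s) / n_u
    k_test <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_test - 1L, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k,
               expected = expd,
               fold = if (expd > 0) k / expd else NA_real_,
               p = p, genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), c("set", "set_size", "overlap",
                                      "expected", "fold", "p", "fdr",
                                      "genes")]
  rownames(out) <- NULL
  out
}

#' Enrichment on the consistent genes of preserved modules
#'
#' Convenience wrapper reproducing the standard workflow: for each
#' preserved module, the query is the subset of its genes whose kME sign
#' agrees between species, tested against the supplied collection over
#' the harmonized universe.
#'
#' @param ref_ms,test_ms aligned `module_summary` objects.
#' @param ma `module_assignment`.
#' @param pres preservation report with a `preserved` column.
#' @param sets named list of gene sets.
#' @param universe background (default: all genes in the summaries).
#' @return data.frame with a leading `module` column.
#' @export
module_enrichment <- function(ref_ms, test_ms, ma, pres, sets,
                              universe = rownames(ref_ms$kme)) {
  labels <- if (inherits(ma, "module_assignment")) ma$labels else ma
  out <- NULL
  for (m in pres$module[pres$preserved]) {
    g <- names(labels)[labels == m]
    cons <- sign(ref_ms$kme[g, as.character(m)]) ==
      sign(test_ms$kme[g, as.character(m)]) &
      ref_ms$kme[g, as.character(m)] != 0 &
      test_ms$kme[g, as.character(m)] != 0
    res <- hypergeom_enrichment(g[cons], sets, universe)
    if (nrow(res)) res <- cbind(module = m, res)
    out <- rbind(out, res)
  }
  out
}
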