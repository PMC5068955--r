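#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j, where
#' l_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; the
#' diagonal is 1. Entries stay in [0, 1] for adjacencies in [0, 1].
#'
#' @param am symmetric adjacency matrix with entries in [0, 1].
#' @return TOM similarity matrix (same dimnames).
#' @export
tom_similarity <- function(am) {
  if (!isSymmetric(unname(am), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(am < 0 | am > 1)) stop("adjacency entries must lie in [0, 1]")
  a <- am
  diag(a) <- 0
  # sum_{u != i,j} a_iu a_uj = (A %*% A)_ij - a_ii a_ij - a_ij a_jj = (A%*%A)_ij
  # with zeroed diagonal; the u = i and u = j terms vanish because a has
  # zero diagonal.
  l <- a %*% a
  k <- rowSums(a)
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(am)
  tom
}

#' TOM-based dissimilarity (1 - TOM)
#' @param tom TOM similarity matrix.
#' @return dissimilarity matrix.
#' @export
tom_dissimilarity <- function(tom) 1 - tom
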