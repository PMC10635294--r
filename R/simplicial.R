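#' Simplicial complexes and combinatorial (Hodge) Laplacians
#'
#' A simplicial complex is stored as a list of integer matrices, one per
#' dimension: element `d + 1` holds the d-simplices as rows of `d + 1`
#' vertex ids, sorted ascending within a row and lexicographically across
#' rows.  The sorted-vertex convention fixes the orientation; Laplacian
#' spectra do not depend on this choice.
#'
#' @param generators list of integer vectors, each a simplex given by its
#'   vertex ids; faces are added automatically (face closure).
#' @return an object of class `simplicial_complex`.
#' @examples
#' K <- simplicial_complex(list(c(0, 1, 2)))
#' n_simplices(K, 1)  # 3 edges from the filled triangle
#' @export
simplicial_complex <- function(generators = list()) {
  by_dim <- list()
  for (g in generators) {
    v <- sort(unique(as.integer(g)))
    stopifnot(length(v) >= 1)
    # all non-empty subsets = faces (guard combn's scalar-n behaviour)
    for (m in seq_len(length(v))) {
      sub <- if (length(v) == 1) matrix(v, 1, 1) else utils::combn(v, m)
      key <- as.character(m)
      by_dim[[key]] <- cbind(by_dim[[key]], sub)
    }
  }
  dims <- list()
  if (length(by_dim)) {
    maxm <- max(as.integer(names(by_dim)))
    for (m in seq_len(maxm)) {
      mat <- by_dim[[as.character(m)]]
      if (is.null(mat)) {
        dims[[m]] <- matrix(integer(0), nrow = 0, ncol = m)
        next
      }
      mat <- t(mat)
      mat <- unique(mat)
      ord <- do.call(order, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
      dims[[m]] <- mat[ord, , drop = FALSE]
    }
  }
  structure(list(simplices = dims), class = "simplicial_complex")
}

#' Number of k-simplices in a complex
#' @param K a `simplicial_complex`
#' @param k simplex dimension
#' @export
n_simplices <- function(K, k) {
  if (k < 0 || k + 1 > length(K$simplices)) return(0L)
  nrow(K$simplices[[k + 1]])
}

#' k-simplices of a complex as a matrix of vertex rows
#' @inheritParams n_simplices
#' @export
simplices <- function(K, k) {
  if (k < 0 || k + 1 > length(K$simplices)) {
    return(matrix(integer(0), nrow = 0, ncol = max(k + 1, 1)))
  }
  K$simplices[[k + 1]]
}

#' @export
print.simplicial_complex <- function(x, ...) {
  counts <- vapply(seq_along(x$simplices), function(m) nrow(x$simplices[[m]]), 0L)
  cat("simplicial complex:",
      paste(sprintf("%d %d-simplices", counts, seq_along(counts) - 1L),
            collapse = ", "), "\n")
  invisible(x)
}

simplex_keys <- function(mat) {
  if (nrow(mat) == 0) return(character(0))
  apply(mat, 1L, paste, collapse = ",")
}

#' Boundary matrix of the k-th boundary operator
#'
#' Rows index the (k-1)-simplices, columns the k-simplices, both in the
#' complex's canonical order.  The column of a k-simplex carries the
#' alternating signs (-1)^i of its facets obtained by dropping the i-th
#' vertex (0-based) of the ascending vertex tuple.  `B0` is the zero map,
#' returned as a 0-row matrix.
#'
#' @inheritParams n_simplices
#' @return numeric matrix with entries in \{-1, 0, 1\}.
#' @export
boundary_matrix <- function(K, k) {
  nk <- n_simplices(K, k)
  if (k <= 0) return(matrix(0, nrow = 0, ncol = nk))
  nkm1 <- n_simplices(K, k - 1)
  B <- matrix(0, nrow = nkm1, ncol = nk)
  if (nk == 0 || nkm1 == 0) return(B)
  faces <- simplex_keys(simplices(K, k - 1))
  up <- simplices(K, k)
  for (j in seq_len(nk)) {
    v <- up[j, ]
    for (i in seq_along(v)) {
      key <- paste(v[-i], collapse = ",")
      r <- match(key, faces)
      B[r, j] <- (-1)^(i - 1)
    }
  }
  B
}

#' Combinatorial (Hodge) Laplacian L_k = B_{k+1} B_{k+1}^T + B_k^T B_k
#'
#' For k = 0 this reduces to the graph Laplacian of the 1-skeleton since the
#' 0-th boundary operator is the zero map.  The matrix is symmetric positive
#' semi-definite with integer entries; the multiplicity of its zero
#' eigenvalue equals the k-th Betti number (combinatorial Hodge theorem).
#'
#' @inheritParams n_simplices
#' @return square numeric matrix of size `n_simplices(K, k)` (0 x 0 when the
#'   complex has no k-simplices, signalling an empty spectrum).
#' @export
hodge_laplacian <- function(K, k) {
  nk <- n_simplices(K, k)
  if (nk == 0) return(matrix(0, 0, 0))
  Bk1 <- boundary_matrix(K, k + 1)
  up <- if (ncol(Bk1) > 0) Bk1 %*% t(Bk1) else matrix(0, nk, nk)
  if (k == 0) return(up)
  Bk <- boundary_matrix(K, k)
  up + t(Bk) %*% Bk
}

#' Entrywise construction of the combinatorial Laplacian
#'
#' Independent of the boundary-matrix products: assembles L_k from the
#' degree / upper-adjacency / lower-adjacency case analysis.  For k = 0 the
#' diagonal holds vertex degrees and off-diagonal entries are -1 for edges.
#' For k > 0 the diagonal is (upper degree) + k + 1; off-diagonal entries
#' vanish for upper-adjacent simplices and are otherwise the product of the
#' signs with which the shared (k-1)-face enters the two boundaries.
#' Used as a cross-check oracle against [hodge_laplacian()].
#'
#' @inheritParams n_simplices
#' @export
hodge_laplacian_entrywise <- function(K, k) {
  nk <- n_simplices(K, k)
  if (nk == 0) return(matrix(0, 0, 0))
  Sk <- simplices(K, k)
  Sk1 <- simplices(K, k + 1)
  L <- matrix(0, nk, nk)
  keys_k <- simplex_keys(Sk)
  # upper degree and upper adjacency from the (k+1)-simplices
  upper_deg <- integer(nk)
  upper_adj <- matrix(FALSE, nk, nk)
  if (nrow(Sk1) > 0) {
    for (r in seq_len(nrow(Sk1))) {
      v <- Sk1[r, ]
      idx <- vapply(seq_along(v), function(i) {
        match(paste(v[-i], collapse = ","), keys_k)
      }, 0L)
      upper_deg[idx] <- upper_deg[idx] + 1L
      for (a in idx) for (b in idx) if (a != b) upper_adj[a, b] <- TRUE
    }
  }
  if (k == 0) {
    diag(L) <- upper_deg
    L[upper_adj] <- -1
    return(L)
  }
  diag(L) <- upper_deg + k + 1
  for (i in seq_len(nk)) {
    vi <- Sk[i, ]
    for (j in seq_len(nk)) {
      if (j == i || upper_adj[i, j]) next
      vj <- Sk[j, ]
      shared <- intersect(vi, vj)
      if (length(shared) != k) next  # not lower adjacent via a common facet
      # sign with which the shared facet appears in each boundary
      pos_i <- which(!(vi %in% shared))
      pos_j <- which(!(vj %in% shared))
      L[i, j] <- (-1)^(pos_i - 1) * (-1)^(pos_j - 1)
    }
  }
  L
}

#' Eigenvalue spectrum of a Laplacian matrix
#' @param L symmetric matrix (possibly 0 x 0)
#' @return ascending numeric vector of eigenvalues (length 0 for an empty
#'   matrix), clamped at 0 from below within tolerance.
#' @export
laplacian_spectrum <- function(L) {
  if (nrow(L) == 0) return(numeric(0))
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  pmax(ev, 0)
}

#' Betti number from a Laplacian spectrum
#'
#' Counts the harmonic (zero) eigenvalues: beta_k = nullity(L_k).  The
#' tolerance scales with the largest eigenvalue so integer-valued fixture
#' Laplacians split cleanly.
#'
#' @param L symmetric PSD matrix, or a numeric vector of eigenvalues
#' @param tol relative zero threshold
#' @export
betti_from_spectrum <- function(L, tol = 1e-8) {
  ev <- if (is.matrix(L)) {
    if (nrow(L) == 0) return(0L)
    eigen(L, symmetric = TRUE, only.values = TRUE)$values
  } else L
  if (length(ev) == 0) return(0L)
  thr <- tol * max(1, max(abs(ev)))
  sum(abs(ev) <= thr)
}
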