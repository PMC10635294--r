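#' Filtration grid used throughout the 0-dimensional featurization
#'
#' The default spans 0 to 6 Angstrom in 0.5 Angstrom steps (13 values),
#' the range over which site--environment contact distances carry signal.
#'
#' @param from,to,by grid limits and step in Angstrom
#' @return strictly increasing numeric vector
#' @export
filtration_grid <- function(from = 0, to = 6, by = 0.5) {
  g <- seq(from, to, by = by)
  stopifnot(length(g) >= 1, all(diff(g) > 0))
  g
}

#' Vietoris-Rips snapshot complexes over a distance matrix
#'
#' At filtration value f a simplex is included iff every pairwise distance
#' among its vertices is at most f (threshold inclusive).  Infinite entries
#' are legal and model forbidden contacts, e.g. the interactive distance
#' between two atoms sharing a location class.  Vertices are always present.
#'
#' @param D symmetric distance matrix; `Inf` allowed
#' @param grid filtration values, see [filtration_grid()]
#' @param max_dim highest simplex dimension to build (1 = graph skeleton,
#'   sufficient for 0-dimensional Laplacians)
#' @return list of `simplicial_complex`, one per grid value, nested
#' @export
rips_snapshots <- function(D, grid = filtration_grid(), max_dim = 1) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), max_dim >= 1)
  n <- nrow(D)
  lapply(grid, function(f) {
    gens <- lapply(seq_len(n), function(i) i)
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (D[i, j] <= f) gens[[length(gens) + 1]] <- c(i, j)
      }
      if (max_dim >= 2 && n >= 3) {
        cmb <- utils::combn(n, 3)
        for (c3 in seq_len(ncol(cmb))) {
          v <- cmb[, c3]
          if (max(D[v[1], v[2]], D[v[1], v[3]], D[v[2], v[3]]) <= f) {
            gens[[length(gens) + 1]] <- v
          }
        }
      }
    }
    simplicial_complex(gens)
  })
}

#' Laplacian spectra along a filtration
#'
#' For each snapshot complex, the full ascending eigenvalue multiset of the
#' k-th combinatorial Laplacian; an empty multiset where the snapshot has no
#' k-simplices.
#'
#' @param snapshots list of `simplicial_complex` (nested)
#' @param k Laplacian dimension
#' @return object of class `spectral_profile`: list of numeric vectors
#' @export
spectra_over_filtration <- function(snapshots, k = 0) {
  sp <- lapply(snapshots, function(K) laplacian_spectrum(hodge_laplacian(K, k)))
  structure(list(spectra = sp, k = k), class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("spectral profile (k = %d) over %d snapshots\n",
              x$k, length(x$spectra)))
  invisible(x)
}

#' Cech filtration of a 3D point cloud
#'
#' Enumerates simplices up to `max_dim` with filtration value equal to the
#' radius of the smallest enclosing ball of the vertex set (monotone by
#' construction).  This nerve of the union-of-balls filtration has the same
#' persistence diagram as the alpha complex but needs no Delaunay
#' triangulation, so degenerate (coplanar, cocircular) fixtures are exact.
#'
#' @param coords n x 3 numeric matrix of coordinates in Angstrom
#' @param max_dim highest simplex dimension (capped at 3)
#' @param rmax only simplices entering at radius <= rmax are enumerated
#' @return list with `vertices` (padded matrix), `dim`, `filtration`
#' @export
cech_filtration <- function(coords, max_dim = 3, rmax = Inf) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  if (!is.finite(rmax)) {
    # all homology of dimension >= 1 dies by the enclosing radius, which is
    # bounded by the largest distance from any single point
    d1 <- sqrt(colSums((t(coords) - coords[1, ])^2))
    rmax <- max(d1) + 1e-6
  }
  cech_filtration_cpp(coords, as.integer(max_dim), rmax)
}

#' Snapshot complex of the Cech filtration at a fixed radius
#' @inheritParams cech_filtration
#' @param r radius in Angstrom
#' @export
cech_complex_at <- function(coords, r, max_dim = 3) {
  filt <- cech_filtration(coords, max_dim = max_dim, rmax = r)
  keep <- filt$filtration <= r + 1e-12
  gens <- lapply(which(keep), function(s) {
    v <- filt$vertices[s, ]
    v[!is.na(v)]
  })
  simplicial_complex(gens)
}

reduce_filtration <- function(filt, max_dim_report) {
  vm <- filt$vertices
  dm <- filt$dim
  fv <- filt$filtration
  # order by (filtration, dim, lexicographic vertices)
  ordcols <- lapply(seq_len(ncol(vm)), function(j) {
    v <- vm[, j]
    v[is.na(v)] <- -1L
    v
  })
  ord <- do.call(order, c(list(fv, dm), ordcols))
  reduce_persistence_cpp(vm[ord, , drop = FALSE], dm[ord], fv[ord],
                         as.integer(max_dim_report))
}

#' Persistence barcode of a point cloud under the alpha/Cech filtration
#'
#' Intervals are reported on the radius scale in Angstrom.  Zero-length
#' pairs are dropped; the essential 0-dimensional class is reported with
#' `death = Inf`.
#'
#' @inheritParams cech_filtration
#' @param max_dim highest homology dimension to report (simplices one
#'   dimension higher are enumerated internally)
#' @return data.frame of class `barcode` with columns
#'   `dimension`, `birth`, `death`
#' @export
alpha_barcode <- function(coords, max_dim = 2) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 1) {
    return(new_barcode(data.frame(dimension = 0L, birth = 0, death = Inf)))
  }
  filt <- cech_filtration(coords, max_dim = min(max_dim + 1, 3))
  bars <- reduce_filtration(filt, max_dim)
  df <- as.data.frame(bars)
  names(df) <- c("dimension", "birth", "death")
  df$dimension <- as.integer(df$dimension)
  df <- df[df$death > df$birth, , drop = FALSE]
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  new_barcode(df)
}

new_barcode <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("barcode", "data.frame")
  df
}

#' 0-dimensional persistence over an arbitrary distance matrix
#'
#' Kruskal/union-find computation of the component merge tree of the Rips
#' filtration: every point is born at 0; a bar dies at the distance at which
#' its component is absorbed; components never merged (e.g. across an
#' infinite interactive distance) give `death = Inf`.
#'
#' @param D symmetric distance matrix; `Inf` allowed
#' @return `barcode` data.frame (all `dimension` 0)
#' @export
rips_diagram0 <- function(D) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  deaths <- numeric(0)
  if (n >= 2) {
    pairs <- which(upper.tri(D) & is.finite(D), arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      w <- D[pairs]
      ord <- order(w)
      for (e in ord) {
        ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
        if (ri != rj) {
          parent[max(ri, rj)] <- min(ri, rj)
          deaths <- c(deaths, w[e])
        }
      }
    }
  }
  ncomp <- n - length(deaths)
  df <- data.frame(
    dimension = 0L,
    birth = 0,
    death = c(sort(deaths), rep(Inf, ncomp))
  )
  new_barcode(df)
}

#' Drop short persistence bars
#'
#' Bars shorter than `min_length` carry no clear physical meaning at
#' interatomic scale and are removed before any statistic is taken.
#' Infinite bars are always kept; the boundary case
#' `death - birth == min_length` is kept ("shorter than" is strict).
#'
#' @param bars `barcode` data.frame
#' @param min_length minimum bar length in Angstrom (default 0.1)
#' @export
filter_bars <- function(bars, min_length = 0.1) {
  if (nrow(bars) == 0) return(bars)
  keep <- is.infinite(bars$death) | (bars$death - bars$birth >= min_length)
  new_barcode(bars[keep, , drop = FALSE])
}

#' Betti number at a filtration value, read off a barcode
#' @param bars `barcode` data.frame
#' @param k homology dimension
#' @param f filtration value (bar alive iff birth <= f < death)
#' @export
betti_from_barcode <- function(bars, k, f) {
  sum(bars$dimension == k & bars$birth <= f + 1e-12 & bars$death > f + 1e-12)
}

#' Write a barcode as tab-separated text ("inf" for infinite deaths)
#' @param bars `barcode` data.frame
#' @param path output file
#' @export
write_barcode <- function(bars, path) {
  out <- bars
  out$death <- ifelse(is.infinite(out$death), "inf",
                      format(out$death, digits = 12))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode written by [write_barcode()]
#' @param path input file
#' @export
read_barcode <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric", "character"))
  df$death <- ifelse(df$death == "inf", Inf, as.numeric(df$death))
  new_barcode(df)
}
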