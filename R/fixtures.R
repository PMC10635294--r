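SIDE_CHAINS <- list(
  GLY = character(0),
  ALA = c(CB = "C"),
  SER = c(CB = "C", OG = "O"),
  THR = c(CB = "C", OG1 = "O", CG2 = "C"),
  CYS = c(CB = "C", SG = "S"),
  VAL = c(CB = "C", CG1 = "C", CG2 = "C"),
  LEU = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
  ILE = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
  MET = c(CB = "C", CG = "C", SD = "S", CE = "C"),
  PRO = c(CB = "C", CG = "C", CD = "C"),
  PHE = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
          CZ = "C"),
  TYR = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
          CZ = "C", OH = "O"),
  TRP = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", NE1 = "N", CE2 = "C",
          CE3 = "C", CZ2 = "C", CZ3 = "C", CH2 = "C"),
  ASP = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
  GLU = c(CB = "C", CG = "C", CD = "C", OE1 = "O", OE2 = "O"),
  ASN = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
  GLN = c(CB = "C", CG = "C", CD = "C", OE1 = "O", NE2 = "N"),
  LYS = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N"),
  ARG = c(CB = "C", CG = "C", CD = "C", NE = "N", CZ = "C", NH1 = "N",
          NH2 = "N"),
  HIS = c(CB = "C", CG = "C", ND1 = "N", CD2 = "C", CE1 = "C", NE2 = "N")
)

# deterministic sub-Angstrom jitter so fixtures are not exactly collinear
fixture_jitter <- function(seed, i, j, axis) {
  0.25 * sin(seed * 0.37 + i * 2.13 + j * 5.71 + axis * 9.29)
}

residue_atoms <- function(resname, res_index, seed) {
  x0 <- (res_index - 1) * 3.8
  bb <- rbind(
    N  = c(x0 + 0.0, 0.2, 0.0),
    CA = c(x0 + 1.3, 0.8, 0.4),
    C  = c(x0 + 2.5, 0.1, 0.2),
    O  = c(x0 + 2.8, -0.9, 0.8)
  )
  elements <- c(N = "N", CA = "C", C = "C", O = "O")
  sc <- SIDE_CHAINS[[resname]]
  if (length(sc)) {
    ca <- bb["CA", ]
    for (t in seq_along(sc)) {
      pos <- ca + c(0.4 * t, 1.2 + 0.9 * t, 0.7 + 0.35 * t * (-1)^t)
      bb <- rbind(bb, pos)
      rownames(bb)[nrow(bb)] <- names(sc)[t]
      elements[names(sc)[t]] <- unname(sc[t])
    }
  }
  for (j in seq_len(nrow(bb))) {
    for (ax in 1:3) {
      bb[j, ax] <- bb[j, ax] + fixture_jitter(seed, res_index, j, ax)
    }
  }
  data.frame(name = rownames(bb), element = unname(elements[rownames(bb)]),
             x = bb[, 1], y = bb[, 2], z = bb[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

format_pdb_atom <- function(serial, name, resname, chain, resseq, x, y, z,
                            element) {
  # PDB atom-name column convention: single-letter elements start in col 14
  nm <- if (nchar(name) < 4) paste0(" ", formatC(name, width = -3)) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, " ", resname, chain, resseq, " ", x, y, z, 1, 0,
          element)
}

write_peptide <- function(sequence3, chain, path, seed) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(sequence3)) {
    at <- residue_atoms(sequence3[i], i, seed)
    for (j in seq_len(nrow(at))) {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(serial, at$name[j], sequence3[i],
                                        chain, i, at$x[j], at$y[j], at$z[j],
                                        at$element[j]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Synthetic wild-type/mutant peptide pair
#'
#' Writes a pair of idealized-geometry peptide PDB files differing only in
#' the side chain of the mutated residue, plus the matching mutation spec.
#' Geometry is deterministic in (recipe, seed) down to the byte; it is
#' designed to exercise parsing, selection and filtration, not to be
#' physical.
#'
#' @param n_residues number of residues (2..50)
#' @param mutation_position 1-based residue index of the mutation
#' @param seed RNG seed (sequence draw and coordinate jitter)
#' @param dir output directory
#' @param chain chain identifier
#' @return list with `wild`, `mutant` (paths), `spec` (`mutation_spec`),
#'   and `sequence` (wild-type 1-letter string)
#' @export
make_peptide_pdb <- function(n_residues = 6, mutation_position = 3,
                             seed = 1, dir = tempdir(), chain = "A") {
  stopifnot(n_residues >= 2, n_residues <= 50)
  if (mutation_position < 1 || mutation_position > n_residues) {
    stop("invalid mutation position")
  }
  set.seed(seed)
  aa <- sample(names(AA3), n_residues, replace = TRUE)
  wild_aa <- aa[mutation_position]
  mutant_aa <- sample(setdiff(names(AA3), wild_aa), 1)
  seq3_w <- unname(AA3[aa])
  seq3_m <- seq3_w
  seq3_m[mutation_position] <- unname(AA3[mutant_aa])
  wild_path <- file.path(dir, sprintf("wild_s%d.pdb", seed))
  mut_path <- file.path(dir, sprintf("mutant_s%d.pdb", seed))
  write_peptide(seq3_w, chain, wild_path, seed)
  write_peptide(seq3_m, chain, mut_path, seed)
  spec <- mutation_spec(list(chain = chain, wild_aa = wild_aa,
                             residue_number = mutation_position,
                             mutant_aa = mutant_aa))
  list(wild = wild_path, mutant = mut_path, spec = spec,
       sequence = paste(aa, collapse = ""))
}

#' Point clouds with known topology
#'
#' Shapes: `ring6` — a regular hexagon of side `scale` in the xy-plane
#' (one 1-cycle); `two_clusters` — two tight 4-point clusters `scale`
#' Angstrom apart (two components below the gap); `tetra_shell` — the four
#' vertices of a regular tetrahedron of side `scale` (one cavity between
#' the triangle and circumsphere radii); `random` — seeded uniform points
#' in a `scale`-sided box (capped at 25 points).
#'
#' @param shape one of "ring6", "two_clusters", "tetra_shell", "random"
#' @param scale characteristic length in Angstrom
#' @param seed RNG seed (used by "random")
#' @param n point count for "random"
#' @return n x 3 coordinate matrix
#' @export
make_topology_cloud <- function(shape = c("ring6", "two_clusters",
                                          "tetra_shell", "random"),
                                scale = 1.5, seed = 1, n = 15) {
  shape <- match.arg(shape)
  switch(shape,
    ring6 = {
      ang <- seq(0, 2 * pi, length.out = 7)[-7]
      cbind(scale * cos(ang), scale * sin(ang), 0)
    },
    two_clusters = {
      base <- rbind(c(0, 0, 0), c(1, 0.2, 0), c(0.3, 1, 0.2),
                    c(0.5, 0.4, 0.9))
      rbind(base, sweep(base, 2, c(scale, 0, 0), "+"))
    },
    tetra_shell = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      v * scale / (2 * sqrt(2))
    },
    random = {
      n <- min(n, 25)
      set.seed(seed)
      matrix(stats::runif(3 * n, 0, scale), ncol = 3)
    }
  )
}

#' Synthetic labeled feature dataset for classifier tests
#'
#' Three Gaussian classes (labels "-", "N", "+") at a controllable mean
#' separation, optionally drawn with the 1 : 0.69 : 0.34 class imbalance of
#' curated solubility data.
#'
#' @param n_samples total sample count
#' @param n_components feature dimensionality
#' @param class_separation distance between class means in units of the
#'   within-class standard deviation
#' @param seed RNG seed
#' @param imbalance draw classes at the 1:0.69:0.34 ratio instead of
#'   balanced
#' @return list with `x` (matrix), `y` (labels), `ids`
#' @export
make_labeled_features <- function(n_samples = 300, n_components = 10,
                                  class_separation = 5, seed = 1,
                                  imbalance = FALSE) {
  set.seed(seed)
  ratio <- if (imbalance) c(1, 0.69, 0.34) else c(1, 1, 1)
  counts <- floor(n_samples * ratio / sum(ratio))
  rem <- n_samples - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  labels <- c("-", "N", "+")
  means <- matrix(0, 3, n_components)
  for (i in 1:3) means[i, min(i, n_components)] <- class_separation
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(stats::rnorm(counts[i] * n_components), ncol = n_components) +
      matrix(means[i, ], counts[i], n_components, byrow = TRUE)
  }))
  y <- rep(labels, counts)
  perm <- sample(length(y))
  list(x = x[perm, , drop = FALSE], y = y[perm],
       ids = sprintf("s%04d", seq_along(y)))
}
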