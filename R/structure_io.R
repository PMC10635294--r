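#' @useDynLib toplap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

# theoretical Gly-X-Gly maximum accessible surface areas (A^2),
# Tien et al. 2013
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Parse ATOM records of a PDB file
#'
#' Reads the first model only; HETATM records, waters and hydrogens are
#' excluded (heavy-atom convention).  Alternate locations are resolved by
#' keeping the highest-occupancy copy of each atom, ties going to the first
#' listed.  The element is taken from the element column (77-78) and falls
#' back to the atom-name convention when blank.
#'
#' @param path path to a PDB file
#' @return data.frame of class `atom_cloud` with one row per atom:
#'   `serial`, `name`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`,
#'   `z`, `occupancy`, `element`
#' @export
parse_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines <- lines[seq_len(end[1] - 1)]
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0) stop("no ATOM records in ", path)
  fld <- function(a, b) trimws(substr(lines, a, b))
  x <- suppressWarnings(as.numeric(fld(31, 38)))
  y <- suppressWarnings(as.numeric(fld(39, 46)))
  z <- suppressWarnings(as.numeric(fld(47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("unparseable coordinates in ", path)
  occ <- suppressWarnings(as.numeric(fld(55, 60)))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(fld(7, 11))),
    name = fld(13, 16),
    altloc = substr(lines, 17, 17),
    resname = fld(18, 20),
    chain = fld(22, 22),
    resseq = suppressWarnings(as.integer(fld(23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    x = x, y = y, z = z,
    occupancy = occ,
    element = fld(77, 78),
    stringsAsFactors = FALSE
  )
  # element fallback from the atom name: skip leading digits, take the letter
  blank <- atoms$element == ""
  if (any(blank)) {
    nm <- gsub("^[0-9']+", "", atoms$name[blank])
    atoms$element[blank] <- substr(nm, 1, 1)
  }
  atoms$element <- toupper(atoms$element)
  atoms <- atoms[atoms$resname != "HOH" & atoms$element != "H" &
                 atoms$element != "D", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms in ", path)
  # resolve altLocs: highest occupancy, first listed on ties
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "|")
  ord <- order(match(key, unique(key)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resseq, atoms$icode,
                                   atoms$name, sep = "|")), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  class(atoms) <- c("atom_cloud", "data.frame")
  atoms
}

#' Parse a compact mutation string
#'
#' Accepts the "chain:WildNumberMutant" form, e.g. `"A:I283W"`.
#'
#' @param x compact mutation string, or a list with fields `chain`,
#'   `wild_aa`, `residue_number`, `mutant_aa` (returned unchanged)
#' @return list of class `mutation_spec`
#' @export
mutation_spec <- function(x) {
  if (inherits(x, "mutation_spec")) return(x)
  if (is.list(x)) {
    spec <- x
  } else {
    m <- regmatches(x, regexec("^([A-Za-z0-9]):([A-Z])([0-9]+)([A-Z])$", x))[[1]]
    if (length(m) != 5) stop("cannot parse mutation string: ", x)
    spec <- list(chain = m[2], wild_aa = m[3],
                 residue_number = as.integer(m[4]), mutant_aa = m[5])
  }
  stopifnot(spec$wild_aa %in% names(AA3), spec$mutant_aa %in% names(AA3))
  if (spec$wild_aa == spec$mutant_aa) {
    stop("wild-type and mutant amino acids must differ")
  }
  class(spec) <- "mutation_spec"
  spec
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("mutation %s:%s%d%s\n", x$chain, x$wild_aa,
              x$residue_number, x$mutant_aa))
  invisible(x)
}

#' Tag atoms as mutation site or environment
#'
#' Atoms of the residue named by the mutation spec get location `SITE`; all
#' other atoms get `ENV`.  It is a hard error if the residue is absent or
#' its name disagrees with the stated wild-type amino acid.
#'
#' @param atoms `atom_cloud` from [parse_pdb()]
#' @param spec `mutation_spec` or compact string
#' @param check_wild verify the residue name against `wild_aa` (turn off
#'   when labeling the mutant structure, whose residue carries `mutant_aa`)
#' @return `atom_cloud` with an additional `loc` column in \{SITE, ENV\}
#' @export
label_site <- function(atoms, spec, check_wild = TRUE) {
  spec <- mutation_spec(spec)
  site <- atoms$chain == spec$chain & atoms$resseq == spec$residue_number
  if (!any(site)) {
    stop(sprintf("no residue %s:%d in structure", spec$chain,
                 spec$residue_number))
  }
  resname <- unique(atoms$resname[site])
  if (length(resname) != 1) stop("ambiguous residue at mutation site")
  if (check_wild && !identical(unname(AA3[spec$wild_aa]), resname)) {
    stop(sprintf("residue %s:%d is %s, expected %s (%s)", spec$chain,
                 spec$residue_number, resname, AA3[spec$wild_aa],
                 spec$wild_aa))
  }
  atoms$loc <- ifelse(site, "SITE", "ENV")
  class(atoms) <- c("atom_cloud", "data.frame")
  atoms
}

#' Element- and location-specific atom selection
#'
#' Keeps SITE atoms of `site_element` and ENV atoms of `env_element`.
#' The special element `"HEAVY"` selects all of C, N, O, S.  When a
#' neighborhood radius is given, ENV atoms farther than the radius from
#' every SITE atom are dropped, restricting the cloud to the local
#' structure around the mutation.
#'
#' @param cloud labeled `atom_cloud` (with `loc` column)
#' @param site_element,env_element one of "C", "N", "O" or "HEAVY"
#' @param neighborhood_radius Angstrom cutoff for ENV atoms, or `NULL` for
#'   the whole protein
#' @return `atom_cloud` subset (possibly empty); the radius is recorded in
#'   attribute `neighborhood_radius`
#' @export
select_cloud <- function(cloud, site_element, env_element,
                         neighborhood_radius = 12) {
  stopifnot("loc" %in% names(cloud))
  elts <- function(e) if (identical(e, "HEAVY")) c("C", "N", "O", "S") else e
  stopifnot(site_element %in% c("C", "N", "O", "HEAVY"),
            env_element %in% c("C", "N", "O", "HEAVY"))
  keep <- (cloud$loc == "SITE" & cloud$element %in% elts(site_element)) |
          (cloud$loc == "ENV" & cloud$element %in% elts(env_element))
  out <- cloud[keep, , drop = FALSE]
  if (!is.null(neighborhood_radius) && any(out$loc == "ENV") &&
      any(out$loc == "SITE")) {
    sxyz <- as.matrix(out[out$loc == "SITE", c("x", "y", "z")])
    exyz <- as.matrix(out[out$loc == "ENV", c("x", "y", "z")])
    mind <- apply(exyz, 1, function(p) {
      sqrt(min(colSums((t(sxyz) - p)^2)))
    })
    drop_env <- which(out$loc == "ENV")[mind > neighborhood_radius]
    if (length(drop_env)) out <- out[-drop_env, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "neighborhood_radius") <- neighborhood_radius
  class(out) <- c("atom_cloud", "data.frame")
  out
}

#' Coordinates of an atom cloud as a matrix
#' @param cloud `atom_cloud`
#' @export
cloud_coords <- function(cloud) {
  as.matrix(cloud[, c("x", "y", "z")])
}

#' Interior/surface classification of a residue by relative accessible
#' surface area
#'
#' A residue is interior (buried) iff its rASA falls strictly below the
#' cutoff; the default cutoff is 25%.
#'
#' @param rasa relative accessible surface area, a fraction in \[0, 1\]
#' @param cutoff classification cutoff (fraction)
#' @return character vector in \{"interior", "surface"\}
#' @export
classify_region <- function(rasa, cutoff = 0.25) {
  if (any(rasa < 0 | rasa > 1)) stop("rASA must lie in [0, 1]")
  ifelse(rasa < cutoff, "interior", "surface")
}

#' Per-residue relative accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe (1.4 Angstrom) accessible surface computed on heavy atoms
#' with a deterministic golden-spiral point set, normalized by the
#' theoretical Gly-X-Gly maxima.  Adequate for fixture-scale structures;
#' for production use a dedicated SASA tool and [read_rasa_table()].
#'
#' @param atoms `atom_cloud`
#' @param probe probe radius in Angstrom
#' @param n_points sphere sample points per atom
#' @return data.frame with `chain`, `resseq`, `resname`, `rasa`
#' @export
compute_rasa <- function(atoms, probe = 1.4, n_points = 240) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- VDW_RADIUS[atoms$element]
  rad[is.na(rad)] <- 1.7
  # golden-spiral unit sphere
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sphere <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  n <- nrow(xyz)
  area <- numeric(n)
  for (a in seq_len(n)) {
    ra <- rad[a] + probe
    pts <- sweep(sphere * ra, 2, xyz[a, ], "+")
    d2 <- colSums((t(xyz) - xyz[a, ])^2)
    nb <- which(d2 > 0 & sqrt(d2) < ra + rad + probe)
    exposed <- rep(TRUE, n_points)
    for (b in nb) {
      rb <- rad[b] + probe
      db2 <- colSums((t(pts) - xyz[b, ])^2)
      exposed <- exposed & db2 >= rb^2
      if (!any(exposed)) break
    }
    area[a] <- 4 * pi * ra^2 * sum(exposed) / n_points
  }
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "|")
  agg <- tapply(area, key, sum)
  first <- !duplicated(key)
  out <- data.frame(
    chain = atoms$chain[first], resseq = atoms$resseq[first],
    resname = atoms$resname[first],
    asa = as.numeric(agg[paste(atoms$chain[first], atoms$resseq[first],
                               atoms$icode[first], sep = "|")]),
    stringsAsFactors = FALSE
  )
  maxasa <- MAX_ASA[out$resname]
  maxasa[is.na(maxasa)] <- mean(MAX_ASA)
  out$rasa <- pmin(out$asa / maxasa, 1)
  out$asa <- NULL
  rownames(out) <- NULL
  out
}

#' Read a precomputed rASA table
#'
#' Tab-separated columns: chain, residue number, rASA fraction.
#'
#' @param path input file
#' @export
read_rasa_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chain", "resseq", "rasa"),
                          colClasses = c("character", "integer", "numeric"))
  if (any(df$rasa < 0 | df$rasa > 1)) stop("rASA values must lie in [0, 1]")
  df
}
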