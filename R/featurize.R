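ELEMENT_PAIRS <- expand.grid(site = c("C", "N", "O"),
                             env = c("C", "N", "O"),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)[, c("site", "env")]
# site-major order: C-C, C-N, C-O, N-C, ...
ELEMENT_PAIRS <- ELEMENT_PAIRS[order(ELEMENT_PAIRS$site, ELEMENT_PAIRS$env), ]
rownames(ELEMENT_PAIRS) <- NULL

NONHARMONIC_STATS <- c("count", "sum", "min", "max", "mean", "std", "var",
                       "sumsq")
BAR_STATS <- c("len_sum", "len_max", "len_mean", "birth_min", "birth_max",
               "death_min", "death_max")

#' The 54 persistent-spectra set specifications
#'
#' Enumerates protein tag (wild/mutant) x site element x environment element
#' over the three featurization modes: interactive-distance Rips at
#' dimension 0, and Euclidean alpha filtrations at dimensions 1 and 2.
#'
#' @return data.frame with columns `protein`, `mode`, `site_element`,
#'   `env_element` (54 rows)
#' @export
pair_specs <- function() {
  out <- do.call(rbind, lapply(
    c("DI-rips-dim0", "DE-alpha-dim1", "DE-alpha-dim2"),
    function(mode) {
      do.call(rbind, lapply(c("W", "M"), function(g) {
        data.frame(protein = g, mode = mode,
                   site_element = ELEMENT_PAIRS$site,
                   env_element = ELEMENT_PAIRS$env,
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(out) <- NULL
  out
}

#' Interactive distance matrix of a labeled atom cloud
#'
#' Infinite between atoms sharing a location class (both in the mutation
#' site, or both in the environment; the diagonal is infinite since an atom
#' shares its own location), Euclidean in Angstrom otherwise.  A Rips
#' filtration over this matrix therefore encodes only site--environment
#' interactions.
#'
#' @param cloud labeled `atom_cloud` (with `loc` column)
#' @return symmetric matrix with `Inf` entries
#' @export
interactive_distance <- function(cloud) {
  stopifnot(nrow(cloud) >= 1, "loc" %in% names(cloud))
  xyz <- cloud_coords(cloud)
  D <- as.matrix(stats::dist(xyz))
  same <- outer(cloud$loc, cloud$loc, "==")
  D[same] <- Inf
  D
}

#' Non-harmonic spectrum statistics
#'
#' The eight summary values of the strictly positive eigenvalues of a
#' Laplacian spectrum: count, sum, minimum, maximum, mean, standard
#' deviation, variance and the sum of squared eigenvalues (population
#' moments).  An empty or all-harmonic spectrum gives the all-zero vector.
#'
#' @param eigs numeric vector of eigenvalues
#' @param tol relative zero threshold separating harmonic from non-harmonic
#' @return named 8-vector
#' @export
stats_nonharmonic <- function(eigs, tol = 1e-8) {
  out <- stats::setNames(numeric(8), NONHARMONIC_STATS)
  if (length(eigs) == 0) return(out)
  thr <- tol * max(1, max(abs(eigs)))
  nh <- eigs[eigs > thr]
  if (length(nh) == 0) return(out)
  m <- mean(nh)
  v <- mean((nh - m)^2)
  out[] <- c(length(nh), sum(nh), min(nh), max(nh), m, sqrt(v), v,
             sum(nh^2))
  out
}

#' Persistence-bar statistics
#'
#' Seven summaries of a (pre-filtered) barcode: sum, maximum and mean of
#' bar lengths; minimum and maximum birth; minimum and maximum death.
#' Infinite bars are excluded; if only infinite bars remain, their births
#' feed the birth statistics and the length/death entries are zero.  An
#' empty barcode gives the all-zero vector.
#'
#' @param bars `barcode` data.frame, already filtered by the 0.1 Angstrom
#'   rule where applicable
#' @return named 7-vector
#' @export
stats_bars <- function(bars) {
  out <- stats::setNames(numeric(7), BAR_STATS)
  if (nrow(bars) == 0) return(out)
  fin <- bars[is.finite(bars$death), , drop = FALSE]
  if (nrow(fin) == 0) {
    out["birth_min"] <- min(bars$birth)
    out["birth_max"] <- max(bars$birth)
    return(out)
  }
  len <- fin$death - fin$birth
  out[] <- c(sum(len), max(len), mean(len), min(fin$birth), max(fin$birth),
             min(fin$death), max(fin$death))
  out
}

spectrum_over_grid_for_pair <- function(cloud, site_element, env_element,
                                        grid, neighborhood_radius) {
  sel <- select_cloud(cloud, site_element, env_element,
                      neighborhood_radius = neighborhood_radius)
  if (nrow(sel) == 0) {
    return(replicate(length(grid), numeric(0), simplify = FALSE))
  }
  D <- interactive_distance(sel)
  snaps <- rips_snapshots(D, grid = grid, max_dim = 1)
  spectra_over_filtration(snaps, k = 0)$spectra
}

#' 0-dimensional persistent-Laplacian feature block
#'
#' For each protein (wild, mutant), each filtration grid value and each of
#' the nine site/environment element pairs, the eight non-harmonic spectrum
#' statistics of the dimension-0 Laplacian of the interactive-distance Rips
#' complex.  Layout: protein-major, then grid value, then element pair,
#' then statistic; 2 x 13 x 9 x 8 = 1872 components at the default grid.
#'
#' @param wild,mutant labeled `atom_cloud`s (see [label_site()])
#' @param grid filtration grid, see [filtration_grid()]
#' @param neighborhood_radius environment restriction in Angstrom
#' @return named numeric vector of class `feature_block`
#' @export
pl_block_0dim <- function(wild, mutant, grid = filtration_grid(),
                          neighborhood_radius = 12) {
  clouds <- list(W = wild, M = mutant)
  vals <- numeric(0)
  labels <- character(0)
  for (g in names(clouds)) {
    # spectra computed once per pair, reused across the grid
    per_pair <- lapply(seq_len(nrow(ELEMENT_PAIRS)), function(p) {
      spectrum_over_grid_for_pair(clouds[[g]],
                                  ELEMENT_PAIRS$site[p], ELEMENT_PAIRS$env[p],
                                  grid, neighborhood_radius)
    })
    for (fi in seq_along(grid)) {
      for (p in seq_len(nrow(ELEMENT_PAIRS))) {
        st <- stats_nonharmonic(per_pair[[p]][[fi]])
        vals <- c(vals, st)
        labels <- c(labels, sprintf("PL0.%s.f%.1f.%s-%s.%s", g, grid[fi],
                                    ELEMENT_PAIRS$site[p],
                                    ELEMENT_PAIRS$env[p],
                                    NONHARMONIC_STATS))
      }
    }
  }
  new_feature_block("PL-0dim", vals, labels,
                    metadata = list(grid = grid,
                                    neighborhood_radius = neighborhood_radius))
}

highdim_stats_per_protein <- function(cloud, neighborhood_radius,
                                      min_bar_length = 0.1) {
  selections <- rbind(ELEMENT_PAIRS,
                      data.frame(site = "HEAVY", env = "HEAVY"))
  vals <- numeric(0)
  labels <- character(0)
  for (p in seq_len(nrow(selections))) {
    sel <- select_cloud(cloud, selections$site[p], selections$env[p],
                        neighborhood_radius = neighborhood_radius)
    bars <- if (nrow(sel) >= 3) {
      filter_bars(alpha_barcode(cloud_coords(sel), max_dim = 2),
                  min_bar_length)
    } else {
      new_barcode(data.frame(dimension = integer(0), birth = numeric(0),
                             death = numeric(0)))
    }
    for (k in 1:2) {
      st <- stats_bars(bars[bars$dimension == k, , drop = FALSE])
      vals <- c(vals, st)
      labels <- c(labels, sprintf("%s-%s.dim%d.%s", selections$site[p],
                                  selections$env[p], k, BAR_STATS))
    }
  }
  list(values = vals, labels = labels)
}

#' Higher-dimensional persistent-Laplacian feature block
#'
#' Harmonic (barcode) statistics of the Euclidean alpha filtration at
#' homology dimensions 1 and 2, on the nine element pairs plus the
#' heavy-atom pair, with the 0.1 Angstrom bar filter: 10 x 2 x 7 = 140 per
#' protein, concatenated for wild type, mutant and their difference (420).
#'
#' @inheritParams pl_block_0dim
#' @param min_bar_length bar filter threshold in Angstrom
#' @export
pl_block_highdim <- function(wild, mutant, neighborhood_radius = 12,
                             min_bar_length = 0.1) {
  w <- highdim_stats_per_protein(wild, neighborhood_radius, min_bar_length)
  m <- highdim_stats_per_protein(mutant, neighborhood_radius, min_bar_length)
  vals <- c(w$values, m$values, w$values - m$values)
  labels <- c(paste0("PLH.W.", w$labels), paste0("PLH.M.", m$labels),
              paste0("PLH.D.", w$labels))
  new_feature_block("PL-highdim", vals, labels,
                    metadata = list(neighborhood_radius = neighborhood_radius,
                                    min_bar_length = min_bar_length))
}

ph_bins <- function(grid_max = 6, width = 0.5, n = 12) {
  left <- seq(0, by = width, length.out = n)
  cbind(left = left, right = left + width)
}

ph_stats_per_protein <- function(cloud, grid_max, neighborhood_radius,
                                 min_bar_length = 0.1) {
  bins <- ph_bins(grid_max)
  vals <- numeric(0)
  labels <- character(0)
  for (p in seq_len(nrow(ELEMENT_PAIRS))) {
    sel <- select_cloud(cloud, ELEMENT_PAIRS$site[p], ELEMENT_PAIRS$env[p],
                        neighborhood_radius = neighborhood_radius)
    if (nrow(sel) > 0) {
      bars <- filter_bars(rips_diagram0(interactive_distance(sel)),
                          min_bar_length)
      death <- pmin(bars$death, grid_max)  # essential bars capped at grid max
      birth <- bars$birth
    } else {
      death <- birth <- numeric(0)
    }
    for (b in seq_len(nrow(bins))) {
      lo <- bins[b, "left"]; hi <- bins[b, "right"]
      in_bin <- if (b == 1) death >= lo & death <= hi else death > lo & death <= hi
      persisting <- birth <= lo & death >= hi
      vals <- c(vals, sum(death[in_bin]), sum(persisting))
      labels <- c(labels, sprintf("%s-%s.bin%02d.%s", ELEMENT_PAIRS$site[p],
                                  ELEMENT_PAIRS$env[p], b,
                                  c("death_sum", "bar_count")))
    }
  }
  list(values = vals, labels = labels)
}

#' Persistent-homology feature block
#'
#' Binned summary of the dimension-0 bars of the interactive-distance Rips
#' filtration: over 12 half-Angstrom bins and the nine element pairs, the
#' summed death values of bars dying in each bin and the count of bars
#' persisting through it (216 per protein); concatenated for wild type,
#' mutant and their difference (648).  Essential bars are assigned the grid
#' maximum as death for binning.
#'
#' @inheritParams pl_block_0dim
#' @param grid_max upper end of the binned filtration range in Angstrom
#' @export
ph_block <- function(wild, mutant, grid_max = 6, neighborhood_radius = 12) {
  w <- ph_stats_per_protein(wild, grid_max, neighborhood_radius)
  m <- ph_stats_per_protein(mutant, grid_max, neighborhood_radius)
  vals <- c(w$values, m$values, w$values - m$values)
  labels <- c(paste0("PH.W.", w$labels), paste0("PH.M.", m$labels),
              paste0("PH.D.", w$labels))
  new_feature_block("PH", vals, labels,
                    metadata = list(grid_max = grid_max,
                                    neighborhood_radius = neighborhood_radius))
}

new_feature_block <- function(name, values, labels, metadata = list()) {
  stopifnot(length(values) == length(labels))
  structure(stats::setNames(as.numeric(values), labels),
            block = name, metadata = metadata, class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature block '%s': %d components\n", attr(x, "block"),
              length(x)))
  invisible(x)
}

#' Deterministic stand-in for the sequence-transformer embedding
#'
#' The production interface expects a 1280-component per-sequence vector
#' (final-layer mean of a protein language model).  This stub hashes the
#' sequence into a reproducible pseudo-random 1280-vector so pipelines and
#' tests run without model weights; it carries no biological signal.
#'
#' @param sequence amino-acid string
#' @param dim embedding width
#' @return numeric vector of length `dim`
#' @export
transformer_stub <- function(sequence, dim = 1280) {
  codes <- utf8ToInt(sequence)
  h <- 7
  for (v in codes) h <- (h * 131 + v) %% 2147483629
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(h))
  stats::rnorm(dim)
}

#' One-letter sequence of an atom cloud
#' @param atoms `atom_cloud`
#' @export
cloud_sequence <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "|")
  first <- !duplicated(key)
  aa <- AA1[atoms$resname[first]]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Assemble a fixed-layout feature vector
#'
#' Concatenates the feature blocks in a fixed order with a named schema.
#' The `"toplap"` configuration is PL (0-dim + high-dim) + transformer +
#' auxiliary; `"topgbt"` replaces the PL blocks with the PH embedding.
#'
#' @param pl0 0-dim PL block ([pl_block_0dim()]), required for "toplap"
#' @param plhigh high-dim PL block ([pl_block_highdim()]), required for
#'   "toplap"
#' @param ph PH block ([ph_block()]), required for "topgbt"
#' @param transformer numeric 1280-vector (or any fixed width declared via
#'   `transformer_dim`)
#' @param auxiliary optional numeric vector of precomputed physicochemical
#'   features
#' @param config `"toplap"` or `"topgbt"`
#' @param transformer_dim expected transformer width
#' @return named numeric vector of class `feature_vector` with a `schema`
#'   attribute
#' @export
assemble <- function(pl0 = NULL, plhigh = NULL, ph = NULL,
                     transformer = NULL, auxiliary = NULL,
                     config = c("toplap", "topgbt"),
                     transformer_dim = 1280) {
  config <- match.arg(config)
  if (!is.null(transformer) && length(transformer) != transformer_dim) {
    stop(sprintf("transformer block must have %d components, got %d",
                 transformer_dim, length(transformer)))
  }
  blocks <- list()
  if (config == "toplap") {
    if (is.null(pl0) || is.null(plhigh)) {
      stop("the toplap configuration needs the PL blocks")
    }
    blocks[["PL-0dim"]] <- pl0
    blocks[["PL-highdim"]] <- plhigh
  } else {
    if (is.null(ph)) stop("the topgbt configuration needs the PH block")
    blocks[["PH"]] <- ph
  }
  if (!is.null(transformer)) {
    nm <- names(transformer)
    if (is.null(nm)) nm <- sprintf("ESM.%04d", seq_along(transformer))
    blocks[["transformer"]] <- stats::setNames(as.numeric(transformer), nm)
  }
  if (!is.null(auxiliary)) {
    nm <- names(auxiliary)
    if (is.null(nm)) nm <- sprintf("AUX.%03d", seq_along(auxiliary))
    blocks[["auxiliary"]] <- stats::setNames(as.numeric(auxiliary), nm)
  }
  vec <- unlist(blocks, use.names = FALSE)
  names(vec) <- unlist(lapply(blocks, names), use.names = FALSE)
  schema <- data.frame(
    block = rep(names(blocks), vapply(blocks, length, 0L)),
    component = names(vec),
    stringsAsFactors = FALSE
  )
  structure(vec, schema = schema, config = config, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("feature vector (%s): %d components\n", attr(x, "config"),
              length(x)))
  print(table(sch$block)[unique(sch$block)])
  invisible(x)
}

#' Featurize a wild-type/mutant structure pair
#'
#' End-to-end: parse both PDB files, resolve the mutation site, and compute
#' the topological feature blocks plus the (stub or provided) transformer
#' embedding.
#'
#' @param wild_path,mutant_path PDB file paths
#' @param mutation `mutation_spec` or compact string (e.g. `"A:I283W"`)
#' @param grid filtration grid for the 0-dim features
#' @param neighborhood_radius environment restriction in Angstrom
#' @param transformer optional externally supplied 1280-vector for the
#'   (wild, mutant) pair; the deterministic stub on the wild sequence is
#'   used when omitted
#' @param auxiliary optional auxiliary vector
#' @param config `"toplap"` or `"topgbt"`
#' @return `feature_vector`
#' @export
featurize_pair <- function(wild_path, mutant_path, mutation,
                           grid = filtration_grid(),
                           neighborhood_radius = 12,
                           transformer = NULL, auxiliary = NULL,
                           config = "toplap") {
  spec <- mutation_spec(mutation)
  wild <- label_site(parse_pdb(wild_path), spec)
  mutant <- label_site(parse_pdb(mutant_path), spec, check_wild = FALSE)
  if (is.null(transformer)) {
    transformer <- transformer_stub(cloud_sequence(wild))
  }
  if (config == "toplap") {
    assemble(pl0 = pl_block_0dim(wild, mutant, grid, neighborhood_radius),
             plhigh = pl_block_highdim(wild, mutant, neighborhood_radius),
             transformer = transformer, auxiliary = auxiliary,
             config = "toplap")
  } else {
    assemble(ph = ph_block(wild, mutant,
                           grid_max = max(grid),
                           neighborhood_radius = neighborhood_radius),
             transformer = transformer, auxiliary = auxiliary,
             config = "topgbt")
  }
}

#' Write a feature matrix as CSV with a JSON sidecar schema
#'
#' @param features a `feature_vector`, or a list of them (rows)
#' @param path output CSV path; the sidecar is written next to it with
#'   extension `.json`
#' @param ids optional row ids
#' @export
write_features <- function(features, path, ids = NULL) {
  if (inherits(features, "feature_vector")) features <- list(features)
  mat <- do.call(rbind, lapply(features, as.numeric))
  colnames(mat) <- names(features[[1]])
  df <- data.frame(sample_id = ids %||% sprintf("s%03d", seq_len(nrow(mat))),
                   mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  meta <- list(config = attr(features[[1]], "config"),
               n_components = ncol(mat),
               blocks = as.list(table(attr(features[[1]], "schema")$block)))
  writeLines(to_json(meta), sidecar)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal JSON emitter for sidecar metadata (flat lists / scalars)
to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.list(x)) {
    paste0("{", paste(sprintf('"%s": %s', esc(names(x)),
                              vapply(x, to_json, "")), collapse = ", "), "}")
  } else if (is.character(x)) {
    if (length(x) == 1) sprintf('"%s"', esc(x)) else {
      paste0("[", paste(sprintf('"%s"', esc(x)), collapse = ", "), "]")
    }
  } else {
    if (length(x) == 1) format(x, digits = 15) else {
      paste0("[", paste(format(x, digits = 15), collapse = ", "), "]")
    }
  }
}

#' Read a provider table of per-sample embedding vectors
#'
#' Format: `sample_id<TAB>v1,v2,...,vk` per line.
#'
#' @param path input file
#' @return named list of numeric vectors
#' @export
read_embedding_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) as.numeric(strsplit(p[2], ",")[[1]]))
  names(out) <- vapply(parts, `[[`, "", 1)
  out
}
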