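# Independent oracles used across the suite.  Everything here is brute
# force and written against the definitions, not against the package's
# implementation paths.

# --- plain-R persistence by column reduction over GF(2) -------------------
# simplices: list of integer vectors; filt: numeric; returns data.frame
# (dimension, birth, death) including infinite bars, zero-length dropped.
oracle_persistence <- function(simplices, filt, maxdim_report = 2) {
  dims <- vapply(simplices, length, 0L) - 1L
  keys <- vapply(simplices, function(v) paste(sort(v), collapse = ","), "")
  ord <- order(filt, dims, keys)
  simplices <- simplices[ord]
  filt <- filt[ord]
  dims <- dims[ord]
  keys <- keys[ord]
  idx <- seq_along(simplices)
  names(idx) <- keys
  ns <- length(simplices)
  cols <- vector("list", ns)
  pivot_owner <- integer(0)
  paired <- rep(FALSE, ns)
  negative <- rep(FALSE, ns)
  bars <- list()
  for (j in seq_len(ns)) {
    v <- sort(simplices[[j]])
    col <- integer(0)
    if (length(v) > 1) {
      col <- sort(vapply(seq_along(v), function(i) {
        idx[[paste(v[-i], collapse = ",")]]
      }, 0L))
    }
    repeat {
      if (length(col) == 0) break
      low <- max(col)
      owner <- if (as.character(low) %in% names(pivot_owner)) {
        pivot_owner[[as.character(low)]]
      } else NA_integer_
      if (is.na(owner)) break
      col <- sort(union(setdiff(col, cols[[owner]]),
                        setdiff(cols[[owner]], col)))
    }
    if (length(col) > 0) {
      low <- max(col)
      pivot_owner[as.character(low)] <- j
      cols[[j]] <- col
      paired[low] <- TRUE
      negative[j] <- TRUE
      bars[[length(bars) + 1]] <- c(dims[low], filt[low], filt[j])
    }
  }
  for (s in seq_len(ns)) {
    if (!paired[s] && !negative[s] && dims[s] <= maxdim_report) {
      bars[[length(bars) + 1]] <- c(dims[s], filt[s], Inf)
    }
  }
  df <- as.data.frame(do.call(rbind, bars))
  names(df) <- c("dimension", "birth", "death")
  df <- df[df$death > df$birth & df$dimension <= maxdim_report, , drop = FALSE]
  df[order(df$dimension, df$birth, df$death), , drop = FALSE]
}

# Cech filtration in plain R for tiny clouds (min enclosing ball radius by
# brute force over support subsets), independent of the C++ path
oracle_cech_bars <- function(coords, maxdim_report = 2) {
  n <- nrow(coords)
  minball_r <- function(P) {
    m <- nrow(P)
    if (m == 1) return(0)
    best <- Inf
    contains <- function(c0, r2) {
      all(colSums((t(P) - c0)^2) <= r2 * (1 + 1e-9) + 1e-9)
    }
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      c0 <- (P[i, ] + P[j, ]) / 2
      r2 <- sum((P[i, ] - P[j, ])^2) / 4
      if (contains(c0, r2) && r2 < best) best <- r2
    }
    if (m >= 3) {
      cmb <- utils::combn(m, 3)
      for (t in seq_len(ncol(cmb))) {
        a <- P[cmb[1, t], ]; b <- P[cmb[2, t], ]; p <- P[cmb[3, t], ]
        u <- b - a; v <- p - a
        uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
        det <- uu * vv - uv * uv
        if (det < 1e-12 * max(uu * vv, 1)) next
        al <- (uu * vv - vv * uv) / (2 * det)
        be <- (uu * vv - uu * uv) / (2 * det)
        c0 <- a + al * u + be * v
        r2 <- sum((c0 - a)^2)
        if (contains(c0, r2) && r2 < best) best <- r2
      }
    }
    if (m == 4) {
      A <- rbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])
      rhs <- rowSums(A^2) / 2
      if (abs(det(A)) > 1e-10) {
        x <- solve(A, rhs)
        r2 <- sum(x^2)
        c0 <- P[1, ] + x
        if (contains(c0, r2) && r2 < best) best <- r2
      }
    }
    sqrt(best)
  }
  simplices <- list(); filt <- numeric(0)
  for (m in 1:min(4, n)) {
    cmb <- utils::combn(n, m)
    for (t in seq_len(ncol(cmb))) {
      v <- cmb[, t]
      simplices[[length(simplices) + 1]] <- v
      filt <- c(filt, minball_r(coords[v, , drop = FALSE]))
    }
  }
  # enforce monotonicity the same way any filtration must satisfy it
  key <- vapply(simplices, paste, "", collapse = ",")
  for (s in order(vapply(simplices, length, 0L))) {
    v <- simplices[[s]]
    if (length(v) > 1) {
      for (i in seq_along(v)) {
        f <- match(paste(v[-i], collapse = ","), key)
        filt[s] <- max(filt[s], filt[f])
      }
    }
  }
  oracle_persistence(simplices, filt, maxdim_report)
}

# --- union-find component count over a graph ------------------------------
oracle_components <- function(n_vertices, edges) {
  parent <- seq_len(n_vertices)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(edges)) {
    for (e in edges) {
      ri <- find(e[1]); rj <- find(e[2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  length(unique(vapply(seq_len(n_vertices), find, 0L)))
}

# --- naive per-element metric computation ---------------------------------
oracle_metrics <- function(cm) {
  n <- sum(cm); k <- nrow(cm)
  res <- list()
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- n - tp - fn - fp
    div <- function(a, b) if (b == 0) 0 else a / b
    res[[i]] <- c(PPV = div(tp, tp + fp), NPV = div(tn, tn + fn),
                  sensitivity = div(tp, tp + fn),
                  specificity = div(tn, tn + fp))
  }
  cpr <- sum(diag(cm)) / n
  chi2 <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    e <- sum(cm[i, ]) * sum(cm[, j]) / n
    if (e > 0) chi2 <- chi2 + (cm[i, j] - e)^2 / e
  }
  list(per_class = do.call(rbind, res), CPR = cpr, GC2 = chi2 / (n * (k - 1)))
}

# --- random face-closed complex generator ---------------------------------
random_complex <- function(seed, n_vertices = 6, n_generators = 5,
                           max_gen_size = 4) {
  set.seed(seed)
  gens <- lapply(seq_len(n_generators), function(i) {
    sample(n_vertices, sample(2:max_gen_size, 1))
  })
  simplicial_complex(gens)
}

random_confusion <- function(seed, k = 3, lambda = 30) {
  set.seed(seed)
  cm <- matrix(rpois(k * k, lambda), k, k)
  # guarantee positive row sums so normalization is defined
  diag(cm) <- diag(cm) + 1
  cm
}

peptide_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_peptide_pdb(6, 3, seed = 11)
      fx$wild_atoms <- label_site(parse_pdb(fx$wild), fx$spec)
      fx$mutant_atoms <- label_site(parse_pdb(fx$mutant), fx$spec,
                                    check_wild = FALSE)
      cache <<- fx
    }
    cache
  }
})
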