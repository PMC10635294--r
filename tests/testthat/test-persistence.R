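test_that("Rips snapshots: thresholds inclusive, infinities respected", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  snaps <- rips_snapshots(D, grid = c(0.5, 1.0))
  expect_equal(n_simplices(snaps[[1]], 0), 2)
  expect_equal(n_simplices(snaps[[1]], 1), 0)
  expect_equal(n_simplices(snaps[[2]], 1), 1)   # edge appears at f = distance

  Dinf <- matrix(Inf, 3, 3); diag(Dinf) <- 0
  for (K in rips_snapshots(Dinf, grid = filtration_grid())) {
    expect_equal(n_simplices(K, 1), 0)
  }
})

test_that("snapshots are nested along the grid", {
  set.seed(5)
  D <- as.matrix(dist(matrix(runif(30, 0, 4), ncol = 3)))
  snaps <- rips_snapshots(D, grid = filtration_grid(), max_dim = 2)
  for (t in seq_len(length(snaps) - 1)) {
    for (k in 0:2) {
      a <- simplices(snaps[[t]], k)
      b <- simplices(snaps[[t + 1]], k)
      if (nrow(a) == 0) next
      keys_a <- apply(a, 1, paste, collapse = ",")
      keys_b <- apply(b, 1, paste, collapse = ",")
      expect_true(all(keys_a %in% keys_b))
    }
  }
})

test_that("spectra over filtration match hand-computed values", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  prof <- spectra_over_filtration(rips_snapshots(D, grid = c(0.5, 1.0)))
  expect_equal(prof$spectra[[1]], c(0, 0))
  expect_equal(prof$spectra[[2]], c(0, 2))

  # unit square at f = 1: the 4-cycle graph, spectrum {0, 2, 2, 4}
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  prof <- spectra_over_filtration(rips_snapshots(as.matrix(dist(sq)),
                                                 grid = 1.0))
  expect_equal(prof$spectra[[1]], c(0, 2, 2, 4), tolerance = 1e-12)
})

test_that("harmonic count at each snapshot equals the barcode Betti number", {
  set.seed(9)
  pts <- matrix(runif(36, 0, 3), ncol = 3)
  D <- as.matrix(dist(pts))
  grid <- filtration_grid(0, 3, 0.5)
  prof <- spectra_over_filtration(rips_snapshots(D, grid))
  bars <- rips_diagram0(D)
  for (t in seq_along(grid)) {
    harmonic <- sum(prof$spectra[[t]] < 1e-8)
    expect_equal(harmonic, betti_from_barcode(bars, 0, grid[t]))
  }
})

test_that("alpha barcode: known shapes", {
  hex <- make_topology_cloud("ring6", scale = 1.5)
  b <- alpha_barcode(hex, max_dim = 2)
  b1 <- b[b$dimension == 1, ]
  expect_equal(nrow(b1), 1)               # exactly one ring
  expect_equal(b1$birth, 0.75, tolerance = 1e-9)   # half edge length
  expect_equal(b1$death, 1.5, tolerance = 1e-9)    # circumradius

  single <- matrix(c(0, 0, 0), 1, 3)
  b <- alpha_barcode(single, max_dim = 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$dimension, 0L)
  expect_true(is.infinite(b$death))

  # coincident points collapse to a single essential component
  coin <- matrix(0, 4, 3)
  b <- alpha_barcode(coin, max_dim = 1)
  expect_equal(sum(is.infinite(b$death)), 1)
  expect_equal(nrow(b[b$dimension == 1, ]), 0)

  tet <- make_topology_cloud("tetra_shell", scale = 2)
  b2 <- alpha_barcode(tet, max_dim = 2)
  b2 <- b2[b2$dimension == 2, ]
  expect_equal(nrow(b2), 1)
  expect_equal(b2$birth, 2 / sqrt(3), tolerance = 1e-9)
  expect_equal(b2$death, 2 * sqrt(3 / 8), tolerance = 1e-9)
})

test_that("alpha/Cech persistence agrees with the plain-R reduction oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:12, 1)
    pts <- matrix(runif(3 * n, 0, 3), ncol = 3)
    got <- alpha_barcode(pts, max_dim = 2)
    want <- oracle_cech_bars(pts, maxdim_report = 2)
    expect_equal(nrow(got), nrow(want))
    for (k in 0:2) {
      g <- got[got$dimension == k, ]
      w <- want[want$dimension == k, ]
      expect_equal(g$birth, w$birth, tolerance = 1e-6)
      expect_equal(g$death, w$death, tolerance = 1e-6)
    }
  }
})

test_that("0-dim Rips diagram matches full reduction on distance matrices", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:9, 1)
    pts <- matrix(runif(3 * n, 0, 4), ncol = 3)
    D <- as.matrix(dist(pts))
    got <- rips_diagram0(D)
    # oracle: vertices + edges with pair distance as filtration
    simp <- lapply(seq_len(n), function(i) i)
    filt <- rep(0, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      simp[[length(simp) + 1]] <- c(i, j)
      filt <- c(filt, D[i, j])
    }
    want <- oracle_persistence(simp, filt, maxdim_report = 0)
    expect_equal(sort(got$death[is.finite(got$death)]),
                 sort(want$death[is.finite(want$death)]), tolerance = 1e-12)
    expect_equal(sum(is.infinite(got$death)), sum(is.infinite(want$death)))
  }
})

test_that("bar filtering follows the strict shorter-than rule", {
  bars <- structure(data.frame(
    dimension = c(1L, 1L, 1L, 0L),
    birth = c(0, 0, 0.5, 0),
    death = c(0.05, 0.1, 2.5, Inf)
  ), class = c("barcode", "data.frame"))
  f <- filter_bars(bars)
  expect_equal(nrow(f), 3)                    # 0.05-long bar removed
  expect_true(any(f$death == 0.1))            # boundary kept
  expect_true(any(is.infinite(f$death)))      # infinite kept
  empty <- bars[0, ]
  expect_equal(nrow(filter_bars(empty)), 0)
})

test_that("barcode text round trip", {
  bars <- alpha_barcode(make_topology_cloud("ring6", 1.5), max_dim = 1)
  path <- tempfile(fileext = ".tsv")
  write_barcode(bars, path)
  back <- read_barcode(path)
  expect_equal(back$dimension, bars$dimension)
  expect_equal(back$birth, bars$birth, tolerance = 1e-9)
  expect_equal(back$death, bars$death, tolerance = 1e-9)
})
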