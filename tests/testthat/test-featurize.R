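test_that("interactive distance: infinity within a location class", {
  cloud <- data.frame(
    element = c("C", "C", "O"),
    x = c(0, 1, 3), y = 0, z = 0,
    loc = c("SITE", "SITE", "ENV")
  )
  class(cloud) <- c("atom_cloud", "data.frame")
  D <- interactive_distance(cloud)
  expect_true(all(is.infinite(diag(D))))
  expect_equal(D[1, 3], 3)         # cross pair: Euclidean
  expect_equal(D[2, 3], 2)
  expect_true(is.infinite(D[1, 2]))  # same-location pair
})

test_that("non-harmonic statistics: arithmetic and conventions", {
  expect_equal(unname(stats_nonharmonic(c(0, 2))),
               c(1, 2, 2, 2, 2, 0, 0, 4))
  expect_equal(unname(stats_nonharmonic(numeric(0))), rep(0, 8))
  expect_equal(unname(stats_nonharmonic(c(0, 0, 0))), rep(0, 8))
  # two distinct eigenvalues: population std/var
  got <- stats_nonharmonic(c(0, 1, 3))
  expect_equal(unname(got),
               c(2, 4, 1, 3, 2, 1, 1, 10))
})

test_that("bar statistics follow the stated order", {
  one <- structure(data.frame(dimension = 1L, birth = 0.2, death = 1.2),
                   class = c("barcode", "data.frame"))
  expect_equal(unname(stats_bars(one)), c(1, 1, 1, 0.2, 0.2, 1.2, 1.2))
  expect_equal(unname(stats_bars(one[0, ])), rep(0, 7))
  two <- structure(data.frame(dimension = 1L, birth = c(0, 0.5),
                              death = c(1, 2.5)),
                   class = c("barcode", "data.frame"))
  expect_equal(unname(stats_bars(two)), c(3, 2, 1.5, 0, 0.5, 1, 2.5))
})

test_that("54 spectra sets enumerate: 18 per mode", {
  ps <- pair_specs()
  expect_equal(nrow(ps), 54)
  expect_equal(as.vector(table(ps$mode)), rep(18L, 3))
  expect_equal(as.vector(table(ps$protein)), rep(27L, 2))
  expect_false(any(duplicated(ps)))
})

test_that("feature block layouts match the printed constants", {
  fx <- peptide_fixture()
  pl0 <- pl_block_0dim(fx$wild_atoms, fx$mutant_atoms)
  expect_length(pl0, 1872)
  # per-protein per-snapshot sub-block: 9 pairs x 8 stats = 72
  f0 <- grepl("^PL0\\.W\\.f0\\.0\\.", names(pl0))
  expect_equal(sum(f0), 72)

  plh <- pl_block_highdim(fx$wild_atoms, fx$mutant_atoms)
  expect_length(plh, 420)
  expect_equal(sum(grepl("^PLH\\.W\\.", names(plh))), 140)

  ph <- ph_block(fx$wild_atoms, fx$mutant_atoms)
  expect_length(ph, 648)
  expect_equal(sum(grepl("^PH\\.W\\.", names(ph))), 216)
})

test_that("wild == mutant collapses the difference blocks to zero", {
  fx <- peptide_fixture()
  w <- fx$wild_atoms
  pl0 <- pl_block_0dim(w, w)
  half <- length(pl0) / 2
  expect_equal(unname(pl0[seq_len(half)]), unname(pl0[half + seq_len(half)]))
  plh <- pl_block_highdim(w, w)
  expect_equal(unname(plh[grepl("^PLH\\.D\\.", names(plh))]), rep(0, 140))
  ph <- ph_block(w, w)
  expect_equal(unname(ph[grepl("^PH\\.D\\.", names(ph))]), rep(0, 216))
})

test_that("featurization is deterministic and atom-order invariant", {
  fx <- peptide_fixture()
  w <- fx$wild_atoms; m <- fx$mutant_atoms
  a <- pl_block_0dim(w, m)
  b <- pl_block_0dim(w, m)
  expect_identical(as.numeric(a), as.numeric(b))
  set.seed(42)
  wp <- w[sample(nrow(w)), ]
  class(wp) <- class(w)
  expect_equal(as.numeric(pl_block_0dim(wp, m)), as.numeric(a),
               tolerance = 1e-10)
  expect_equal(as.numeric(pl_block_highdim(wp, m)),
               as.numeric(pl_block_highdim(w, m)), tolerance = 1e-10)
})

test_that("harmonic count is non-increasing along the grid", {
  fx <- peptide_fixture()
  grid <- filtration_grid()
  for (p in seq_len(9)) {
    site <- c("C", "N", "O")[(p - 1) %/% 3 + 1]
    env <- c("C", "N", "O")[(p - 1) %% 3 + 1]
    sel <- select_cloud(fx$wild_atoms, site, env, 12)
    if (nrow(sel) == 0) next
    prof <- spectra_over_filtration(rips_snapshots(interactive_distance(sel),
                                                   grid))
    harm <- vapply(prof$spectra, function(ev) sum(ev < 1e-8), 0)
    expect_true(all(diff(harm) <= 0))
  }
})

test_that("0-dim PH bin placement: a single cross pair", {
  cloud <- data.frame(
    element = c("C", "C"),
    x = c(0, 1.7), y = 0, z = 0,
    loc = c("SITE", "ENV")
  )
  class(cloud) <- c("atom_cloud", "data.frame")
  bars <- rips_diagram0(interactive_distance(cloud))
  expect_equal(sort(bars$death), c(1.7, Inf))
  dummy <- cloud  # wild == mutant; only the C-C pair is populated
  ph <- ph_block(dummy, dummy)
  # death 1.7 falls in bin 4 = (1.5, 2]; the essential bar (capped at 6) in bin 12
  expect_equal(unname(ph["PH.W.C-C.bin04.death_sum"]), 1.7)
  expect_equal(unname(ph["PH.W.C-C.bin12.death_sum"]), 6)
})

test_that("assemble validates widths and builds both configurations", {
  fx <- peptide_fixture()
  pl0 <- pl_block_0dim(fx$wild_atoms, fx$mutant_atoms)
  plh <- pl_block_highdim(fx$wild_atoms, fx$mutant_atoms)
  ph <- ph_block(fx$wild_atoms, fx$mutant_atoms)
  tr <- transformer_stub(fx$sequence)
  expect_length(tr, 1280)

  fv <- assemble(pl0 = pl0, plhigh = plh, transformer = tr)
  expect_length(fv, 1872 + 420 + 1280)
  expect_error(assemble(pl0 = pl0, plhigh = plh, transformer = tr[-1]),
               "1280")

  gv <- assemble(ph = ph, transformer = tr, config = "topgbt")
  sch <- attr(gv, "schema")
  expect_equal(sum(sch$block == "PH"), 648)

  aux <- c(sasa = 1.2, charge = -0.5)
  av <- assemble(pl0 = pl0, plhigh = plh, transformer = tr, auxiliary = aux)
  expect_length(av, 3572 + 2)
})

test_that("transformer stub is deterministic per sequence", {
  a <- transformer_stub("ACDEFGHIK")
  b <- transformer_stub("ACDEFGHIK")
  c2 <- transformer_stub("ACDEFGHIR")
  expect_identical(a, b)
  expect_false(identical(a, c2))
})

test_that("feature CSV + sidecar round trip and provider table reader", {
  fx <- peptide_fixture()
  fv <- featurize_pair(fx$wild, fx$mutant, fx$spec, config = "topgbt")
  path <- tempfile(fileext = ".csv")
  write_features(fv, path, ids = "pair1")
  df <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(df), 1)
  expect_equal(ncol(df), length(fv) + 1)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))

  et <- tempfile()
  writeLines(c("s1\t0.5,1.5,-2", "s2\t1,2,3"), et)
  emb <- read_embedding_table(et)
  expect_equal(emb$s1, c(0.5, 1.5, -2))
  expect_equal(names(emb), c("s1", "s2"))
})
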