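single_atom_pdb <- function(path,
                            lines = "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C") {
  writeLines(c(lines, "END"), path)
  path
}

test_that("parse_pdb: single record, elements, errors", {
  p <- single_atom_pdb(tempfile(fileext = ".pdb"))
  atoms <- parse_pdb(p)
  expect_equal(nrow(atoms), 1)
  expect_equal(atoms$element, "C")
  expect_equal(unname(unlist(atoms[1, c("x", "y", "z")])), c(0, 0, 0))

  expect_error(parse_pdb(tempfile()), "not found")
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.0     0.0     0.0",
               "END"), empty)
  expect_error(parse_pdb(empty), "no ATOM")
})

test_that("parse_pdb resolves altLocs by occupancy, first on ties", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END"), p)
  atoms <- parse_pdb(p)
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$x[atoms$name == "CA"], 1.0)   # higher occupancy wins
  expect_equal(atoms$x[atoms$name == "CB"], 2.0)   # tie: first listed
})

test_that("fixture round trip preserves counts, elements, coordinates", {
  fx <- peptide_fixture()
  atoms <- fx$wild_atoms
  # independent count of what the fixture wrote
  raw <- readLines(fx$wild)
  raw <- raw[startsWith(raw, "ATOM")]
  expect_equal(nrow(atoms), length(raw))
  expect_equal(atoms$element,
               toupper(trimws(substr(raw, 77, 78))))
  expect_equal(atoms$x, as.numeric(substr(raw, 31, 38)), tolerance = 5e-4)
})

test_that("label_site partitions atoms and validates the wild residue", {
  fx <- peptide_fixture()
  atoms <- fx$wild_atoms
  expect_true(all(atoms$loc %in% c("SITE", "ENV")))
  expect_equal(sum(atoms$loc == "SITE") + sum(atoms$loc == "ENV"),
               nrow(atoms))
  # SITE atoms are exactly those of residue 3
  expect_equal(sum(atoms$loc == "SITE"), sum(atoms$resseq == 3))

  wrong <- mutation_spec(list(chain = "A",
                              wild_aa = setdiff(c("I", "W"),
                                                fx$spec$wild_aa)[1],
                              residue_number = 3, mutant_aa = "G"))
  expect_error(label_site(parse_pdb(fx$wild), wrong), "expected")
  absent <- mutation_spec(list(chain = "A", wild_aa = "A",
                               residue_number = 99, mutant_aa = "G"))
  expect_error(label_site(parse_pdb(fx$wild), absent), "no residue")
})

test_that("mutation_spec parses the compact form and rejects identity", {
  s <- mutation_spec("A:I283W")
  expect_equal(s$chain, "A")
  expect_equal(s$wild_aa, "I")
  expect_equal(s$residue_number, 283L)
  expect_equal(s$mutant_aa, "W")
  expect_error(mutation_spec("A:I283I"), "differ")
  expect_error(mutation_spec("bogus"), "cannot parse")
})

test_that("select_cloud: elements, radius, idempotence, monotonicity", {
  fx <- peptide_fixture()
  cloud <- fx$wild_atoms
  sel <- select_cloud(cloud, "C", "O", neighborhood_radius = NULL)
  expect_true(all(sel$element[sel$loc == "SITE"] == "C"))
  expect_true(all(sel$element[sel$loc == "ENV"] == "O"))

  # ENV side without nitrogens leaves SITE nitrogens only
  no_n <- cloud[cloud$loc == "SITE" | cloud$element != "N", ]
  class(no_n) <- class(cloud)
  sel2 <- select_cloud(no_n, "N", "N", neighborhood_radius = NULL)
  expect_true(all(sel2$loc == "SITE"))

  # radius drops the far atom: ENV at 5 and 20 Angstrom, cutoff 12
  tiny <- data.frame(element = "C", x = c(0, 5, 20), y = 0, z = 0,
                     loc = c("SITE", "ENV", "ENV"))
  class(tiny) <- c("atom_cloud", "data.frame")
  expect_equal(nrow(select_cloud(tiny, "C", "C", 12)), 2)
  expect_equal(nrow(select_cloud(tiny, "C", "C", NULL)), 3)

  # idempotent and monotone in the radius
  s1 <- select_cloud(cloud, "C", "C", 8)
  s11 <- select_cloud(s1, "C", "C", 8)
  expect_equal(nrow(s1), nrow(s11))
  for (r in c(2, 5, 8, 12, 20)) {
    expect_true(nrow(select_cloud(cloud, "C", "C", r)) <=
                nrow(select_cloud(cloud, "C", "C", r + 3)))
  }
})

test_that("classify_region uses the strict 25% cutoff", {
  expect_equal(classify_region(0.10), "interior")
  expect_equal(classify_region(0.25), "surface")   # boundary is surface
  expect_equal(classify_region(0.90), "surface")
  expect_error(classify_region(1.2), "0, 1")
})

test_that("rASA: buried core vs exposed termini on a fixture", {
  fx <- peptide_fixture()
  rasa <- compute_rasa(fx$wild_atoms)
  expect_equal(nrow(rasa), 6)
  expect_true(all(rasa$rasa >= 0 & rasa$rasa <= 1))
  # an isolated residue is fully exposed
  iso <- parse_pdb(single_atom_pdb(tempfile(fileext = ".pdb")))
  expect_gt(compute_rasa(iso)$rasa, 0.2)
})

test_that("rASA table reader validates its range", {
  p <- tempfile()
  writeLines(c("A\t1\t0.12", "A\t2\t0.80"), p)
  tab <- read_rasa_table(p)
  expect_equal(tab$rasa, c(0.12, 0.80))
  expect_equal(classify_region(tab$rasa), c("interior", "surface"))
  bad <- tempfile()
  writeLines("A\t1\t1.4", bad)
  expect_error(read_rasa_table(bad), "0, 1")
})
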