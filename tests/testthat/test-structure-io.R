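# Parsing, altloc resolution, chain typing, assembly expansion, selection.

test_that("a minimal mixed file parses into typed chains and residues", {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.2, 0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 2.0, 2.4, 0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.2, -1.2, 0),
    pdb_atom_line(6, "P", "G", "B", 1, 10, 0, 0, element = "P"),
    pdb_atom_line(7, "P", "C", "B", 2, 16, 0, 0, element = "P"),
    pdb_atom_line(8, "P", "U", "B", 3, 22, 0, 0, element = "P"),
    "END")
  m <- read_trna_complex(lines, entry_id = "MINI")
  expect_identical(m$protein_chains, "A")
  expect_identical(m$trna_chains, "B")
  expect_equal(nrow(complex_residues(m)), 4)
  expect_equal(nrow(m$atoms), 8)
})

test_that("altloc resolution keeps the highest-occupancy variant", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 1, 1, 0),
    pdb_atom_line(4, "P", "G", "B", 1, 9, 0, 0, element = "P"),
    "END")
  m <- read_trna_complex(lines, entry_id = "ALTL")
  ca <- m$atoms[m$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 0)          # the occupancy-0.6 variant
  expect_equal(ca$occupancy, 0.6)
})

test_that("altloc occupancy ties break by altloc character order", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 7, 0, 0, occ = 0.5, alt = "B"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, alt = "A"),
    pdb_atom_line(3, "P", "G", "B", 1, 9, 0, 0, element = "P"),
    "END")
  m <- read_trna_complex(lines, entry_id = "TIE1")
  expect_equal(m$atoms$x[m$atoms$atom == "CA"], 0)  # altloc A wins
})

test_that("waters, ligands and unknown residues are excluded", {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "O", "HOH", "A", 101, 3, 3, 3, record = "HETATM"),
    # free glutamine substrate in the catalytic pocket
    pdb_atom_line(3, "CA", "GLN", "A", 201, 4, 4, 4, record = "HETATM"),
    pdb_atom_line(4, "P", "AMP", "A", 202, 5, 5, 5, record = "HETATM"),
    pdb_atom_line(5, "P", "G", "B", 1, 9, 0, 0, element = "P"),
    # pseudouridine stays part of the tRNA polymer
    pdb_atom_line(6, "P", "PSU", "B", 2, 15, 0, 0, record = "HETATM",
                  element = "P"),
    "END")
  m <- suppressMessages(read_trna_complex(lines, entry_id = "LIGS"))
  res <- complex_residues(m)
  expect_false(any(res$res_name == "HOH"))
  expect_identical(m$trna_chains, "B")
  expect_equal(sum(res$kind == "ribonucleotide"), 2)  # G + PSU
  expect_equal(sum(res$kind == "amino_acid"), 1)      # only the polymer ALA
  # chain typing is a partition
  expect_length(intersect(m$trna_chains, m$protein_chains), 0)
})

test_that("malformed coordinates and empty structures raise parse errors", {
  bad <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END")
  bad[1] <- sub("   0.000", "  xx.000", bad[1])
  expect_error(read_trna_complex(bad, entry_id = "BAD1"),
               "malformed coordinate.*line 1")
  expect_error(read_trna_complex(c("REMARK none", "END"), entry_id = "EMP1"),
               "empty structure")
  expect_error(read_trna_complex(c("data_1ABC", "loop_"), entry_id = "CIF1"),
               "mmCIF")
})

test_that("synthetic fixtures round-trip through write/parse", {
  bp <- complex_blueprint(12, 15, planted = tibble::tibble(
    rib = c(3, 7), aa = c(2, 9), distance = c(2.8, 3.25)), seed = 11)
  fx <- make_synthetic_complex(bp)
  m1 <- fx$model
  m2 <- read_trna_complex(write_trna_complex(m1), entry_id = m1$entry_id)
  expect_equal(nrow(complex_residues(m2)), nrow(complex_residues(m1)))
  expect_equal(m2$atoms$x, round(m1$atoms$x, 3), tolerance = 1e-9)
  expect_equal(m2$atoms$y, round(m1$atoms$y, 3), tolerance = 1e-9)
  # idempotence on a second round trip
  m3 <- read_trna_complex(write_trna_complex(m2), entry_id = m1$entry_id)
  expect_equal(m3$atoms[, c("x", "y", "z")], m2$atoms[, c("x", "y", "z")])
  expect_equal(nrow(m3$atoms), nrow(m2$atoms))
})

test_that("parsed atom counts agree with an independent PDB reader", {
  bp <- complex_blueprint(8, 10, planted = tibble::tibble(
    rib = 4, aa = 5, distance = 3.0), seed = 5)
  fx <- make_synthetic_complex(bp)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb_lines, tf)
  ref <- bio3d::read.pdb(tf, verbose = FALSE)
  expect_equal(nrow(fx$model$atoms), nrow(ref$atom))
  expect_equal(sort(unique(fx$model$atoms$chain)),
               sort(unique(ref$atom$chain)))
  expect_equal(round(fx$model$atoms$x, 3), ref$atom$x)
})

test_that("identity-only assemblies leave coordinates unchanged", {
  bp <- complex_blueprint(5, 5, seed = 2)
  fx <- make_synthetic_complex(bp)
  biomt <- list(list(chains = c("T", "A"),
                     operators = list(cbind(diag(3), c(0, 0, 0)))))
  m2 <- apply_first_assembly(fx$model, biomt)
  expect_equal(m2$assembly_index, 1L)
  expect_equal(m2$atoms[, c("x", "y", "z")],
               fx$model$atoms[, c("x", "y", "z")])
  # empty biomt: unchanged, assembly_index 0
  m3 <- apply_first_assembly(fx$model, list())
  expect_equal(m3$assembly_index, 0L)
})

test_that("a two-fold operator pair doubles chains and atoms", {
  bp <- complex_blueprint(4, 6, seed = 3)
  fx <- make_synthetic_complex(bp)
  rot2 <- cbind(diag(c(-1, -1, 1)), c(200, 0, 0))
  biomt <- list(list(chains = c("T", "A"),
                     operators = list(cbind(diag(3), c(0, 0, 0)), rot2)))
  m2 <- apply_first_assembly(fx$model, biomt)
  expect_equal(nrow(m2$atoms), 2 * nrow(fx$model$atoms))
  expect_equal(length(m2$protein_chains), 2)
  expect_equal(length(m2$trna_chains), 2)
  # only the FIRST assembly is applied
  biomt2 <- c(biomt, list(list(chains = "A",
                               operators = rep(list(cbind(diag(3), c(5, 5, 5))), 4))))
  m3 <- apply_first_assembly(fx$model, biomt2)
  expect_equal(nrow(m3$atoms), nrow(m2$atoms))
})

test_that("applying an operator then its inverse recovers coordinates", {
  bp <- complex_blueprint(6, 6, seed = 4)
  fx <- make_synthetic_complex(bp)
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(3.5, -2, 7)
  fwd <- list(list(chains = c("T", "A"), operators = list(cbind(rot, tr))))
  inv <- list(list(chains = c("T", "A"),
                   operators = list(cbind(t(rot), -t(rot) %*% tr))))
  m1 <- apply_first_assembly(fx$model, fwd)
  m2 <- apply_first_assembly(m1, inv)
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(fx$model$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("non-right-handed operators warn but are applied", {
  bp <- complex_blueprint(3, 3, seed = 6)
  fx <- make_synthetic_complex(bp)
  mirror <- list(list(chains = c("T", "A"),
                      operators = list(cbind(diag(c(-1, 1, 1)), c(0, 0, 0)))))
  expect_warning(m2 <- apply_first_assembly(fx$model, mirror),
                 "right-handed")
  expect_equal(m2$atoms$x, -fx$model$atoms$x)
})

test_that("tRNA selection follows file order and survives duplication", {
  # chains in file order D (tRNA), A (tRNA)
  lines <- c(
    pdb_atom_line(1, "P", "G", "D", 1, 0, 0, 0, element = "P"),
    pdb_atom_line(2, "P", "C", "A", 1, 40, 0, 0, element = "P"),
    "END")
  m <- read_trna_complex(lines, entry_id = "TWO1")
  expect_identical(select_trna(m), "D")

  # symmetry-duplicated tRNA: original chain stays selected, and the
  # interface counts are identical from either copy
  bp <- complex_blueprint(6, 8, planted = tibble::tibble(
    rib = c(2, 4), aa = c(3, 6), distance = c(2.6, 3.1)), seed = 9)
  fx <- make_synthetic_complex(bp)
  rot2 <- cbind(diag(c(-1, -1, 1)), c(500, 0, 0))
  biomt <- list(list(chains = c("T", "A"),
                     operators = list(cbind(diag(3), c(0, 0, 0)), rot2)))
  m2 <- apply_first_assembly(fx$model, biomt)
  expect_identical(m2$selected_trna, "T")
  counts <- vapply(m2$trna_chains, function(ch) {
    alt <- m2; alt$selected_trna <- ch
    nrow(dplyr::distinct(find_contacts(alt), rib_chain, rib_seq))
  }, integer(1))
  expect_true(all(counts == counts[1]))

  no_trna <- read_trna_complex(
    c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END"),
    entry_id = "PROT")
  expect_error(select_trna(no_trna), "no tRNA")
})
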