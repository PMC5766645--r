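# Universal position assignment, cloverleaf segmentation, region lookup,
# canonicity, and crystal-to-original alignment.

test_that("the region table partitions positions 1-76", {
  rt <- region_table()
  expanded <- unlist(mapply(seq, rt$from, rt$to))
  expect_equal(sort(expanded), 1:76)          # disjoint and covering
  for (lab in as.character(1:76)) {
    expect_length(region_of(lab), 1)
  }
  expect_equal(region_of("34"), "S8")
  expect_equal(region_of("73"), "S15")
  expect_equal(region_of("e11"), "excluded")
  expect_equal(region_of(c("17a", "20a", "20b")), c("S4", "S4", "S4"))
  expect_error(region_of("99x"), "unknown")
})

test_that("a canonical 76-nt tRNA maps to the identity labeling", {
  fx <- canonical_trna_example()
  a <- assign_from_secondary_structure(fx$seq, fx$ss)
  expect_equal(a$label, as.character(1:76))
  expect_false(any(grepl("^e", a$label)))
  expect_equal(a$label[35], "35")           # anticodon center
  expect_equal(a$region[34], "S8")
  # labels strictly increase 5' to 3'
  expect_true(all(diff(sprinzl_order(a$label)) > 0))
})

test_that("long variable arms keep 44-48 and overflow into e-labels", {
  fx <- canonical_trna_example()
  # replace the 5-nt variable region with a 22-nt V-arm (stem-loop)
  varm_seq <- paste0("GGCCC", "AGUUCAA", "GGGCC", "AGCGU")
  varm_ss <- paste0("(((((", ".......", ")))))", ".....")
  seq <- paste0(substr(fx$seq, 1, 43), varm_seq, substr(fx$seq, 49, 76))
  ss <- paste0(substr(fx$ss, 1, 43), varm_ss, substr(fx$ss, 49, 76))
  a <- assign_from_secondary_structure(seq, ss)
  v <- a$label[44:65]
  expect_equal(v[1:5], as.character(44:48))
  expect_equal(v[6:22], paste0("e", 1:17))
  expect_true(all(region_of(v[6:22]) == "excluded"))
  # downstream labels resume at 49
  expect_equal(a$label[66], "49")
  expect_equal(tail(a$label, 4), as.character(73:76))
})

test_that("D-loop fill rules enumerate loop sizes 6-11 deterministically", {
  fx <- canonical_trna_example()
  # D-loop occupies indices 14-21 in the canonical example
  mk <- function(loop) {
    seq <- paste0(substr(fx$seq, 1, 13), loop, substr(fx$seq, 22, 76))
    ss <- paste0(substr(fx$ss, 1, 13), strrep(".", nchar(loop)),
                 substr(fx$ss, 22, 76))
    assign_from_secondary_structure(seq, ss)
  }
  dlab <- function(a) a$label[a$region == "S4" & !is.na(a$label)]
  expect_equal(dlab(mk("AGUAGA")),                        # 6 nt: drop 17, 20
               c("14", "15", "16", "18", "19", "21"))
  expect_equal(dlab(mk("AGUAGAU")),                       # 7 nt: drop 17
               c("14", "15", "16", "18", "19", "20", "21"))
  expect_equal(dlab(mk("AGUAGAUC")),                      # 8 nt: core
               as.character(14:21))
  expect_equal(dlab(mk("AGUAGAUCA")),                     # 9 nt: +17a
               c("14", "15", "16", "17", "17a", "18", "19", "20", "21"))
  expect_equal(dlab(mk("AGUAGAUCAA")),                    # 10 nt: +20a
               c("14", "15", "16", "17", "17a", "18", "19", "20", "20a",
                 "21"))
  expect_equal(dlab(mk("AGUAGAUCAAA")),                   # 11 nt: +20b
               c("14", "15", "16", "17", "17a", "18", "19", "20", "20a",
                 "20b", "21"))
  expect_error(mk("AGUAGAUCAAAA"), "noncanonical")        # 12 nt
})

test_that("surplus insertion prefers keeping the conserved GG at 18-19", {
  fx <- canonical_trna_example()
  mk <- function(loop) {
    seq <- paste0(substr(fx$seq, 1, 13), loop, substr(fx$seq, 22, 76))
    ss <- paste0(substr(fx$ss, 1, 13), strrep(".", nchar(loop)),
                 substr(fx$ss, 22, 76))
    assign_from_secondary_structure(seq, ss)
  }
  # 9-nt loop whose GG sits where only the 20a-side insertion keeps it:
  # the default (+17a) allocation would put loop offsets 6,7 (G,U) at 18-19
  a <- mk("AUCAGGUUA")   # GG at loop offsets 5,6
  labs <- a$label[a$region == "S4"]
  bases <- a$base[a$region == "S4"]
  expect_equal(bases[match(c("18", "19"), labs)], c("G", "G"))
})

test_that("noncanonical cloverleafs are rejected with named violations", {
  fx <- canonical_trna_example()
  # 9-nt anticodon loop
  seq <- paste0(substr(fx$seq, 1, 38), "GG", substr(fx$seq, 39, 76))
  ss <- paste0(substr(fx$ss, 1, 38), "..", substr(fx$ss, 39, 76))
  ic <- is_canonical(seq, ss)
  expect_false(ic$canonical)
  expect_true(any(grepl("anticodon loop", ic$violations)))
  expect_error(assign_from_secondary_structure(seq, ss),
               class = "trnasurf_noncanonical")
  # canonical case is clean
  expect_true(is_canonical(fx$seq, fx$ss)$canonical)
  # batch bookkeeping: constructed canonical/broken mix
  ss_short <- paste0("..", substr(fx$ss, 3, 70), "..",
                     substr(fx$ss, 73, 76))   # 5-bp acceptor stem
  batch <- list(list(fx$seq, fx$ss), list(seq, ss), list(fx$seq, ss_short))
  ok <- vapply(batch, function(b) is_canonical(b[[1]], b[[2]])$canonical,
               logical(1))
  expect_equal(ok, c(TRUE, FALSE, FALSE))
})

test_that("crystal-to-original alignment recovers gaps and labels", {
  fx <- canonical_trna_example()
  orig <- fx$seq
  a_orig <- assign_from_secondary_structure(fx$seq, fx$ss)

  # identical sequences align gaplessly at 100% identity
  al0 <- align_crystal_to_original(orig, orig)
  expect_equal(attr(al0, "identity"), 1)
  expect_false(any(is.na(al0$crystal_pos)))

  # crystal missing a 5-nt internal window (44-48, whose flanks make the
  # gap placement unambiguous): labels skip that window
  crystal <- paste0(substr(orig, 1, 43), substr(orig, 49, 76))
  al <- align_crystal_to_original(crystal, orig)
  expect_equal(sum(is.na(al$crystal_base)), 5)
  tr <- transfer_labels(al, a_orig)
  expect_equal(sum(!tr$determined), 5)
  missing_labels <- tr$label[!tr$determined]
  expect_equal(missing_labels, as.character(44:48))
  # determined positions carry crystal residue numbers in order
  expect_equal(tr$seq_id[tr$determined], seq_len(nchar(crystal)))

  # gross mismatch errors out
  expect_error(
    align_crystal_to_original(paste(rep("A", 60), collapse = ""), orig),
    class = "trnasurf_mismatch")
})

test_that("alignment scores equal an independent dynamic-programming oracle", {
  set.seed(202)
  fx <- canonical_trna_example()
  orig <- fx$seq
  for (rep in 1:6) {
    crystal <- strsplit(orig, "")[[1]]
    subs <- sample(76, 4)                       # ~5% substitutions
    crystal[subs] <- sample(c("A", "U", "G", "C"), 4, replace = TRUE)
    # also delete a short window
    del <- sample(10:60, 1)
    crystal <- crystal[-(del:(del + 2))]
    crystal <- paste(crystal, collapse = "")
    al <- align_crystal_to_original(crystal, orig, min_identity = 0)
    expect_equal(attr(al, "score"), nw_score(crystal, orig))
  }
})

test_that("original-sequence search picks the parent above the identity floor", {
  fx <- canonical_trna_example()
  parent <- fx$seq
  set.seed(303)
  mutate_seq <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), k)
    v[idx] <- sample(c("A", "U", "G", "C"), k, replace = TRUE)
    paste(v, collapse = "")
  }
  decoys <- vapply(1:10, function(i) mutate_seq(parent, 35), character(1))
  library <- c(setNames(decoys, paste0("decoy", 1:10)), parent = parent)

  # exact parent in the library
  hit <- find_original_sequence(parent, library)
  expect_equal(hit$name, "parent")
  expect_equal(hit$identity, 1)

  # crystal with 2 substitutions still finds the parent
  crystal <- mutate_seq(parent, 2)
  hit2 <- find_original_sequence(crystal, library)
  expect_equal(hit2$name, "parent")

  # all identities below the floor: no hit
  none <- find_original_sequence(paste(rep("ACGU", 19), collapse = ""),
                                 library["decoy1"])
  expect_equal(nrow(none), 0)
  expect_error(find_original_sequence(parent, character()), "empty")
})

test_that("assignments round-trip through TSV serialization", {
  fx <- canonical_trna_example()
  a <- assign_from_secondary_structure(fx$seq, fx$ss)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(a), tf)
  b <- readr::read_tsv(tf, show_col_types = FALSE,
                       col_types = readr::cols(label = "c"))
  expect_equal(b$label, a$label)
  expect_equal(b$region, a$region)
  expect_equal(b$determined, a$determined)
})
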