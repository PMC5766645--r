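# Record filtering, Shannon entropy, nine-rank scores, frequencies, and
# region-level conservation.

test_that("record filtering enforces the three criteria and deduplicates", {
  fx <- canonical_trna_example()
  rec <- tibble::tibble(
    species = c("sp1", "sp1", "sp1", "sp2", "sp2", "sp3"),
    isoacceptor = "Ala",
    sequence = c(fx$seq, fx$seq,                      # identical copies
                 gsub("^G", "N", fx$seq),             # criterion c
                 fx$seq, fx$seq,                      # dup in sp2
                 fx$seq),
    pseudogene = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),  # criterion a
    canonical = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  out <- filter_records(rec)
  # sp1 keeps one copy (N-record removed), sp2 keeps one, sp3 dropped
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$species), c("sp1", "sp2"))

  # criterion b via explicit structure testing
  ss_bad <- paste0(substr(fx$ss, 1, 38), "..", substr(fx$ss, 39, 74))
  seq_bad <- paste0(substr(fx$seq, 1, 38), "GG", substr(fx$seq, 39, 74))
  rec2 <- tibble::tibble(
    species = c("a", "b"), isoacceptor = "Ala",
    sequence = c(fx$seq, seq_bad), pseudogene = FALSE,
    ss = c(fx$ss, ss_bad))
  out2 <- filter_records(rec2)
  expect_equal(out2$species, "a")
  expect_warning(filter_records(rec2[2, ]), "no records")
})

test_that("column entropy matches its closed forms and skips gaps", {
  expect_equal(column_entropy(rep("G", 12)), 0)
  expect_equal(column_entropy(c("A", "C", "G", "U")), 2)
  expect_equal(column_entropy(c("A", "A", "U", "U")), 1)
  expect_equal(column_entropy(c("A", "A", "-", NA)), 0)  # gap skipping
  expect_true(is.na(column_entropy(c("-", NA, "."))))    # all gaps
  # invariance under base relabeling
  expect_equal(column_entropy(c("A", "A", "C", "G")),
               column_entropy(c("U", "U", "G", "A")))
})

test_that("nine ranks cover [0,2] with boundaries falling conserved-ward", {
  expect_equal(rank_entropy(0), 9L)
  expect_equal(rank_entropy(2), 1L)
  expect_equal(rank_entropy(1), 5L)        # bin 4 from the variable end
  w <- 2 / 9
  # exact bin edges belong to the more-conserved rank
  expect_equal(rank_entropy(w), 9L)
  expect_equal(rank_entropy(2 * w), 8L)
  expect_equal(rank_entropy(w + 1e-9), 8L)
  # recompute every rank from the declared bin edges 2k/9
  h <- seq(0.01, 1.99, by = 0.02)
  expect_equal(rank_entropy(h), as.integer(9 - ceiling(h / w) + 1))
  expect_error(rank_entropy(2.5), "out of range")
  expect_error(rank_entropy(-0.3), "out of range")
})

test_that("identical sequences give rank 9 at every covered position", {
  probs <- matrix(0, 10, 4, dimnames = list(as.character(1:10),
                                            c("A", "C", "G", "U")))
  probs[, "G"] <- 1
  ts <- make_synthetic_trna_set(trna_set_blueprint(10, probs, seed = 1))
  expect_equal(length(unique(ts$records$sequence)), 1)
  cp <- conservation_profile(ts$records)
  expect_true(all(cp$entropy == 0))
  expect_true(all(cp$rank == 9L))
})

test_that("planted conserved and variable positions get ranks 9 and 1", {
  labels <- as.character(c(34, 35, 36, 44))
  probs <- matrix(0.25, 4, 4,
                  dimnames = list(labels, c("A", "C", "G", "U")))
  probs["35", ] <- c(0, 0, 0, 1)     # fixed U at the anticodon center
  ts <- make_synthetic_trna_set(trna_set_blueprint(400, probs, seed = 17))
  cp <- conservation_profile(ts$records)
  expect_equal(cp$rank[cp$label == "35"], 9L)
  expect_equal(cp$rank[cp$label == "44"], 1L)
  expect_equal(cp$coverage, rep(400L, 4))
})

test_that("CCA and e-labels are excluded from entropy profiles", {
  labels <- c("72", "73", "74", "75", "76", "e1")
  probs <- matrix(0.25, 6, 4, dimnames = list(labels, c("A", "C", "G", "U")))
  ts <- make_synthetic_trna_set(trna_set_blueprint(20, probs, seed = 2))
  cp <- conservation_profile(ts$records)
  expect_equal(cp$label, c("72", "73"))
  # optional masking mirrors displays that blank sparse positions
  cp2 <- conservation_profile(ts$records, mask_labels = "72")
  expect_equal(cp2$label, "73")
})

test_that("empirical entropies recover analytic values within 3 sigma", {
  set.seed(99)
  k <- 12
  raw <- matrix(rgamma(k * 4, shape = 0.8), k, 4)   # Dirichlet(0.8) rows
  probs <- raw / rowSums(raw)
  dimnames(probs) <- list(as.character(seq_len(k)), c("A", "C", "G", "U"))
  n <- 500
  ts <- make_synthetic_trna_set(trna_set_blueprint(n, probs, seed = 7))
  cp <- conservation_profile(ts$records)
  ana <- ts$analytic
  bias <- 3 / (2 * n * log(2))        # first-order plug-in bias bound
  for (l in ana$label) {
    se <- entropy_se(probs[l, ], n)
    expect_lt(abs(cp$entropy[cp$label == l] - ana$entropy[ana$label == l]),
              3 * se + 2 * bias + 1e-6)
  }
  # estimates tighten as n grows
  err_at <- function(n, seed) {
    t2 <- make_synthetic_trna_set(trna_set_blueprint(n, probs, seed = seed))
    c2 <- conservation_profile(t2$records)
    mean(abs(c2$entropy - ana$entropy))
  }
  expect_lt(err_at(5000, 11), err_at(50, 11))
})

test_that("frequency tables report exact fractions that sum to one", {
  labels <- as.character(1:3)
  probs <- matrix(0, 3, 4, dimnames = list(labels, c("A", "C", "G", "U")))
  probs[1, "A"] <- 1
  probs[2, c("A", "U")] <- 0.5
  probs[3, ] <- 0.25
  ts <- make_synthetic_trna_set(trna_set_blueprint(40, probs, seed = 13))
  ft <- frequency_table(ts$records)
  f1 <- ft[ft$label == "1", ]
  expect_equal(f1$freq[f1$base == "A"], 1)
  expect_equal(sum(f1$freq), 1)
  f2 <- ft[ft$label == "2", ]
  expect_equal(f2$freq[f2$base == "C"], 0)
  expect_equal(f2$freq[f2$base == "G"], 0)
  expect_equal(f2$freq[f2$base == "A"] + f2$freq[f2$base == "U"], 1)
  sums <- tapply(ft$freq, ft$label, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("region conservation averages ranks with standard errors", {
  prof <- tibble::tibble(
    label = c("1", "2", "26", "34", "35"),
    region = region_of(c("1", "2", "26", "34", "35")),
    entropy = c(0, 0, 0.5, 1.0, 0),
    rank = rank_entropy(c(0, 0, 0.5, 1.0, 0)),
    coverage = 10L)
  class(prof) <- c("trna_entropy_profile", class(prof))
  rc <- region_conservation(prof)
  expect_equal(rc$mean_rank[rc$region == "S1"], 9)
  # single-label region mean equals that label's rank
  expect_equal(rc$mean_rank[rc$region == "S6"],
               as.numeric(rank_entropy(0.5)))
  expect_equal(rc$mean_rank[rc$region == "S8"],
               mean(rank_entropy(c(1.0, 0))))
  expect_equal(rc$se[rc$region == "S1"], 0)
  expect_true(is.na(rc$se[rc$region == "S6"]))
  # all-rank-9 profile averages to 9 everywhere
  prof9 <- prof
  prof9$rank <- 9L
  expect_true(all(region_conservation(prof9)$mean_rank == 9))
})

test_that("duplicates and dropped sequences behave monotonically", {
  labels <- as.character(1:6)
  probs <- matrix(0.25, 6, 4, dimnames = list(labels, c("A", "C", "G", "U")))
  ts <- make_synthetic_trna_set(trna_set_blueprint(30, probs,
                                                   gap_prob = 0.2, seed = 5))
  rec <- ts$records
  # dedup idempotence: stacking the same records twice changes nothing
  doubled <- filter_records(dplyr::bind_rows(rec, rec))
  base <- filter_records(rec)
  expect_equal(nrow(doubled), nrow(base))
  expect_equal(conservation_profile(doubled)$entropy,
               conservation_profile(base)$entropy)
  # removing a sequence never increases coverage
  cov_all <- conservation_profile(rec)$coverage
  cov_less <- conservation_profile(rec[-1, ])$coverage
  expect_true(all(cov_less <= cov_all))
})
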