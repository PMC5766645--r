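# Assignment of universal tRNA positions from a cloverleaf secondary
# structure, canonicity checking, and alignment of crystallized fragments to
# their full-length genomic originals.

#' Assign universal tRNA positions from a cloverleaf secondary structure
#'
#' Takes an RNA sequence and its cloverleaf secondary structure and assigns
#' each nucleotide a universal (Sprinzl) position label plus its sequence
#' region S1-S15. The structure may be a dot-bracket string (`"("`/`")"`;
#' `">"`/`"<"` as produced by tRNA gene scanners are accepted) or a
#' precomputed arm segmentation from [parse_cloverleaf()].
#'
#' Deterministic fill rules (a declared convention, since the universal rule
#' leaves unusual loop sizes open): the D-loop core carries labels 14-21;
#' surplus nucleotides are inserted as 17a, then 20a, then 20b, preferring an
#' allocation that keeps the loop's conserved G18-G19 when present; deficits
#' drop 17 first, then 20. Variable regions of up to 5 nucleotides map to
#' 44-48; longer V-arms keep 44-48 for the first five nucleotides and label
#' the overflow e1, e2, ... in 5' to 3' order (excluded from region
#' statistics). The anticodon loop center receives label 35.
#'
#' @param seq RNA sequence (A/U/G/C; T is read as U).
#' @param ss dot-bracket string of the same length, or a `parse_cloverleaf()`
#'   result.
#' @param strict error on a noncanonical structure (default `TRUE`); with
#'   `strict = FALSE` a best-effort assignment is returned with the
#'   violations in `attr(, "violations")`.
#' @return tibble of class `sprinzl_assignment`: index, base, label, region,
#'   determined (all `TRUE` for a genomic sequence).
#' @examples
#' fx <- canonical_trna_example()
#' head(assign_from_secondary_structure(fx$seq, fx$ss))
#' @export
assign_from_secondary_structure <- function(seq, ss, strict = TRUE) {
  seq <- toupper(gsub("T", "U", seq))
  bases <- strsplit(seq, "")[[1]]
  arms <- if (is.list(ss)) ss else parse_cloverleaf(seq, ss)
  viol <- arms$violations

  if (length(viol) && strict) {
    rlang::abort(
      paste0("noncanonical tRNA structure: ", paste(viol, collapse = "; ")),
      class = "trnasurf_noncanonical", violations = viol)
  }

  labels <- rep(NA_character_, length(bases))
  put <- function(idx, labs) {
    labels[idx] <<- labs[seq_along(idx)]
  }
  a <- arms
  put(a$acceptor5, as.character(seq(8 - length(a$acceptor5), 7)))
  put(a$spacer1, as.character(c(8, 9))[seq_along(a$spacer1)])
  put(a$dstem5, as.character(seq(10, 9 + length(a$dstem5))))
  put(a$dloop, dloop_labels(length(a$dloop), bases[a$dloop]))
  put(a$dstem3, as.character(seq(26 - length(a$dstem3), 25)))
  put(a$spacer2, "26")
  put(a$acstem5, as.character(seq(32 - length(a$acstem5), 31)))
  put(a$acloop, as.character(seq(32, 31 + length(a$acloop))))
  put(a$acstem3, as.character(seq(39, 38 + length(a$acstem3))))
  put(a$vregion, vregion_labels(length(a$vregion)))
  put(a$tstem5, as.character(seq(49, 48 + length(a$tstem5))))
  put(a$tloop, as.character(seq(54, 53 + length(a$tloop))))
  put(a$tstem3, as.character(seq(61, 60 + length(a$tstem3))))
  put(a$acceptor3, as.character(seq(66, 65 + length(a$acceptor3))))
  put(a$tail, as.character(seq(73, 72 + length(a$tail))))

  out <- tibble::tibble(
    index = seq_along(bases),
    base = bases,
    label = labels,
    region = ifelse(is.na(labels), NA_character_, region_of(labels)),
    determined = TRUE
  )
  class(out) <- c("sprinzl_assignment", class(out))
  attr(out, "violations") <- viol
  out
}

# D-loop label vector for a loop of the given length, preferring an
# insertion allocation that keeps G at positions 18-19
#' @noRd
dloop_labels <- function(len, bases = NULL) {
  core <- c("14", "15", "16", "17", "18", "19", "20", "21")
  if (len == 8) return(core)
  if (len < 8) {
    drop <- c("17", "20", "16", "15")[seq_len(8 - len)]
    return(setdiff(core, drop))
  }
  surplus <- len - 8
  candidates <- list()
  for (k1 in 1:0) {             # 17a used first by default
    k2 <- surplus - k1
    if (k1 > 1 || k2 < 0 || k2 > 2) next
    labs <- c("14", "15", "16", "17", if (k1) "17a", "18", "19", "20",
              c("20a", "20b")[seq_len(k2)], "21")
    candidates[[length(candidates) + 1]] <- labs
  }
  if (!length(candidates)) {
    rlang::abort("D-loop too long for the universal numbering (max 11)")
  }
  if (!is.null(bases)) {
    for (labs in candidates) {
      gg <- bases[match(c("18", "19"), labs)]
      if (identical(gg, c("G", "G"))) return(labs)
    }
  }
  candidates[[1]]
}

# V-region labels: up to 5 nucleotides take 44-48, overflow gets e-labels
#' @noRd
vregion_labels <- function(len) {
  if (len == 0) return(character())
  if (len <= 5) return(as.character(seq(44, 43 + len)))
  c(as.character(44:48), paste0("e", seq_len(len - 5)))
}

#' Segment a tRNA cloverleaf from dot-bracket pairing
#'
#' Pairs the brackets, groups base pairs into ungapped stems, and identifies
#' the acceptor stem, D-arm, anticodon arm, variable region and T-arm of a
#' cloverleaf. Canonicity violations (stem/loop sizes outside the universal
#' rule) are collected rather than thrown.
#'
#' @param seq RNA sequence.
#' @param ss dot-bracket string (`(` `)` or `>` `<`; anything else is
#'   unpaired).
#' @return list of index vectors (`acceptor5`, `spacer1`, `dstem5`, `dloop`,
#'   `dstem3`, `spacer2`, `acstem5`, `acloop`, `acstem3`, `vregion`,
#'   `tstem5`, `tloop`, `tstem3`, `acceptor3`, `tail`) plus `violations`, a
#'   character vector (empty for a canonical cloverleaf).
#' @export
parse_cloverleaf <- function(seq, ss) {
  n <- nchar(ss)
  if (nchar(seq) != n) rlang::abort("sequence and structure lengths differ")
  sym <- strsplit(chartr("><", "()", ss), "")[[1]]
  stack <- integer()
  pair <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (sym[i] == "(") stack <- c(stack, i)
    else if (sym[i] == ")") {
      if (!length(stack)) rlang::abort("unbalanced secondary structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j; pair[j] <- i
    }
  }
  if (length(stack)) rlang::abort("unbalanced secondary structure")

  viol <- character()
  opens <- which(!is.na(pair) & pair > seq_len(n))
  if (!length(opens)) {
    return(list(violations = "no base pairs in structure"))
  }
  # group pairs into ungapped stems: consecutive (i+1, j-1) nesting
  stems <- list()
  cur <- opens[1]
  for (i in opens[-1]) {
    last <- cur[length(cur)]
    if (i == last + 1 && pair[i] == pair[last] - 1) cur <- c(cur, i)
    else { stems[[length(stems) + 1]] <- cur; cur <- i }
  }
  stems[[length(stems) + 1]] <- cur

  # hairpin arms close on themselves (pair inside the 5' half ... no: a stem
  # is a hairpin when nothing lies between its two sides except the loop)
  is_hairpin <- vapply(stems, function(s) {
    inner <- (s[length(s)] + 1):(pair[s[length(s)]] - 1)
    all(is.na(pair[inner]))
  }, logical(1))
  hp <- stems[is_hairpin]
  long_range <- stems[!is_hairpin]

  if (!length(long_range)) {
    return(list(violations = c(viol, "no acceptor stem")))
  }
  acceptor <- long_range[[1]]
  # nested long-range stems (bulged acceptor stem) -> noncanonical
  if (length(long_range) > 1) {
    viol <- c(viol, "acceptor stem is interrupted (bulge)")
    acceptor <- long_range[[1]]
  }
  n_hp <- length(hp)
  if (n_hp < 3 || n_hp > 4) {
    viol <- c(viol, sprintf("expected 3 hairpin arms (plus optional V-stem), found %d", n_hp))
    if (n_hp < 3) return(list(violations = viol))
  }
  darm <- hp[[1]]
  acarm <- hp[[2]]
  tarm <- hp[[n_hp]]

  seg <- function(from, to) if (from > to) integer() else from:to
  acc5 <- acceptor
  acc3 <- rev(pair[acceptor])
  d5 <- darm; d3 <- rev(pair[darm])
  ac5 <- acarm; ac3 <- rev(pair[acarm])
  t5 <- tarm; t3 <- rev(pair[tarm])
  arms <- list(
    acceptor5 = acc5,
    spacer1 = seg(max(acc5) + 1, min(d5) - 1),
    dstem5 = d5,
    dloop = seg(max(d5) + 1, min(d3) - 1),
    dstem3 = d3,
    spacer2 = seg(max(d3) + 1, min(ac5) - 1),
    acstem5 = ac5,
    acloop = seg(max(ac5) + 1, min(ac3) - 1),
    acstem3 = ac3,
    vregion = seg(max(ac3) + 1, min(t5) - 1),
    tstem5 = t5,
    tloop = seg(max(t5) + 1, min(t3) - 1),
    tstem3 = t3,
    acceptor3 = acc3,
    tail = seg(max(acc3) + 1, n)
  )
  if (!length(acc5)) arms$acceptor3 <- integer()

  # canonicity checks against the universal positioning rule
  chk <- function(cond, msg) if (cond) viol <<- c(viol, msg)
  chk(length(acc5) > 7, "acceptor stem longer than 7 bp")
  chk(length(acc5) < 6, "acceptor stem shorter than 6 bp")
  chk(length(arms$spacer1) != 2, "spacer between acceptor and D-stem is not 2 nt")
  chk(!length(d5) %in% 3:4, "D-stem size outside 3-4 bp")
  chk(!length(arms$dloop) %in% 6:11, "D-loop size outside 6-11 nt")
  chk(length(arms$spacer2) != 1, "inter-stem position 26 missing or duplicated")
  chk(length(ac5) != 5, "anticodon stem is not 5 bp")
  chk(length(arms$acloop) != 7, "anticodon loop size is not 7 nt")
  chk(length(t5) != 5, "T-stem is not 5 bp")
  chk(length(arms$tloop) != 7, "T-loop size is not 7 nt")
  chk(length(arms$acceptor3) != length(acc5), "acceptor stem sides differ")
  chk(length(arms$tail) > 4, "more than 4 nt after the acceptor stem")
  # V-region pairs (long-arm stem) are allowed; anything paired elsewhere is
  # already covered by the stem checks above
  arms$violations <- viol
  arms
}

#' Canonicity of a tRNA cloverleaf
#'
#' A tRNA is canonical when its cloverleaf follows the universal positioning
#' rules (arm sizes in bounds, every nucleotide placeable).
#'
#' @inheritParams assign_from_secondary_structure
#' @return list with `canonical` (logical) and `violations` (character).
#' @export
is_canonical <- function(seq, ss) {
  arms <- parse_cloverleaf(seq, ss)
  list(canonical = length(arms$violations) == 0,
       violations = arms$violations)
}

#' A canonical 76-nt tRNA example
#'
#' Yeast tRNA-Phe-like canonical cloverleaf (7 bp acceptor stem, 4 bp
#' D-stem, 8 nt D-loop, 5 nt variable region, CCA tail), used in examples
#' and as a fixture seed.
#'
#' @return list with `seq` and `ss` (dot-bracket).
#' @export
canonical_trna_example <- function() {
  seq <- paste0(
    "GCGGAUU", "UA", "GCUC", "AGUUGGGA", "GAGC",  # 1-7, 8-9, 10-13, D-loop, 22-25
    "G", "CCAGA", "CUGAAGA", "UCUGG",             # 26, 27-31, AC loop 32-38, 39-43
    "AGGUC",                                       # V-region 44-48
    "CUGUG", "UUCGAUC", "CACAG",                  # 49-53, T-loop 54-60, 61-65
    "AAUUCGC", "ACCA")                             # 66-72, 73-76
  ss <- paste0(
    "(((((((", "..", "((((", "........", "))))",
    ".", "(((((", ".......", ")))))",
    ".....",
    "(((((", ".......", ")))))",
    ")))))))", "....")
  list(seq = seq, ss = ss)
}

# ---- crystal-to-original alignment ----------------------------------------

#' Globally align a crystallized tRNA fragment to its full-length original
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap opening -4,
#' gap extension -1 per position, so a length-k gap costs 4 + k) via
#' Biostrings. Crystal positions inherit the Sprinzl labels of the aligned
#' original positions; modified bases must be mapped to parents beforehand
#' (see [trna_sequence()]).
#'
#' @param crystal_seq,original_seq RNA strings over A/U/G/C.
#' @param min_identity abort below this identity over the crystal length
#'   (default 0.6), the signature of aligning against the wrong original.
#' @return tibble of class `trna_alignment`: one row per alignment column
#'   with crystal_pos, crystal_base, original_pos, original_base (NA at
#'   gaps); attributes `score` and `identity`.
#' @export
align_crystal_to_original <- function(crystal_seq, original_seq,
                                      min_identity = 0.6) {
  crystal_seq <- toupper(gsub("T", "U", crystal_seq))
  original_seq <- toupper(gsub("T", "U", original_seq))
  mat <- alignment_substitution_matrix()
  aln <- Biostrings::pairwiseAlignment(
    crystal_seq, original_seq, type = "global",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cp <- cumsum(p != "-"); cp[p == "-"] <- NA
  sp <- cumsum(s != "-"); sp[s == "-"] <- NA
  out <- tibble::tibble(
    crystal_pos = cp,
    crystal_base = ifelse(p == "-", NA_character_, p),
    original_pos = sp,
    original_base = ifelse(s == "-", NA_character_, s)
  )
  matches <- sum(!is.na(out$crystal_base) & !is.na(out$original_base) &
                   out$crystal_base == out$original_base)
  identity <- matches / nchar(crystal_seq)
  if (identity < min_identity) {
    rlang::abort(sprintf(
      "alignment identity %.1f%% below %.0f%%: wrong original sequence?",
      100 * identity, 100 * min_identity), class = "trnasurf_mismatch")
  }
  attr(out, "score") <- Biostrings::score(aln)
  attr(out, "identity") <- identity
  class(out) <- c("trna_alignment", class(out))
  out
}

#' @noRd
alignment_substitution_matrix <- function() {
  b <- c("A", "C", "G", "U")
  mat <- matrix(-1, 4, 4, dimnames = list(b, b))
  diag(mat) <- 1
  mat
}

#' Transfer Sprinzl labels from an original sequence to a crystal fragment
#'
#' @param alignment tibble from [align_crystal_to_original()].
#' @param original_assignment `sprinzl_assignment` of the original sequence.
#' @param crystal_seq_ids optional crystal residue numbers (same order as the
#'   crystal sequence); defaults to 1..n.
#' @return `sprinzl_assignment`-shaped tibble over the ORIGINAL positions:
#'   index, base, label, region, determined (`TRUE` where the crystal covers
#'   the position), seq_id (crystal residue number, NA where absent).
#' @export
transfer_labels <- function(alignment, original_assignment,
                            crystal_seq_ids = NULL) {
  out <- original_assignment
  cov <- alignment |>
    dplyr::filter(!is.na(.data$original_pos)) |>
    dplyr::select("original_pos", "crystal_pos")
  out$determined <- out$index %in% cov$original_pos[!is.na(cov$crystal_pos)]
  cpos <- cov$crystal_pos[match(out$index, cov$original_pos)]
  if (is.null(crystal_seq_ids)) {
    out$seq_id <- cpos
  } else {
    out$seq_id <- crystal_seq_ids[cpos]
  }
  out$seq_id[!out$determined] <- NA_integer_
  out
}

#' Find the original genomic tRNA of a crystallized sequence
#'
#' Scores the crystal sequence against every library sequence with the
#' global alignment of [align_crystal_to_original()] and returns the best
#' hit, provided its identity over the crystal length reaches the floor
#' (default 85%); otherwise a zero-row tibble (no hit).
#'
#' @param crystal_seq RNA string.
#' @param library named character vector of library sequences, or a tibble
#'   with columns `name` and `seq`.
#' @param min_identity identity floor for accepting a hit.
#' @return tibble with 0 or 1 rows: name, seq, score, identity.
#' @export
find_original_sequence <- function(crystal_seq, library, min_identity = 0.85) {
  if (is.data.frame(library)) {
    library <- setNames(library$seq, library$name)
  }
  if (!length(library)) rlang::abort("empty sequence library")
  scored <- purrr::map(names(library), function(nm) {
    aln <- tryCatch(
      align_crystal_to_original(crystal_seq, library[[nm]],
                                min_identity = 0),
      error = function(e) NULL)
    if (is.null(aln)) return(NULL)
    tibble::tibble(name = nm, seq = unname(library[[nm]]),
                   score = attr(aln, "score"),
                   identity = attr(aln, "identity"))
  })
  scored <- dplyr::bind_rows(scored)
  if (nrow(scored) == 0) {
    return(tibble::tibble(name = character(), seq = character(),
                          score = numeric(), identity = numeric()))
  }
  scored <- dplyr::arrange(scored, dplyr::desc(.data$score), .data$name)
  best <- scored[1, ]
  if (best$identity < min_identity) return(scored[0, ])
  best
}
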