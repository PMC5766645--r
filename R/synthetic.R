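# Synthetic fixtures with planted, exactly known ground truth: two-chain
# complexes whose residue set-distances are constructed to hit target values,
# and tRNA sequence sets drawn from specified per-position base
# distributions with analytically known entropies.

#' Blueprint of a synthetic tRNA-protein complex
#'
#' Describes a complex of `n_rib` ribonucleotides (one tRNA chain) and
#' `n_aa` amino acids (one protein chain) in which selected
#' (ribonucleotide, amino acid) pairs are planted at exact set distances.
#' Residues are laid out on a coarse lattice so that every non-planted pair
#' is guaranteed farther than the largest planted distance plus 1 Angstrom.
#'
#' @param n_rib,n_aa residue counts (rib residues are numbered 1..n_rib,
#'   amino acids 1..n_aa).
#' @param planted tibble with columns `rib`, `aa`, `distance` (Angstrom,
#'   each >= 1.5); each ribonucleotide and each amino acid may appear in at
#'   most one planted pair (the lattice spacing cannot realize more).
#' @param undetermined integer vector of ribonucleotide indices omitted from
#'   the emitted structure (simulating crystallographically undetermined
#'   positions).
#' @param seed integer seed controlling the atom jitter.
#' @return validated blueprint (list of class `complex_blueprint`).
#' @export
complex_blueprint <- function(n_rib, n_aa,
                              planted = tibble::tibble(
                                rib = integer(), aa = integer(),
                                distance = numeric()),
                              undetermined = integer(), seed = 1) {
  stopifnot(n_rib >= 1, n_aa >= 1, n_rib <= 76)
  planted <- tibble::as_tibble(planted)
  if (nrow(planted)) {
    if (any(planted$distance < 1.5)) {
      rlang::abort("planted distances must be >= 1.5 Angstrom")
    }
    if (anyDuplicated(planted[, c("rib", "aa")])) {
      rlang::abort("planted pairs must be unique")
    }
    if (anyDuplicated(planted$rib) || anyDuplicated(planted$aa)) {
      rlang::abort(paste0("infeasible geometry: a residue is used in more ",
                          "than one planted contact"))
    }
    if (any(planted$rib > n_rib) || any(planted$aa > n_aa)) {
      rlang::abort("planted indices exceed residue counts")
    }
    if (any(planted$rib %in% undetermined)) {
      rlang::abort("cannot plant a contact on an undetermined position")
    }
    if (any(planted$distance > 12)) {
      rlang::abort(paste0("infeasible geometry: planted distance exceeds ",
                          "the lattice spacing margin"))
    }
  }
  structure(list(n_rib = as.integer(n_rib), n_aa = as.integer(n_aa),
                 planted = planted,
                 undetermined = as.integer(undetermined),
                 seed = as.integer(seed)),
            class = "complex_blueprint")
}

#' Realize a synthetic complex as legacy PDB text
#'
#' Emits a parseable two-chain structure (chain T: ribonucleotides with
#' minimal P/C1'/N9/O2' atom sets, chain A: alanines with N/CA/C/O/CB) whose
#' realized set-distances match the planted targets to well under 1e-3
#' Angstrom, plus the ground-truth manifest. Non-planted pairs are at least
#' `max(planted distance) + 1` Angstrom apart by construction.
#'
#' @param bp a [complex_blueprint()].
#' @return list with `pdb_lines` (character), `model` (parsed
#'   `trna_complex`), `manifest` (tibble rib, aa, distance of the planted
#'   pairs), `assignment` (identity Sprinzl assignment over 1..n_rib with
#'   `determined` flags honoring the blueprint's undetermined set).
#' @examples
#' fx <- make_synthetic_complex(complex_blueprint(
#'   5, 8, planted = tibble::tibble(rib = 2, aa = 4, distance = 3.2),
#'   seed = 42))
#' find_contacts(fx$model)
#' @export
make_synthetic_complex <- function(bp) {
  stopifnot(inherits(bp, "complex_blueprint"))
  withr_seed(bp$seed)
  spacing <- 30
  jitter <- function(n) matrix(stats::runif(3 * n, -0.3, 0.3), ncol = 3)

  rib_offsets <- rbind(c(0, 0, 0), c(0.9, 0.3, 0), c(0.4, -0.8, 0.3),
                       c(-0.7, 0.5, -0.4))
  rib_atom_names <- c("P", "C1'", "N9", "O2'")
  rib_elements <- c("P", "C", "N", "O")
  aa_offsets <- rbind(c(0, 0, 0), c(0.8, 0.4, 0), c(1.6, -0.2, 0.3),
                      c(2.2, 0.6, -0.3), c(1.0, 1.2, 0.5))
  aa_atom_names <- c("N", "CA", "C", "O", "CB")
  aa_elements <- c("N", "C", "C", "O", "C")
  rib_names <- rep(c("A", "U", "G", "C"), length.out = bp$n_rib)

  keep_rib <- setdiff(seq_len(bp$n_rib), bp$undetermined)
  rib_xyz <- vector("list", bp$n_rib)
  rows <- list()
  for (i in keep_rib) {
    center <- c(spacing * i, 0, 0)
    xyz <- sweep(rib_offsets + jitter(nrow(rib_offsets)), 2, center, "+")
    rib_xyz[[i]] <- xyz
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom = rib_atom_names, res_name = rib_names[i], chain = "T",
      seq_id = i, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = rib_elements)
  }
  planted_of_aa <- setNames(rep(NA_integer_, bp$n_aa), seq_len(bp$n_aa))
  if (nrow(bp$planted)) planted_of_aa[bp$planted$aa] <- bp$planted$rib
  for (j in seq_len(bp$n_aa)) {
    i <- planted_of_aa[[j]]
    if (!is.na(i)) {
      d <- bp$planted$distance[bp$planted$aa == j]
      # anchor the amino acid's first atom exactly d beyond the
      # ribonucleotide's maximum-x atom; all other atoms lie strictly
      # farther in x, so the pair minimum is exactly d
      anchor <- rib_xyz[[i]][which.max(rib_xyz[[i]][, 1]), ]
      base <- anchor + c(d, 0, 0)
      xyz <- sweep(aa_offsets, 2, base, "+")
    } else {
      center <- c(spacing * j, 90, 0)
      xyz <- sweep(aa_offsets + jitter(nrow(aa_offsets)), 2, center, "+")
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom = aa_atom_names, res_name = "ALA", chain = "A", seq_id = j,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = aa_elements)
  }
  atoms <- dplyr::bind_rows(rows) |>
    dplyr::mutate(icode = "", occupancy = 1, altloc = "",
                  kind = residue_kind(.data$res_name)) |>
    dplyr::arrange(match(.data$chain, c("T", "A")), .data$seq_id)
  model <- new_trna_complex("SYNT", atoms, assembly_index = 0L)
  lines <- write_trna_complex(model)
  assignment <- tibble::tibble(
    index = seq_len(bp$n_rib),
    base = gsub("T", "U", rib_names),
    label = as.character(seq_len(bp$n_rib)),
    region = region_of(as.character(seq_len(bp$n_rib))),
    determined = !seq_len(bp$n_rib) %in% bp$undetermined,
    seq_id = ifelse(seq_len(bp$n_rib) %in% bp$undetermined,
                    NA_integer_, seq_len(bp$n_rib))
  )
  manifest <- dplyr::arrange(bp$planted, .data$rib)
  list(pdb_lines = lines, model = model, manifest = manifest,
       assignment = assignment)
}

# run the rest of the caller under a local RNG seed
#' @noRd
withr_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
}

#' Blueprint of a synthetic tRNA sequence set
#'
#' Sequences are drawn independently per universal position from specified
#' base distributions, so the expected (analytic) per-position entropy is
#' known exactly from the blueprint.
#'
#' @param n_sequences number of sequences to draw.
#' @param probs numeric matrix (positions x 4, columns A, C, G, U), each row
#'   summing to 1; row names are the Sprinzl labels (default `1:76`).
#' @param gap_prob per-position probability of a gap (scalar or vector).
#' @param isoacceptor isoacceptor label carried by the records.
#' @param seed integer seed.
#' @return list of class `trna_set_blueprint`.
#' @export
trna_set_blueprint <- function(n_sequences, probs, gap_prob = 0,
                               isoacceptor = "Ala", seed = 1) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) colnames(probs) <- c("A", "C", "G", "U")
  if (is.null(rownames(probs))) rownames(probs) <- as.character(seq_len(nrow(probs)))
  if (any(abs(rowSums(probs) - 1) > 1e-9) || any(probs < 0)) {
    rlang::abort("each probability row must be a distribution")
  }
  gap_prob <- rep(gap_prob, length.out = nrow(probs))
  structure(list(n_sequences = as.integer(n_sequences), probs = probs,
                 gap_prob = gap_prob, isoacceptor = isoacceptor,
                 seed = as.integer(seed)),
            class = "trna_set_blueprint")
}

#' Analytic per-position entropy of a sequence-set blueprint
#'
#' @param bp a [trna_set_blueprint()].
#' @return tibble: label, entropy (bits, the exact entropy of the base
#'   distribution, gaps excluded by construction).
#' @export
blueprint_entropy <- function(bp) {
  stopifnot(inherits(bp, "trna_set_blueprint"))
  h <- apply(bp$probs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  tibble::tibble(label = rownames(bp$probs), entropy = unname(h))
}

#' Draw a synthetic tRNA sequence set
#'
#' @param bp a [trna_set_blueprint()].
#' @return list with `records` (tibble: species, isoacceptor, sequence,
#'   pseudogene, canonical, and the list-column `assignment`), `alignment`
#'   (long tibble seq/label/base with gaps as `NA`), and `analytic`
#'   (the [blueprint_entropy()] table).
#' @export
make_synthetic_trna_set <- function(bp) {
  stopifnot(inherits(bp, "trna_set_blueprint"))
  withr_seed(bp$seed)
  labels <- rownames(bp$probs)
  bases <- colnames(bp$probs)
  n <- bp$n_sequences
  mat <- matrix(NA_character_, n, length(labels),
                dimnames = list(NULL, labels))
  for (l in seq_along(labels)) {
    draw <- sample(bases, n, replace = TRUE, prob = bp$probs[l, ])
    if (bp$gap_prob[l] > 0) {
      draw[stats::runif(n) < bp$gap_prob[l]] <- NA_character_
    }
    mat[, l] <- draw
  }
  records <- tibble::tibble(
    species = sprintf("synthetic_sp%04d", seq_len(n)),
    isoacceptor = bp$isoacceptor,
    sequence = apply(mat, 1, function(r) paste(ifelse(is.na(r), "", r),
                                               collapse = "")),
    pseudogene = FALSE,
    canonical = TRUE,
    assignment = purrr::map(seq_len(n), function(i) {
      keep <- which(!is.na(mat[i, ]))
      tibble::tibble(index = seq_along(keep), base = mat[i, keep],
                     label = labels[keep],
                     region = region_of(labels[keep]), determined = TRUE)
    })
  )
  alignment <- tibble::tibble(
    seq = rep(seq_len(n), times = length(labels)),
    label = rep(labels, each = n),
    base = as.vector(mat))
  list(records = records, alignment = alignment,
       analytic = blueprint_entropy(bp))
}

#' Write records to FASTA
#'
#' @param records tibble with `species` and `sequence`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_records_fasta <- function(records, file) {
  lines <- as.vector(rbind(paste0(">", records$species),
                           records$sequence))
  writeLines(lines, file)
  invisible(file)
}

#' Read a FASTA file into a name/sequence tibble
#'
#' @param file FASTA path.
#' @return tibble: name, seq.
#' @export
read_fasta_tbl <- function(file) {
  x <- Biostrings::readBStringSet(file)
  tibble::tibble(name = names(x),
                 seq = unname(toupper(gsub("T", "U", as.character(x)))))
}
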