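# Interface extraction: minimum atom-set distances between tRNA
# ribonucleotides and synthetase amino acids, contact sets at a distance
# threshold, threshold sweeps, per-position profiles and entry summaries.

# equality at the threshold counts as interacting; float slack for exact ties
DIST_EPS <- 1e-9

#' Minimum atom-set distance between two residues
#'
#' The distance between a ribonucleotide and an amino acid is the minimum
#' Euclidean distance over all pairs of atoms drawn from the two residues:
#' `distance(X, Y) = min { d(x, y) : x in X, y in Y }`.
#'
#' @param x,y numeric matrices (n x 3) of atom coordinates, or data frames
#'   with columns `x`, `y`, `z`.
#' @return single non-negative distance in Angstrom.
#' @examples
#' set_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))  # 5
#' @export
set_distance <- function(x, y) {
  x <- as_coord_matrix(x)
  y <- as_coord_matrix(y)
  if (nrow(x) == 0 || nrow(y) == 0) {
    rlang::abort("set_distance requires non-empty atom sets")
  }
  sqrt(min(cross_dist2(x, y)))
}

#' @noRd
as_coord_matrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m[, c("x", "y", "z")])
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  storage.mode(m) <- "double"
  m
}

# squared Euclidean cross-distance matrix, nrow(x) x nrow(y)
#' @noRd
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  pmax(d2, 0)
}

#' Residue-level set-distance matrix of a complex
#'
#' Computes the minimum atom-set distance from every ribonucleotide of the
#' selected tRNA chain to every amino acid of every protein chain (dimer
#' partners included). This matrix backs [find_contacts()],
#' [threshold_sweep()] and [distance_profile()].
#'
#' @param model a `trna_complex` with at least one tRNA and one protein
#'   chain.
#' @return list with `dist` (numeric matrix, ribonucleotides x amino acids),
#'   `rib` and `aa` (tibbles describing the rows / columns: chain, seq_id,
#'   icode, res_name).
#' @export
set_distance_matrix <- function(model) {
  stopifnot(inherits(model, "trna_complex"))
  trna_chain <- select_trna(model)
  if (!length(model$protein_chains)) {
    rlang::abort(paste0("no protein chain found in ", model$entry_id))
  }
  rib_atoms <- model$atoms |>
    dplyr::filter(.data$chain == trna_chain,
                  .data$kind == "ribonucleotide")
  aa_atoms <- model$atoms |>
    dplyr::filter(.data$chain %in% model$protein_chains,
                  .data$kind == "amino_acid")
  rib_key <- paste(rib_atoms$chain, rib_atoms$seq_id, rib_atoms$icode)
  aa_key <- paste(aa_atoms$chain, aa_atoms$seq_id, aa_atoms$icode)
  rib_ids <- unique(rib_key)
  aa_ids <- unique(aa_key)
  aa_group <- factor(aa_key, levels = aa_ids)
  P <- as_coord_matrix(aa_atoms)
  D <- matrix(NA_real_, length(rib_ids), length(aa_ids),
              dimnames = list(rib_ids, aa_ids))
  for (i in seq_along(rib_ids)) {
    xi <- as_coord_matrix(rib_atoms[rib_key == rib_ids[i], ])
    d2 <- cross_dist2(xi, P)
    atom_min <- if (nrow(xi) == 1) d2[1, ] else apply(d2, 2, min)
    D[i, ] <- sqrt(vapply(split(atom_min, aa_group), min, numeric(1)))
  }
  describe <- function(atoms, key, ids) {
    idx <- match(ids, key)
    tibble::tibble(chain = atoms$chain[idx], seq_id = atoms$seq_id[idx],
                   icode = atoms$icode[idx], res_name = atoms$res_name[idx])
  }
  list(dist = D,
       rib = describe(rib_atoms, rib_key, rib_ids),
       aa = describe(aa_atoms, aa_key, aa_ids))
}

#' Find interacting ribonucleotide / amino-acid pairs
#'
#' A pair interacts when its minimum atom-set distance is within the
#' threshold (default 3.3 Angstrom; equality counts as interacting).
#'
#' @param model a `trna_complex`.
#' @param threshold interaction distance threshold in Angstrom.
#' @param sdm optional precomputed [set_distance_matrix()] result.
#' @return tibble of contacts: rib_chain, rib_seq, rib_icode, rib_name,
#'   aa_chain, aa_seq, aa_icode, aa_name, distance.
#' @export
find_contacts <- function(model, threshold = 3.3, sdm = NULL) {
  if (threshold <= 0) rlang::abort("threshold must be positive")
  sdm <- sdm %||% set_distance_matrix(model)
  hit <- which(sdm$dist <= threshold + DIST_EPS, arr.ind = TRUE)
  out <- tibble::tibble(
    rib_chain = sdm$rib$chain[hit[, 1]],
    rib_seq = sdm$rib$seq_id[hit[, 1]],
    rib_icode = sdm$rib$icode[hit[, 1]],
    rib_name = sdm$rib$res_name[hit[, 1]],
    aa_chain = sdm$aa$chain[hit[, 2]],
    aa_seq = sdm$aa$seq_id[hit[, 2]],
    aa_icode = sdm$aa$icode[hit[, 2]],
    aa_name = sdm$aa$res_name[hit[, 2]],
    distance = sdm$dist[hit]
  )
  dplyr::arrange(out, .data$rib_seq, .data$aa_chain, .data$aa_seq)
}

#' Sweep the interaction threshold
#'
#' Counts interacting ribonucleotides and amino acids at every threshold of
#' a grid (default 2.0-5.0 Angstrom in 0.1 steps), the scan used to select
#' the working threshold.
#'
#' @param model a `trna_complex`.
#' @param lo,hi,step sweep grid in Angstrom.
#' @param sdm optional precomputed [set_distance_matrix()] result.
#' @return tibble: threshold, n_rib_interacting, n_aa_interacting.
#' @export
threshold_sweep <- function(model, lo = 2.0, hi = 5.0, step = 0.1,
                            sdm = NULL) {
  if (!(lo < hi) || step <= 0) {
    rlang::abort("need lo < hi and step > 0")
  }
  sdm <- sdm %||% set_distance_matrix(model)
  thr <- seq(lo, hi, by = step)
  rib_min <- apply(sdm$dist, 1, min)
  aa_min <- apply(sdm$dist, 2, min)
  tibble::tibble(
    threshold = thr,
    n_rib_interacting = vapply(
      thr, function(t) sum(rib_min <= t + DIST_EPS), integer(1)),
    n_aa_interacting = vapply(
      thr, function(t) sum(aa_min <= t + DIST_EPS), integer(1))
  )
}

#' Per-position distance profile of the selected tRNA
#'
#' For every universal tRNA position of the assignment: the minimum set
#' distance to any amino acid, the number of amino acids within the
#' threshold, and whether the position is crystallographically determined.
#' This is the content of a per-entry interaction map.
#'
#' @param model a `trna_complex`.
#' @param assignment tibble mapping crystal residues of the selected tRNA
#'   chain to Sprinzl labels: columns `seq_id` and `label` (plus optionally
#'   `icode`). Labels absent from the crystal may be included as rows with
#'   `seq_id = NA` and are reported as undetermined.
#' @param threshold interaction threshold in Angstrom (default 3.3).
#' @param sdm optional precomputed [set_distance_matrix()] result.
#' @return tibble of class `trna_distance_profile`: label, region, seq_id,
#'   min_distance, n_interacting_aa, determined.
#' @export
distance_profile <- function(model, assignment, threshold = 3.3, sdm = NULL) {
  sdm <- sdm %||% set_distance_matrix(model)
  stopifnot(all(c("seq_id", "label") %in% names(assignment)))
  rib <- sdm$rib
  min_d <- unname(apply(sdm$dist, 1, min))
  n_aa <- unname(rowSums(sdm$dist <= threshold + DIST_EPS))
  idx <- match(assignment$seq_id, rib$seq_id)
  out <- tibble::tibble(
    label = as.character(assignment$label),
    region = region_of(as.character(assignment$label)),
    seq_id = assignment$seq_id,
    min_distance = min_d[idx],
    n_interacting_aa = as.integer(n_aa[idx]),
    determined = !is.na(idx)
  )
  out$n_interacting_aa[!out$determined] <- NA_integer_
  class(out) <- c("trna_distance_profile", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "entry_id") <- model$entry_id
  out
}

#' Entry-level interface summary
#'
#' Counts of interacting ribonucleotides and amino acids against the totals
#' present in the structure (the crystallographically determined residues),
#' plus the surface universe when an RSA profile is supplied.
#'
#' @param model a `trna_complex`.
#' @param contacts tibble from [find_contacts()].
#' @param rsa optional tibble from [compute_rsa()]; adds `n_aa_surface`.
#' @param surface_cutoff,surface_direction passed to [surface_residues()]
#'   when `rsa` is given.
#' @return one-row tibble: entry_id, n_rib_interacting, n_rib_total,
#'   rib_ratio, n_aa_interacting, n_aa_total, aa_ratio, n_aa_surface,
#'   aa_surface_ratio (ratios rounded to 2 decimals).
#' @export
interface_summary <- function(model, contacts, rsa = NULL,
                              surface_cutoff = 0.20,
                              surface_direction = "below") {
  res <- complex_residues(model)
  trna_chain <- select_trna(model)
  n_rib_total <- sum(res$chain == trna_chain & res$kind == "ribonucleotide")
  n_aa_total <- sum(res$chain %in% model$protein_chains &
                      res$kind == "amino_acid")
  n_rib <- nrow(dplyr::distinct(contacts, .data$rib_chain, .data$rib_seq,
                                .data$rib_icode))
  n_aa <- nrow(dplyr::distinct(contacts, .data$aa_chain, .data$aa_seq,
                               .data$aa_icode))
  out <- tibble::tibble(
    entry_id = model$entry_id,
    n_rib_interacting = n_rib, n_rib_total = n_rib_total,
    rib_ratio = round(n_rib / n_rib_total, 2),
    n_aa_interacting = n_aa, n_aa_total = n_aa_total,
    aa_ratio = round(n_aa / n_aa_total, 2)
  )
  if (!is.null(rsa)) {
    surf <- surface_residues(rsa, cutoff = surface_cutoff,
                             direction = surface_direction)
    out$n_aa_surface <- nrow(surf)
    out$aa_surface_ratio <- round(n_aa / max(nrow(surf), 1), 2)
  }
  out
}
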