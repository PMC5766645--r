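# Region-level interacting scores across complexes, the 25%-undetermined
# rule, representative selection, correlation distance over pairwise-complete
# regions, and complete-linkage clustering of interaction patterns.

#' Per-region interacting scores of one complex
#'
#' For each of the fifteen cloverleaf sequence regions, the sum of the
#' number of interacting amino acids per ribonucleotide is normalized to the
#' number of ribonucleotides in the region. Positions undetermined in the
#' crystal are excluded from the calculation, and a region with 25% or more
#' undetermined positions is reported as undetermined (score `NA`).
#' `e`-labelled variable-arm positions are excluded throughout.
#'
#' @param profile `trna_distance_profile` from [distance_profile()].
#' @param denominator `"determined"` (default) divides by the number of
#'   determined positions in the region; `"all"` divides by all positions of
#'   the region present in the original tRNA.
#' @return tibble of class `trna_region_scores`: region, score, n_positions,
#'   n_determined, n_undetermined, undetermined.
#' @export
region_scores <- function(profile, denominator = c("determined", "all")) {
  denominator <- match.arg(denominator)
  mask <- mark_undetermined(profile)
  out <- profile |>
    dplyr::filter(.data$region != "excluded", !is.na(.data$region)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_positions = dplyr::n(),
      n_determined = sum(.data$determined),
      n_undetermined = sum(!.data$determined),
      incidence = sum(.data$n_interacting_aa[.data$determined]),
      .groups = "drop") |>
    dplyr::left_join(mask, by = "region") |>
    dplyr::mutate(
      denom = if (denominator == "determined") .data$n_determined
              else .data$n_positions,
      score = ifelse(.data$undetermined | .data$denom == 0, NA_real_,
                     .data$incidence / .data$denom)) |>
    dplyr::select("region", "score", "n_positions", "n_determined",
                  "n_undetermined", "undetermined")
  out <- out[match(paste0("S", 1:15), out$region), ]
  out <- out[!is.na(out$region), ]
  class(out) <- c("trna_region_scores", class(out))
  attr(out, "entry_id") <- attr(profile, "entry_id")
  out
}

#' Undetermined-region mask (25% rule)
#'
#' A sequence region is regarded as undetermined when 25% or more of its
#' ribonucleotides are structurally undetermined in the crystal (inclusive
#' at exactly 25%).
#'
#' @param assignment tibble with columns `region` and `determined` (a
#'   `sprinzl_assignment` with crystal coverage, or a distance profile).
#' @return tibble: region, undetermined (logical).
#' @export
mark_undetermined <- function(assignment) {
  assignment |>
    dplyr::filter(.data$region != "excluded", !is.na(.data$region)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      undetermined = mean(!.data$determined) >= 0.25 - 1e-12,
      .groups = "drop")
}

#' Assemble a complexes-by-regions score matrix
#'
#' @param score_list named list of `trna_region_scores` (names = complex
#'   ids), or a long tibble with columns `complex_id`, `region`, `score`.
#' @param metadata optional tibble keyed by `complex_id` (domain of life,
#'   tRNA type, aaRS class...) joined onto the result.
#' @return wide tibble of class `trna_region_matrix`: complex_id, any
#'   metadata, then S1..S15 (NA = undetermined).
#' @export
region_score_matrix <- function(score_list, metadata = NULL) {
  long <- if (is.data.frame(score_list)) {
    score_list
  } else {
    purrr::imap(score_list, function(s, id) {
      tibble::tibble(complex_id = id, region = s$region, score = s$score)
    }) |> dplyr::bind_rows()
  }
  wide <- long |>
    dplyr::select("complex_id", "region", "score") |>
    tidyr::pivot_wider(names_from = "region", values_from = "score")
  keep <- c("complex_id", intersect(paste0("S", 1:15), names(wide)))
  wide <- wide[, keep]
  if (!is.null(metadata)) {
    wide <- dplyr::left_join(wide, metadata, by = "complex_id")
    wide <- wide[, c("complex_id", setdiff(names(metadata), "complex_id"),
                     intersect(paste0("S", 1:15), names(wide)))]
  }
  class(wide) <- c("trna_region_matrix", class(wide))
  wide
}

#' Normalize scores to per-domain heat ranks
#'
#' Divides every score by the maximum score within its domain of life so the
#' strongest interaction in each domain maps to 1.0, clipped to \[0, 1\].
#'
#' @param matrix `trna_region_matrix` with a `domain` column (or one domain).
#' @return the matrix with scores replaced by ranks in \[0, 1\]; the
#'   per-domain maxima are stored in `attr(, "domain_max")`.
#' @export
normalize_heat_ranks <- function(matrix) {
  cols <- intersect(paste0("S", 1:15), names(matrix))
  dom <- if ("domain" %in% names(matrix)) matrix$domain
         else rep("all", nrow(matrix))
  mx <- tapply(unlist(matrix[, cols]),
               rep(dom, times = length(cols)), max, na.rm = TRUE)
  for (col in cols) {
    matrix[[col]] <- as.numeric(
      pmin(matrix[[col]] / unname(mx[as.character(dom)]), 1))
  }
  attr(matrix, "domain_max") <- mx
  matrix
}

#' Select a representative complex per group
#'
#' Within each group (one per cognate amino acid, optionally per domain),
#' the complex with the fewest undetermined tRNA positions is selected; ties
#' are broken by lexicographic accession order. Groups whose best complex
#' still has more than `max_undetermined` undetermined positions are kept
#' but flagged.
#'
#' @param candidates tibble with columns `complex_id`, `group` (e.g. the
#'   cognate amino acid) and `n_undetermined`.
#' @param max_undetermined flag limit (default 3).
#' @return tibble: group, complex_id, n_undetermined, flagged.
#' @export
select_representative <- function(candidates, max_undetermined = 3) {
  candidates |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(.data$n_undetermined, .data$complex_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = .data$n_undetermined > max_undetermined) |>
    dplyr::select("group", "complex_id", "n_undetermined", "flagged")
}

#' Correlation distance between complexes
#'
#' One minus the Pearson product-moment correlation of the region score
#' vectors, computed over the regions determined in both complexes
#' (pairwise-complete observations). A pair sharing fewer than
#' `min_shared` determined regions, or with zero variance in the shared
#' regions, gets a missing distance.
#'
#' @param matrix `trna_region_matrix` (or any tibble with `complex_id` and
#'   S1..S15 columns).
#' @param min_shared minimum shared determined regions (default 3).
#' @return symmetric distance matrix (complexes x complexes) with zero
#'   diagonal; `NA` where undefined.
#' @export
correlation_distance_matrix <- function(matrix, min_shared = 3) {
  cols <- intersect(paste0("S", 1:15), names(matrix))
  X <- t(as.matrix(matrix[, cols]))
  colnames(X) <- matrix$complex_id
  if (ncol(X) < 2) rlang::abort("need at least two complexes")
  suppressWarnings(
    cc <- stats::cor(X, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(X))
  cc[shared < min_shared] <- NA
  d <- 1 - cc
  diag(d) <- 0
  if (all(is.na(d[upper.tri(d)]))) {
    rlang::abort("all pairwise distances undefined; clustering impossible")
  }
  d
}

#' Cluster complexes by interaction pattern
#'
#' Complete-linkage (furthest neighbor) agglomerative clustering of the
#' correlation distances. Missing distances are imputed with the matrix
#' maximum before linkage so incomparable complexes merge last; rows are
#' ordered by accession beforehand so ties resolve deterministically with
#' the lower accession on the left.
#'
#' @param dist symmetric distance matrix from
#'   [correlation_distance_matrix()].
#' @return object of class `trna_clust`: list with `hclust` (the stats
#'   object), `imputed` (tibble of imputed pairs) and `dist`.
#' @export
cluster_complexes <- function(dist) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  ord <- order(rownames(dist))
  dist <- dist[ord, ord]
  miss <- which(is.na(dist) & upper.tri(dist), arr.ind = TRUE)
  imputed <- tibble::tibble(
    a = rownames(dist)[miss[, 1]], b = colnames(dist)[miss[, 2]])
  if (nrow(imputed)) {
    mx <- max(dist, na.rm = TRUE)
    dist[is.na(dist)] <- mx
    rlang::inform(sprintf(
      "imputed %d missing distance(s) with the matrix maximum %.3f",
      nrow(imputed), mx))
  }
  hc <- stats::hclust(stats::as.dist(dist), method = "complete")
  structure(list(hclust = hc, imputed = imputed, dist = dist),
            class = "trna_clust")
}

#' @export
print.trna_clust <- function(x, ...) {
  cat("<trna_clust> complete-linkage clustering of",
      length(x$hclust$labels), "complexes\n")
  cat("  merge heights:",
      paste(sprintf("%.3f", x$hclust$height), collapse = ", "), "\n")
  if (nrow(x$imputed)) {
    cat("  imputed distances:", nrow(x$imputed), "\n")
  }
  invisible(x)
}

#' Export a clustering as a Newick tree
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param clust `trna_clust` object.
#' @param file optional output path.
#' @return Newick string (invisibly when written to file).
#' @export
cluster_newick <- function(clust, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    rlang::abort("Newick export needs the 'ape' package")
  }
  phy <- ape::as.phylo(clust$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
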