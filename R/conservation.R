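# Evolutionary conservation of tRNA positions: per-column Shannon entropy
# over sequences stacked on their universal positions, nine-rank scores,
# base-frequency tables and region-level summaries.

#' Filter a tRNA record set for conservation analysis
#'
#' Keeps records that (a) are not pseudogenes, (b) have a canonical
#' cloverleaf following the universal positioning rules, and (c) contain no
#' characters other than A, U, G and C. Identical (species, isoacceptor,
#' sequence) triplets collapse to one record regardless of genomic copy
#' number; distinct sequences of the same isoacceptor within a species are
#' all kept unless `one_per_species = TRUE`.
#'
#' @param records tibble with columns `species`, `isoacceptor`, `sequence`,
#'   `pseudogene` (logical) and either `canonical` (logical) or `ss`
#'   (dot-bracket, tested via [is_canonical()]). Extra columns pass through.
#' @param one_per_species keep only the first distinct sequence per
#'   (species, isoacceptor) (default `FALSE`).
#' @return filtered tibble (possibly empty, with a warning).
#' @export
filter_records <- function(records, one_per_species = FALSE) {
  stopifnot(all(c("species", "isoacceptor", "sequence", "pseudogene")
                %in% names(records)))
  out <- dplyr::filter(records, !.data$pseudogene)
  out <- dplyr::filter(
    out, !grepl("[^AUGCaugc]", gsub("T", "U", toupper(.data$sequence))))
  if ("canonical" %in% names(out)) {
    out <- dplyr::filter(out, .data$canonical)
  } else if ("ss" %in% names(out)) {
    ok <- purrr::map2_lgl(out$sequence, out$ss,
                          function(s, d) is_canonical(s, d)$canonical)
    out <- out[ok, ]
  }
  out <- dplyr::distinct(out, .data$species, .data$isoacceptor,
                         .data$sequence, .keep_all = TRUE)
  if (one_per_species) {
    out <- dplyr::distinct(out, .data$species, .data$isoacceptor,
                           .keep_all = TRUE)
  }
  if (nrow(out) == 0) rlang::warn("no records survive filtering")
  out
}

#' Shannon entropy of an alignment column
#'
#' `H = -sum f(b) log2 f(b)` over the bases A, C, G, U, with frequencies
#' computed over non-gap observations only (gaps are skipped) and
#' `0 * log 0 = 0`. An all-gap column has no entropy (`NA`).
#'
#' @param column character vector of bases; `NA`, `"-"` and `"."` are gaps.
#' @return entropy in bits, in \[0, 2\].
#' @examples
#' column_entropy(c("A", "A", "U", "U"))  # 1 bit
#' @export
column_entropy <- function(column) {
  obs <- column[!is.na(column) & !column %in% c("-", ".")]
  if (!length(obs)) return(NA_real_)
  f <- table(factor(obs, levels = c("A", "C", "G", "U"))) / length(obs)
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Nine-rank conservation score from entropy
#'
#' The entropy range \[0, 2\] bits is divided into nine equal-width bins;
#' rank 9 is the most conserved bin (containing 0) and rank 1 the most
#' variable (containing 2). A value exactly on a bin edge falls to the
#' more-conserved rank.
#'
#' @param h entropy in bits (vectorized); values outside \[0, 2\] beyond
#'   numeric slack are an error.
#' @return integer rank 1-9 (`NA` for `NA` input).
#' @examples
#' rank_entropy(c(0, 1, 2))  # 9 5 1
#' @export
rank_entropy <- function(h) {
  if (any(h < -1e-9 | h > 2 + 1e-9, na.rm = TRUE)) {
    rlang::abort("entropy out of range [0, 2] bits")
  }
  h <- pmin(pmax(h, 0), 2)
  r <- 9L - as.integer(ceiling(h / (2 / 9))) + 1L
  as.integer(pmin(r, 9L))
}

#' Stack tRNA records on their universal positions
#'
#' Realizes the structure-based alignment: no heuristic multiple alignment,
#' sequences are stacked position-wise on their Sprinzl labels. Records lack
#' optional labels (17a, 20a, 20b, ...) simply contribute gaps there.
#'
#' @param records tibble with a list-column `assignment` (each element a
#'   `sprinzl_assignment` for that record's sequence) or columns
#'   `sequence` + `ss` from which assignments are computed.
#' @return long tibble: record number `seq`, `label`, `base`.
#' @export
stack_by_label <- function(records) {
  if (!"assignment" %in% names(records)) {
    records$assignment <- purrr::map2(
      records$sequence, records$ss,
      function(s, d) assign_from_secondary_structure(s, d))
  }
  purrr::imap(records$assignment, function(a, i) {
    a <- dplyr::filter(a, !is.na(.data$label))
    tibble::tibble(seq = i, label = a$label, base = a$base)
  }) |> dplyr::bind_rows()
}

#' Per-position conservation profile of an isoacceptor group
#'
#' Entropy, nine-rank score and coverage for every universal position
#' observed in the group. Conservation is computed within one isoacceptor
#' group (tRNAs sharing a cognate amino acid), never across groups.
#' `e`-labelled variable-arm positions and the 3' terminal CCA (labels
#' 74-76, not always genomically encoded) are excluded.
#'
#' @param records record tibble (see [stack_by_label()]); when an
#'   `isoacceptor` column is present it must be unique or `group` given.
#' @param group optional isoacceptor to filter on.
#' @param mask_labels additional labels to drop (e.g.
#'   `c("17", "17a", "20a", "20b", "45", "46", "47")` to mirror a display
#'   that omits sparsely occupied positions).
#' @return tibble of class `trna_entropy_profile`: label, region, entropy,
#'   rank, coverage, ordered 5' to 3'.
#' @export
conservation_profile <- function(records, group = NULL,
                                 mask_labels = character()) {
  if (!is.null(group) && "isoacceptor" %in% names(records)) {
    records <- dplyr::filter(records, .data$isoacceptor == group)
  }
  if ("isoacceptor" %in% names(records) &&
      length(unique(records$isoacceptor)) > 1) {
    rlang::abort("records span several isoacceptor groups; pass `group`")
  }
  if (nrow(records) == 0) {
    out <- tibble::tibble(label = character(), region = character(),
                          entropy = numeric(), rank = integer(),
                          coverage = integer())
    class(out) <- c("trna_entropy_profile", class(out))
    return(out)
  }
  long <- stack_by_label(records)
  long <- dplyr::filter(
    long,
    !grepl("^e[0-9]+$", .data$label),
    !.data$label %in% c("74", "75", "76"),
    !.data$label %in% mask_labels)
  out <- long |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(entropy = column_entropy(.data$base),
                     coverage = sum(!is.na(.data$base) &
                                      !.data$base %in% c("-", ".")),
                     .groups = "drop") |>
    dplyr::mutate(rank = rank_entropy(.data$entropy),
                  region = region_of(.data$label)) |>
    dplyr::arrange(sprinzl_order(.data$label)) |>
    dplyr::select("label", "region", "entropy", "rank", "coverage")
  class(out) <- c("trna_entropy_profile", class(out))
  attr(out, "n_sequences") <- nrow(records)
  out
}

#' Base-frequency table per universal position
#'
#' Fraction of A, C, G and U at every position, over non-gap observations.
#'
#' @inheritParams conservation_profile
#' @return tibble: label, region, base, freq, n (non-gap observations);
#'   per-label fractions sum to 1.
#' @export
frequency_table <- function(records, group = NULL) {
  if (!is.null(group) && "isoacceptor" %in% names(records)) {
    records <- dplyr::filter(records, .data$isoacceptor == group)
  }
  long <- stack_by_label(records)
  long <- dplyr::filter(long, !is.na(.data$base),
                        !.data$base %in% c("-", "."))
  long |>
    dplyr::group_by(.data$label) |>
    dplyr::count(base = factor(.data$base, levels = c("A", "C", "G", "U")),
                 .drop = FALSE) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(base = as.character(.data$base),
                  region = region_of(.data$label)) |>
    dplyr::arrange(sprinzl_order(.data$label), .data$base) |>
    dplyr::select("label", "region", "base", "freq", "n")
}

#' Region-level conservation summary
#'
#' Mean nine-rank conservation per cloverleaf region, with the standard
#' error of the mean. CCA and `e`-labels are already absent from the
#' profile.
#'
#' @param profile `trna_entropy_profile`.
#' @return tibble: region, mean_rank, se, n_labels.
#' @export
region_conservation <- function(profile) {
  if (nrow(profile) == 0) rlang::abort("empty entropy profile")
  profile |>
    dplyr::filter(!is.na(.data$rank)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      mean_rank = mean(.data$rank),
      se = stats::sd(.data$rank) / sqrt(dplyr::n()),
      n_labels = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$region, paste0("S", 1:15)))
}

#' Join interaction and conservation summaries per region
#'
#' Pairs the mean interacting-amino-acid score with the mean conservation
#' rank per region, the content of an interaction-versus-conservation
#' scatter.
#'
#' @param region_scores_summary tibble with `region` and a mean interaction
#'   column (`mean_score` or `score`).
#' @param conservation_summary tibble from [region_conservation()].
#' @return joined tibble: region, mean_score, mean_rank, se.
#' @export
interaction_vs_conservation <- function(region_scores_summary,
                                        conservation_summary) {
  if (!"mean_score" %in% names(region_scores_summary)) {
    region_scores_summary <- dplyr::rename(region_scores_summary,
                                           mean_score = "score")
  }
  dplyr::inner_join(
    dplyr::select(region_scores_summary, "region", "mean_score"),
    conservation_summary, by = "region")
}
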