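# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a parsed complex into its residue table
#'
#' @param x a `trna_complex`.
#' @param ... unused.
#' @return tibble, one row per residue (see [complex_residues()]).
#' @method tidy trna_complex
#' @export
tidy.trna_complex <- function(x, ...) complex_residues(x)

#' One-row summary of a parsed complex
#'
#' @param x a `trna_complex`.
#' @param ... unused.
#' @return tibble: entry_id, assembly_index, n_atoms, n_residues,
#'   n_trna_chains, n_protein_chains, selected_trna.
#' @method glance trna_complex
#' @export
glance.trna_complex <- function(x, ...) {
  res <- complex_residues(x)
  tibble::tibble(
    entry_id = x$entry_id,
    assembly_index = x$assembly_index,
    n_atoms = nrow(x$atoms),
    n_residues = nrow(res),
    n_trna_chains = length(x$trna_chains),
    n_protein_chains = length(x$protein_chains),
    selected_trna = x$selected_trna)
}

#' Tidy a complete-linkage clustering into its merge table
#'
#' @param x a `trna_clust`.
#' @param ... unused.
#' @return tibble, one row per merge: step, height, and the two merged
#'   members (negative numbers are leaves, following [stats::hclust()]).
#' @method tidy trna_clust
#' @export
tidy.trna_clust <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    step = seq_along(hc$height),
    height = hc$height,
    member1 = hc$merge[, 1],
    member2 = hc$merge[, 2])
}

#' One-row summary of a clustering
#'
#' @param x a `trna_clust`.
#' @param ... unused.
#' @return tibble: n_complexes, n_merges, max_height, n_imputed.
#' @method glance trna_clust
#' @export
glance.trna_clust <- function(x, ...) {
  tibble::tibble(
    n_complexes = length(x$hclust$labels),
    n_merges = length(x$hclust$height),
    max_height = max(x$hclust$height),
    n_imputed = nrow(x$imputed))
}

#' Tidy an entropy profile (drops the class, keeps the table)
#'
#' @param x a `trna_entropy_profile`.
#' @param ... unused.
#' @method tidy trna_entropy_profile
#' @export
tidy.trna_entropy_profile <- function(x, ...) {
  tibble::as_tibble(unclass_first(x))
}

#' @noRd
unclass_first <- function(x) {
  class(x) <- setdiff(class(x), class(x)[1])
  x
}
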