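# Solvent accessibility: Shrake-Rupley sphere-sampling ASA with a probe of
# 1.4 Angstrom, normalized to per-residue-type maxima to give relative
# accessible surface area (RSA). Used to define the synthetase surface
# universe.

# deterministic, nearly uniform points on the unit sphere (golden spiral)
#' @noRd
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative accessible surface area of the protein component
#'
#' Shrake-Rupley sphere sampling: each atom's van der Waals sphere is
#' expanded by the probe radius and covered with a deterministic quasi-uniform
#' point set; the accessible fraction is the share of points outside all
#' neighboring expanded spheres. Per-residue ASA is normalized by a shipped
#' per-residue-type theoretical maximum to give RSA.
#'
#' By default the area is computed on the protein component alone (tRNA and
#' other molecules removed), since the surface universe is a property of the
#' enzyme; `context = "complex"` keeps all polymer atoms as occluders.
#'
#' @param model a `trna_complex`.
#' @param context `"protein"` (default) or `"complex"`.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sampling points per atom (default 960).
#' @return tibble of class `trna_rsa`: chain, seq_id, icode, res_name, asa,
#'   max_asa, rsa. Residues with no atoms after filtering are dropped with a
#'   warning; residue types without a reference maximum get `rsa = NA`.
#' @export
compute_rsa <- function(model, context = c("protein", "complex"),
                        probe = 1.4, n_points = 960) {
  stopifnot(inherits(model, "trna_complex"))
  context <- match.arg(context)
  occl <- if (context == "protein") {
    dplyr::filter(model$atoms, .data$chain %in% model$protein_chains,
                  .data$kind == "amino_acid")
  } else {
    dplyr::filter(model$atoms, .data$kind != "other")
  }
  target <- dplyr::filter(occl, .data$kind == "amino_acid",
                          .data$chain %in% model$protein_chains)
  if (nrow(target) == 0) rlang::abort("no protein chains present")

  asa <- atom_asa(occl, probe = probe, n_points = n_points)
  occl$asa <- asa
  prof <- occl |>
    dplyr::filter(.data$kind == "amino_acid",
                  .data$chain %in% model$protein_chains) |>
    dplyr::group_by(.data$chain, .data$seq_id, .data$icode,
                    .data$res_name) |>
    dplyr::summarise(asa = sum(.data$asa), .groups = "drop")
  prof$max_asa <- unname(max_asa_table()[prof$res_name])
  prof$max_asa[prof$res_name == "MSE"] <- max_asa_table()[["MET"]]
  # an isolated residue exceeds its in-chain reference maximum; cap at 1
  prof$rsa <- pmin(prof$asa / prof$max_asa, 1)
  class(prof) <- c("trna_rsa", class(prof))
  prof
}

# per-atom accessible surface area over a set of occluding atoms
#' @noRd
atom_asa <- function(atoms, probe = 1.4, n_points = 960) {
  xyz <- as_coord_matrix(atoms)
  radius <- vdw_radius(atoms$element) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # coarse neighbor lists via chunked squared-distance cutoff
  max_r <- max(radius)
  chunk <- 512L
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    d2 <- cross_dist2(xyz[idx, , drop = FALSE], xyz)
    cutoff2 <- outer(radius[idx], radius, "+")^2
    for (k in seq_along(idx)) {
      i <- idx[k]
      nb <- which(d2[k, ] < cutoff2[k, ] & seq_len(n) != i)
      surf <- pts * radius[i] + rep(xyz[i, ], each = n_points)
      if (length(nb) == 0) {
        frac <- 1
      } else {
        dn <- cross_dist2(surf, xyz[nb, , drop = FALSE])
        covered <- dn < rep(radius[nb]^2, each = n_points)
        frac <- mean(!matrixStats_rowAnys(covered))
      }
      out[i] <- 4 * pi * radius[i]^2 * frac
    }
  }
  out
}

# rowAnys without the matrixStats dependency
#' @noRd
matrixStats_rowAnys <- function(m) {
  if (is.null(dim(m))) return(m)
  rowSums(m) > 0
}

#' Select surface (or buried) residues by RSA cutoff
#'
#' The surface criterion is expressed as an RSA inequality against a cutoff
#' (default 20%). `direction = "below"` selects residues with RSA strictly
#' below the cutoff, `"at_or_above"` the complement; both directions are
#' exposed because the conventional definition of "exposed" is RSA at or
#' above the cutoff while the criterion may be printed the other way around.
#'
#' @param rsa tibble from [compute_rsa()].
#' @param cutoff RSA fraction in (0, 1); default 0.20.
#' @param direction `"below"` (default) or `"at_or_above"`.
#' @return tibble of the selected residues (subset of `rsa` rows).
#' @export
surface_residues <- function(rsa, cutoff = 0.20,
                             direction = c("below", "at_or_above")) {
  direction <- match.arg(direction)
  if (!(cutoff > 0 && cutoff < 1)) rlang::abort("cutoff must be in (0, 1)")
  keep <- if (direction == "below") rsa$rsa < cutoff else rsa$rsa >= cutoff
  rsa[which(keep), ]
}
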