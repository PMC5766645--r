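# Universal tRNA coordinate system: canonical label ordering, the fifteen
# cloverleaf sequence regions, and residue-name vocabularies shared by the
# structure and sequence modules.

#' Universal tRNA position labels in canonical order
#'
#' The universal (Sprinzl) coordinate system numbers tRNA positions 1-76 with
#' optional insertions 17a, 20a and 20b in the D-loop. Long variable arms are
#' labelled with `e`-prefixed positions (`e1`, `e2`, ...) which sort between
#' positions 48 and 49; they are excluded from region statistics. Positions
#' 74-76 are the 3' terminal C, C, A.
#'
#' @param n_e number of `e`-prefixed variable-arm labels to interleave
#'   (default 0, i.e. the 79 canonical labels).
#' @return character vector of labels in 5' to 3' order.
#' @examples
#' head(sprinzl_labels(), 20)
#' @export
sprinzl_labels <- function(n_e = 0) {
  base <- as.character(1:76)
  # insertions after 17 and after 20
  out <- append(base, "17a", after = match("17", base))
  out <- append(out, c("20a", "20b"), after = match("20", out))
  if (n_e > 0) {
    out <- append(out, paste0("e", seq_len(n_e)), after = match("48", out))
  }
  out
}

#' Rank of a label in the canonical 5' to 3' ordering
#'
#' Numeric labels and D-loop insertions get their canonical rank; `e`-labels
#' are placed between 48 and 49 in their own numeric order.
#'
#' @param label character vector of Sprinzl labels.
#' @return numeric rank usable for sorting; `NA` for unknown labels.
#' @export
sprinzl_order <- function(label) {
  canon <- sprinzl_labels()
  r <- match(label, canon)
  is_e <- grepl("^e[0-9]+$", label)
  r[is_e] <- match("48", canon) + as.numeric(sub("^e", "", label[is_e])) / 1e3
  as.numeric(r)
}

#' The fifteen cloverleaf sequence regions
#'
#' Partition of the universal tRNA positions 1-76 into fifteen contiguous
#' sequence regions following the cloverleaf secondary structure: acceptor
#' stem (S1, S14), inter-stem residues (S2, S6), D-stem (S3, S5), D-loop
#' (S4), anticodon stem (S7, S9) and loop (S8), variable region (S10),
#' T-stem (S11, S13) and loop (S12), and the 3' CCA region (S15). D-loop
#' insertions 17a/20a/20b belong to S4.
#'
#' @return tibble with columns `region`, `from`, `to` (numeric label spans).
#' @examples
#' region_table()
#' @export
region_table <- function() {
  tibble::tibble(
    region = paste0("S", 1:15),
    from = c(1, 8, 10, 14, 22, 26, 27, 32, 39, 44, 49, 54, 61, 66, 73),
    to   = c(7, 9, 13, 21, 25, 26, 31, 38, 43, 48, 53, 60, 65, 72, 76)
  )
}

#' Map a Sprinzl label to its cloverleaf region
#'
#' @param label character vector of Sprinzl labels (`"34"`, `"17a"`, `"e3"`...).
#' @return character vector: region id `"S1"`..`"S15"`, or `"excluded"` for
#'   `e`-prefixed variable-arm labels.
#' @examples
#' region_of(c("34", "73", "e11", "17a"))
#' @export
region_of <- function(label) {
  label <- as.character(label)
  bad <- !label %in% sprinzl_labels() & !grepl("^e[0-9]+$", label)
  if (any(bad)) {
    rlang::abort(paste0("unknown Sprinzl label(s): ",
                        paste(unique(label[bad]), collapse = ", ")))
  }
  num <- suppressWarnings(as.numeric(sub("[ab]$", "", label)))
  rt <- region_table()
  idx <- findInterval(num, rt$from)
  out <- ifelse(is.na(num), "excluded", rt$region[pmax(idx, 1)])
  out[!is.na(num) & (num < 1 | num > 76)] <- "excluded"
  out
}

# ---- residue-name vocabularies --------------------------------------------

#' @noRd
standard_amino_acids <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# modified amino-acid residue names routinely deposited inside polymer chains
#' @noRd
modified_amino_acids <- function() {
  c("MSE", "SEC", "PYL", "CME", "CSO", "PTR", "SEP", "TPO", "HYP", "MLY",
    "KCX", "LLP", "OCS", "CSD", "PCA")
}

#' @noRd
standard_ribonucleotides <- function() c("A", "U", "G", "C")

# common modified ribonucleotides found in tRNA crystal structures, mapped to
# their parent base (used both for chain typing and for sequence extraction)
#' @noRd
modified_ribonucleotides <- function() {
  c(PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", UR3 = "U", OMU = "U",
    "70U" = "U", "2MU" = "U", "1MA" = "A", MIA = "A", "6IA" = "A",
    RIA = "A", T6A = "A", A2M = "A", MA6 = "A", "12A" = "A",
    "2MG" = "G", M2G = "G", "7MG" = "G", G7M = "G", OMG = "G", YG = "G",
    YYG = "G", "1MG" = "G", QUO = "G", GDP = "G",
    "5MC" = "C", OMC = "C", "4OC" = "C", CBV = "C", M4C = "C",
    I = "A", N = "A")
}

#' @noRd
residue_kind <- function(res_name) {
  res_name <- toupper(res_name)
  dplyr::case_when(
    res_name %in% standard_ribonucleotides() ~ "ribonucleotide",
    res_name %in% names(modified_ribonucleotides()) ~ "ribonucleotide",
    res_name %in% standard_amino_acids() ~ "amino_acid",
    res_name %in% modified_amino_acids() ~ "amino_acid",
    TRUE ~ "other"
  )
}

# one-letter base for a ribonucleotide residue name (parent base for
# modified residues), NA otherwise
#' @noRd
parent_base <- function(res_name) {
  res_name <- toupper(res_name)
  out <- rep(NA_character_, length(res_name))
  std <- res_name %in% standard_ribonucleotides()
  out[std] <- res_name[std]
  mod <- res_name %in% names(modified_ribonucleotides())
  out[mod] <- unname(modified_ribonucleotides()[res_name[mod]])
  out
}

# ---- radii and reference areas --------------------------------------------

# van der Waals radii (Angstrom) by element, Bondi-style values
#' @noRd
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# theoretical maximum accessible surface areas (Angstrom^2) per residue type
# (Tien et al. 2013, theoretical set), used to normalize ASA into RSA
#' @noRd
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}
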