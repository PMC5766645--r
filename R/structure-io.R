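# Structure input: fixed-column legacy-PDB parsing, alternate-location
# resolution, chain typing by residue census, and reconstruction of the first
# biological assembly from REMARK 350 BIOMT operators.

#' Parse a tRNA-synthetase complex from a legacy PDB file
#'
#' Reads ATOM/HETATM records (first MODEL only), drops waters and free
#' ligands, resolves alternate locations by keeping the highest-occupancy
#' variant (ties broken by altloc character order), classifies every chain as
#' tRNA / protein / other by residue-name census (a chain is tRNA when at
#' least `chain_purity` of its residues are ribonucleotides, protein when at
#' least that fraction are amino acids), and optionally expands the first
#' biological assembly declared in the REMARK 350 annotation.
#'
#' HETATM residues with recognized modified-nucleotide or modified-amino-acid
#' names are kept as polymer residues; HETATM residues carrying a standard
#' amino-acid name are treated as free ligands (e.g. the amino-acid substrate
#' in the catalytic site) and excluded. Unknown polymer residue names are
#' classified `other` and excluded from distance work with a warning.
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @param assembly `"first"` (default) to apply the first biological assembly
#'   when BIOMT operators are present, `"asu"` to keep the asymmetric unit.
#' @param keep_hydrogens keep hydrogen atoms if present (default `TRUE`; the
#'   set distance is defined over all atoms of the two residues).
#' @param entry_id optional 4-character accession recorded in the model;
#'   defaults to the file name stem.
#' @param chain_purity residue-census fraction for chain typing (default 0.9).
#' @return a `trna_complex` object: a list with `entry_id`,
#'   `assembly_index`, `atoms` (tibble: chain, seq_id, icode, res_name, kind,
#'   atom, element, x, y, z, occupancy, altloc), `trna_chains`,
#'   `protein_chains`, `selected_trna`.
#' @examples
#' bp <- complex_blueprint(n_rib = 5, n_aa = 8,
#'   planted = tibble::tibble(rib = 2, aa = 3, distance = 3.0), seed = 1)
#' fx <- make_synthetic_complex(bp)
#' read_trna_complex(fx$pdb_lines, entry_id = "SYN1")
#' @export
read_trna_complex <- function(file, assembly = c("first", "asu"),
                              keep_hydrogens = TRUE, entry_id = NULL,
                              chain_purity = 0.9) {
  assembly <- match.arg(assembly)
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    entry_id <- entry_id %||% toupper(sub("\\.(pdb|ent)$", "", basename(file)))
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    entry_id <- entry_id %||% "XXXX"
  }
  if (tolower(substr(entry_id, 1, 4)) %in% c("cif", "mmci") ||
      any(grepl("^data_", head(lines, 5)))) {
    rlang::abort("mmCIF input is not supported; supply legacy PDB format")
  }

  atoms <- parse_pdb_atoms(lines)
  if (nrow(atoms) == 0) {
    rlang::abort("empty structure: no ATOM/HETATM records found")
  }
  atoms <- resolve_altlocs(atoms)
  atoms <- classify_and_prune(atoms)
  if (!keep_hydrogens) atoms <- dplyr::filter(atoms, .data$element != "H")
  if (nrow(atoms) == 0) {
    rlang::abort("empty structure: no polymer residues after filtering")
  }

  model <- new_trna_complex(entry_id, atoms, assembly_index = 0L,
                            chain_purity = chain_purity)

  if (assembly == "first") {
    ops <- parse_biomt(lines)
    if (length(ops)) model <- apply_first_assembly(model, ops)
  }
  model
}

# fixed-column parse of ATOM/HETATM records, first MODEL only
#' @noRd
parse_pdb_atoms <- function(lines) {
  # keep only the first model when MODEL/ENDMDL blocks are present
  mdl <- grep("^MODEL ", lines)
  if (length(mdl) >= 1) {
    endm <- grep("^ENDMDL", lines)
    stop_at <- if (length(endm)) endm[1] else length(lines)
    lines <- lines[seq_len(stop_at)]
  }
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (!length(sel)) return(tibble::tibble())
  rec <- lines[sel]
  fx <- function(a, b) trimws(substr(rec, a, b))
  x <- suppressWarnings(as.numeric(fx(31, 38)))
  y <- suppressWarnings(as.numeric(fx(39, 46)))
  z <- suppressWarnings(as.numeric(fx(47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    rlang::abort(paste0("malformed coordinate fields at line ", sel[bad[1]]))
  }
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1
  elem <- fx(77, 78)
  name <- fx(13, 16)
  # derive element from the atom-name column when column 77-78 is blank
  guess <- toupper(sub("^[0-9']*", "", name))
  guess <- substr(guess, 1, 1)
  elem <- ifelse(elem == "", guess, toupper(elem))
  tibble::tibble(
    record = substr(rec, 1, 6),
    atom = name,
    altloc = substr(rec, 17, 17),
    res_name = fx(18, 20),
    chain = substr(rec, 22, 22),
    seq_id = suppressWarnings(as.integer(fx(23, 26))),
    icode = substr(rec, 27, 27),
    x = x, y = y, z = z,
    occupancy = pmin(pmax(occ, 0), 1),
    element = elem
  )
}

# keep, per (residue, atom name), the highest-occupancy altloc; ties broken
# by altloc character order
#' @noRd
resolve_altlocs <- function(atoms) {
  atoms$altloc[atoms$altloc == " "] <- ""
  if (!any(atoms$altloc != "")) return(atoms)
  # pick the winner per (residue, atom name) but keep file order intact
  key <- paste(atoms$chain, atoms$seq_id, atoms$icode, atoms$atom)
  pref <- order(key, -atoms$occupancy, atoms$altloc)
  keep_rows <- pref[!duplicated(key[pref])]
  atoms[sort(keep_rows), ]
}

#' @noRd
classify_and_prune <- function(atoms) {
  atoms$res_name <- toupper(atoms$res_name)
  atoms <- dplyr::filter(atoms, !.data$res_name %in% c("HOH", "WAT", "DOD"))
  kind <- residue_kind(atoms$res_name)
  # HETATM with a standard amino-acid name = free substrate ligand, not polymer
  ligand <- atoms$record == "HETATM" &
    atoms$res_name %in% standard_amino_acids()
  kind[ligand] <- "other"
  atoms$kind <- kind
  unknown <- unique(atoms$res_name[atoms$kind == "other"])
  if (length(unknown)) {
    rlang::inform(paste0("excluding non-polymer/unknown residues: ",
                         paste(unknown, collapse = ", ")))
  }
  dplyr::select(atoms, -"record")
}

#' @noRd
new_trna_complex <- function(entry_id, atoms, assembly_index,
                             chain_purity = 0.9, selected = NULL) {
  census <- atoms |>
    dplyr::distinct(.data$chain, .data$seq_id, .data$icode, .data$kind) |>
    dplyr::count(.data$chain, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n",
                       values_fill = 0)
  for (col in c("ribonucleotide", "amino_acid", "other")) {
    if (!col %in% names(census)) census[[col]] <- 0
  }
  census$total <- census$ribonucleotide + census$amino_acid + census$other
  # preserve file order of chains
  order_in_file <- unique(atoms$chain)
  census <- census[match(order_in_file, census$chain), ]
  trna_chains <- census$chain[census$ribonucleotide / census$total >=
                                chain_purity]
  protein_chains <- census$chain[census$amino_acid / census$total >=
                                   chain_purity]
  protein_chains <- setdiff(protein_chains, trna_chains)
  structure(
    list(entry_id = entry_id,
         assembly_index = as.integer(assembly_index),
         atoms = atoms,
         trna_chains = trna_chains,
         protein_chains = protein_chains,
         selected_trna = selected %||%
           (if (length(trna_chains)) trna_chains[1] else NA_character_)),
    class = "trna_complex")
}

#' Parse REMARK 350 BIOMT operators from PDB lines
#'
#' @param lines character vector of PDB lines.
#' @return list of assemblies; each assembly is a list with `chains`
#'   (targeted chain labels) and `operators` (list of 3x4 matrices, rotation
#'   cbind translation). Empty list when no BIOMT annotation exists.
#' @export
parse_biomt <- function(lines) {
  r350 <- grep("^REMARK 350", lines, value = TRUE)
  if (!length(r350)) return(list())
  out <- list()
  cur <- NULL
  chains <- character()
  rows <- list()
  flush_op <- function() {
    if (length(rows) == 3) {
      op <- do.call(rbind, rows)
      cur$operators[[length(cur$operators) + 1]] <<- op
    }
    rows <<- list()
  }
  for (ln in r350) {
    if (grepl("BIOMOLECULE:", ln)) {
      if (!is.null(cur)) { flush_op(); cur$chains <- chains; out <- c(out, list(cur)) }
      cur <- list(chains = character(), operators = list())
      chains <- character()
    } else if (grepl("APPLY THE FOLLOWING TO CHAINS:|AND CHAINS:", ln)) {
      cc <- sub(".*CHAINS:", "", ln)
      chains <- c(chains, trimws(unlist(strsplit(cc, ","))))
      chains <- chains[chains != ""]
    } else if (grepl("BIOMT[123]", ln)) {
      if (is.null(cur)) cur <- list(chains = character(), operators = list())
      v <- suppressWarnings(as.numeric(
        unlist(strsplit(trimws(sub(".*BIOMT[123]", "", ln)), "\\s+"))))
      # v = opnum, r1, r2, r3, t
      rows[[length(rows) + 1]] <- v[2:5]
      if (grepl("BIOMT3", ln)) flush_op()
    }
  }
  if (!is.null(cur)) { flush_op(); cur$chains <- chains; out <- c(out, list(cur)) }
  out[vapply(out, function(a) length(a$operators) > 0, logical(1))]
}

#' Apply the first biological assembly to a parsed complex
#'
#' Transforms/copies the targeted chains by each BIOMT operator of the first
#' declared assembly only. The identity operator keeps the original chain
#' labels; every additional operator generates copies under fresh chain
#' labels. Operators whose rotation part is not right-handed within 1e-6
#' trigger a warning but are still applied.
#'
#' @param model a `trna_complex`.
#' @param biomt list of assemblies as returned by [parse_biomt()].
#' @return a `trna_complex` with `assembly_index = 1` (or the input unchanged
#'   with `assembly_index = 0` when `biomt` is empty).
#' @export
apply_first_assembly <- function(model, biomt) {
  stopifnot(inherits(model, "trna_complex"))
  if (!length(biomt)) {
    model$assembly_index <- 0L
    return(model)
  }
  asm <- biomt[[1]]
  chains <- if (length(asm$chains)) asm$chains else unique(model$atoms$chain)
  used <- unique(model$atoms$chain)
  fresh <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
  pieces <- list(dplyr::filter(model$atoms, !.data$chain %in% chains))
  for (k in seq_along(asm$operators)) {
    op <- asm$operators[[k]]
    rot <- op[, 1:3, drop = FALSE]
    trans <- op[, 4]
    if (abs(det(rot) - 1) > 1e-6) {
      rlang::warn(sprintf(
        "BIOMT operator %d is not right-handed (det = %.6f); applying anyway",
        k, det(rot)))
    }
    sub <- dplyr::filter(model$atoms, .data$chain %in% chains)
    xyz <- t(rot %*% t(as.matrix(sub[, c("x", "y", "z")])) + trans)
    sub$x <- xyz[, 1]; sub$y <- xyz[, 2]; sub$z <- xyz[, 3]
    if (k > 1) {
      # symmetry copy: relabel each source chain with a fresh label
      map <- setNames(fresh[seq_along(chains)], chains)
      fresh <- fresh[-seq_along(chains)]
      sub$chain <- unname(map[sub$chain])
    }
    pieces <- c(pieces, list(sub))
  }
  atoms <- dplyr::bind_rows(pieces)
  out <- new_trna_complex(model$entry_id, atoms, assembly_index = 1L)
  # keep the original (pre-expansion) tRNA selection when still present
  if (!is.na(model$selected_trna) && model$selected_trna %in% out$trna_chains) {
    out$selected_trna <- model$selected_trna
  }
  out
}

#' Select the working tRNA chain of a complex
#'
#' When the assembly contains more than one tRNA molecule, the first tRNA
#' chain in file order is used (the interaction patterns of symmetry copies
#' are essentially identical).
#'
#' @param model a `trna_complex`.
#' @return single chain label.
#' @export
select_trna <- function(model) {
  stopifnot(inherits(model, "trna_complex"))
  if (!length(model$trna_chains)) {
    rlang::abort(paste0("no tRNA chain found in ", model$entry_id))
  }
  model$trna_chains[1]
}

#' Residue-level view of a parsed complex
#'
#' @param model a `trna_complex`.
#' @return tibble with one row per residue: chain, seq_id, icode, res_name,
#'   kind, n_atoms.
#' @export
complex_residues <- function(model) {
  stopifnot(inherits(model, "trna_complex"))
  model$atoms |>
    dplyr::group_by(.data$chain, .data$seq_id, .data$icode, .data$res_name,
                    .data$kind) |>
    dplyr::summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$chain, unique(model$atoms$chain)),
                   .data$seq_id, .data$icode)
}

#' Write a complex back to legacy PDB lines
#'
#' Minimal ATOM-record writer used for round-trip tests and fixture export.
#'
#' @param model a `trna_complex`.
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_trna_complex <- function(model, file = NULL) {
  stopifnot(inherits(model, "trna_complex"))
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), format_atom_name(a$atom), a$res_name, a$chain,
    a$seq_id, ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

# PDB atom-name column convention: element symbols of one letter start in
# column 14, i.e. get a leading space unless the name is 4 characters
#' @noRd
format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, name, paste0(" ", formatC(name, width = -3)))
}

#' @export
print.trna_complex <- function(x, ...) {
  res <- complex_residues(x)
  cat("<trna_complex> ", x$entry_id,
      if (x$assembly_index > 0) " (first biological assembly)" else
        " (asymmetric unit)", "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), ", residues: ", nrow(res), "\n", sep = "")
  cat("  tRNA chains: ", paste(x$trna_chains, collapse = ", "),
      "  (selected: ", x$selected_trna, ")\n", sep = "")
  cat("  protein chains: ", paste(x$protein_chains, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @method as_tibble trna_complex
#' @export
as_tibble.trna_complex <- function(x, ...) x$atoms

#' Extract the tRNA sequence of the selected chain
#'
#' Modified ribonucleotides are mapped to their parent base.
#'
#' @param model a `trna_complex`.
#' @param chain chain label (default the selected tRNA chain).
#' @return tibble: seq_id, icode, res_name, base.
#' @export
trna_sequence <- function(model, chain = NULL) {
  chain <- chain %||% model$selected_trna
  complex_residues(model) |>
    dplyr::filter(.data$chain == !!chain,
                  .data$kind == "ribonucleotide") |>
    dplyr::mutate(base = parent_base(.data$res_name)) |>
    dplyr::select("seq_id", "icode", "res_name", "base")
}
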