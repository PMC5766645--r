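# In-code fixtures: hand-placed PDB records with exactly known geometry.

pdb_atom_line <- function(serial, name, res, chain, seq, x, y, z,
                          occ = 1, alt = " ", element = NULL,
                          record = "ATOM  ") {
  element <- element %||% substr(gsub("[0-9']", "", name), 1, 1)
  name_fmt <- if (nchar(name) >= 4) name else paste0(" ", formatC(name, width = -3))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, alt, res, chain, seq, x, y, z, occ, 0,
          element)
}

# complex of single-atom residues at given centers: exact set distances are
# just point distances. rib/aa: data frames with seq, x, y, z.
manual_complex_lines <- function(rib, aa) {
  serial <- 0
  lines <- character()
  for (i in seq_len(nrow(rib))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "P", "G", "T", rib$seq[i],
                                    rib$x[i], rib$y[i], rib$z[i],
                                    element = "P"))
  }
  for (i in seq_len(nrow(aa))) {
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CA", "ALA", "A", aa$seq[i],
                                    aa$x[i], aa$y[i], aa$z[i],
                                    element = "C"))
  }
  c(lines, "END")
}

manual_complex <- function(rib, aa, entry_id = "MANU") {
  suppressMessages(read_trna_complex(manual_complex_lines(rib, aa),
                                     entry_id = entry_id))
}

# identity Sprinzl assignment for a manual complex
identity_assignment <- function(n, undetermined = integer()) {
  tibble::tibble(
    seq_id = ifelse(seq_len(n) %in% undetermined, NA_integer_, seq_len(n)),
    label = as.character(seq_len(n)))
}
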