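# Tiny in-code PDB and table fixtures.

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, elem = NULL, alt = " ", record = "ATOM") {
  if (is.null(elem)) elem <- substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, x, y, z, occ, 0,
          elem)
}

# two chains, two residues, a hydrogen, a water and an altloc pair
write_minimal_pdb <- function(path, with_hydrogen = FALSE,
                              with_altloc = FALSE, with_water = FALSE,
                              second_model = FALSE) {
  lines <- c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(3, " CA ", "GLY", "B", 1, 3, 4, 0),
    pdb_line(4, " C  ", "GLY", "B", 1, 4.5, 4, 0))
  if (with_hydrogen)
    lines <- c(lines, pdb_line(5, " H  ", "ALA", "A", 1, 0.5, 0.5, 0,
                               elem = "H"))
  if (with_altloc)
    lines <- c(lines,
               pdb_line(6, " CB ", "ALA", "A", 1, 1.5, 1.5, 0, occ = 0.6,
                        alt = "A"),
               pdb_line(7, " CB ", "ALA", "A", 1, 1.6, 1.6, 0, occ = 0.4,
                        alt = "B"))
  if (with_water)
    lines <- c(lines, pdb_line(8, " O  ", "HOH", "A", 99, 9, 9, 9,
                               record = "HETATM"))
  if (second_model) {
    lines <- c("MODEL        1", lines, "ENDMDL", "MODEL        2",
               pdb_line(1, " CA ", "ALA", "A", 1, 99, 99, 99), "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# small valid labeling table (three residues, one complex)
write_labeling_fixture <- function(path, m_unbound = c(0.5, 0.5, 0.2),
                                   m_bound = c(0.5, 0.1, 0.3),
                                   chain = c("A", "A", "B"),
                                   resno = c(1, 2, 1),
                                   resname = c("ALA", "LEU", "LYS"),
                                   complex_id = "toy",
                                   measure_kind = "rate") {
  df <- data.frame(complex_id = complex_id, chain = chain,
                   residue_number = resno, residue_name = resname,
                   measure_kind = measure_kind, M_unbound = m_unbound,
                   M_bound = m_bound)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
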