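# hand-built toy structures and PDB text fixtures used across tests

# a 3-residue, 3-atom-per-residue toy chain with simple integer-ish
# coordinates (N, CA, C only)
toy_structure <- function(shift = 0) {
  rows <- list()
  for (i in 0:2) {
    base <- c(3.8 * i, 0, 0)
    rows[[i + 1]] <- data.frame(
      element = c("N", "C", "C"),
      atom_name = c("N", "CA", "C"),
      residue_index = i,
      residue_name = "ALA",
      x = base[1] + c(0, 1.2, 2.2) + shift,
      y = base[2] + c(0, 0.9, 0.4),
      z = base[3] + c(0, 0.3, 1.0),
      stringsAsFactors = FALSE)
  }
  qa_structure(do.call(rbind, rows))
}

# random cloud structure: n_res residues x atoms_per residue, coordinates
# uniform in a box; residue names alternate over a few types
random_structure <- function(n_res, atoms_per = 4, box = 18, seed = 1) {
  set.seed(seed)
  names4 <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CE1")[seq_len(atoms_per)]
  elem4 <- substr(gsub("[0-9]", "", names4), 1, 1)
  rows <- list()
  for (i in seq_len(n_res) - 1L) {
    rows[[i + 1]] <- data.frame(
      element = elem4, atom_name = names4, residue_index = i,
      residue_name = "LEU",
      x = runif(atoms_per, 0, box), y = runif(atoms_per, 0, box),
      z = runif(atoms_per, 0, box), stringsAsFactors = FALSE)
  }
  qa_structure(do.call(rbind, rows))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(s, seed = 1, translation = c(5, -3, 2)) {
  decoyQA:::.qa_transform(s, random_rotation(seed), translation)
}

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     elem, record = "ATOM", altloc = " ", occ = 1.00) {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resn, chain, resno, x, y, z, occ, 0, elem)
}

# two-chain, 3+2 residue PDB text with hydrogens, a water and an altloc pair
write_fixture_pdb <- function(path) {
  l <- c(
    pdb_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0.0, 0.0, "C"),
    pdb_line(3, "C",  "ALA", "A", 1, 2.0, 1.4, 0.0, "C"),
    pdb_line(4, "O",  "ALA", "A", 1, 1.5, 2.4, 0.5, "O"),
    pdb_line(5, "H",  "ALA", "A", 1, -0.5, 0.8, 0.0, "H"),
    pdb_line(6, "N",  "GLY", "A", 2, 3.3, 1.4, 0.0, "N"),
    pdb_line(7, "CA", "GLY", "A", 2, 4.1, 2.6, 0.2, "C", altloc = "A", occ = 0.7),
    pdb_line(8, "CA", "GLY", "A", 2, 4.2, 2.7, 0.3, "C", altloc = "B", occ = 0.3),
    pdb_line(9, "C",  "GLY", "A", 2, 5.5, 2.3, 0.6, "C"),
    pdb_line(10, "O", "GLY", "A", 2, 6.0, 1.2, 0.4, "O"),
    pdb_line(11, "N", "SER", "A", 3, 6.2, 3.4, 1.0, "N"),
    pdb_line(12, "CA","SER", "A", 3, 7.6, 3.3, 1.4, "C"),
    pdb_line(13, "C", "SER", "A", 3, 8.3, 4.6, 1.8, "C"),
    pdb_line(14, "O", "SER", "A", 3, 7.7, 5.7, 1.8, "O"),
    pdb_line(15, "OG","SER", "A", 3, 8.4, 2.3, 0.6, "O"),
    pdb_line(16, "N", "VAL", "B", 1, 0.0, 8.0, 0.0, "N"),
    pdb_line(17, "CA","VAL", "B", 1, 1.4, 8.2, 0.2, "C"),
    pdb_line(18, "C", "VAL", "B", 1, 2.2, 9.4, 0.6, "C"),
    pdb_line(19, "N", "THR", "B", 2, 3.5, 9.2, 0.6, "N"),
    pdb_line(20, "CA","THR", "B", 2, 4.5, 10.2, 0.9, "C"),
    pdb_line(21, "O", "HOH", "W", 1, 12.0, 12.0, 12.0, "O", record = "HETATM"),
    "END")
  writeLines(l, path)
  path
}

# a tiny deterministic labelled pool for metric tests
tiny_eval_fixture <- function(seed = 7, n = 50, n_targets = 5) {
  set.seed(seed)
  labels <- runif(n)
  preds <- 0.7 * labels + 0.3 * runif(n)
  targets <- rep(paste0("T", seq_len(n_targets)), length.out = n)
  list(labels = labels, preds = preds, targets = targets)
}
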