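#' The 11-category heavy-atom typing scheme
#'
#' Heavy atoms of the 20 standard amino acids are grouped into 11 chemical
#' categories that refine the element identity (C, N, O, S) by residue
#' context: the alpha-carbon is its own class, other carbons split into
#' sp2 (carbonyl/carboxyl/amide/guanidinium), aromatic and sp3/aliphatic;
#' nitrogens split into amide, aromatic and positively charged; oxygens
#' into carbonyl, hydroxyl and carboxylate; sulfur is a single class.
#' One-hot encodings of these categories are the only atom-level input
#' features of the network.
#'
#' @return A data.frame with columns \code{residue_name}, \code{atom_name}
#'   and \code{type} (integer in 0..10), one row per standard heavy atom.
#' @export
#' @examples
#' tab <- atom_type_table()
#' length(unique(tab$type))  # 11
atom_type_table <- function() {
  .qa_atom_type_table
}

#' Names of the 11 atom-type categories, in index order (0-based indices).
#' @return Character vector of length 11.
#' @export
atom_type_names <- function() {
  c("C_alpha", "C_sp2", "C_aromatic", "C_sp3",
    "N_amide", "N_aromatic", "N_charged",
    "O_carbonyl", "O_hydroxyl", "O_carboxyl", "S")
}

# Heavy-atom inventory of the 20 standard residues (PDB v3 atom names).
.qa_sidechain_atoms <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.qa_build_type_table <- function() {
  # context classes, 0-based indices matching atom_type_names()
  idx <- function(nm) match(nm, atom_type_names()) - 1L

  aromatic <- list(
    HIS = c("CG", "CD2", "CE1"),
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  )
  sp2_side <- list(  # carbons double-bonded to O/N outside rings
    ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD", ARG = "CZ"
  )
  n_amide_side <- list(ASN = "ND2", GLN = "NE2")
  n_aromatic   <- list(HIS = c("ND1", "NE2"), TRP = "NE1")
  n_charged    <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  o_carbonyl_side <- list(ASN = "OD1", GLN = "OE1")
  o_hydroxyl   <- list(SER = "OG", THR = "OG1", TYR = "OH")
  o_carboxyl   <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  sulfur       <- list(CYS = "SG", MET = "SD")

  rows <- list()
  for (res in names(.qa_sidechain_atoms)) {
    atoms <- c("N", "CA", "C", "O", "OXT", .qa_sidechain_atoms[[res]])
    type <- integer(length(atoms))
    for (k in seq_along(atoms)) {
      a <- atoms[k]
      type[k] <- if (a == "N") idx("N_amide")
      else if (a == "CA") idx("C_alpha")
      else if (a == "C") idx("C_sp2")
      else if (a == "O") idx("O_carbonyl")
      else if (a == "OXT") idx("O_carboxyl")
      else if (a %in% aromatic[[res]]) idx("C_aromatic")
      else if (a %in% sp2_side[[res]]) idx("C_sp2")
      else if (a %in% n_amide_side[[res]]) idx("N_amide")
      else if (a %in% n_aromatic[[res]]) idx("N_aromatic")
      else if (a %in% n_charged[[res]]) idx("N_charged")
      else if (a %in% o_carbonyl_side[[res]]) idx("O_carbonyl")
      else if (a %in% o_hydroxyl[[res]]) idx("O_hydroxyl")
      else if (a %in% o_carboxyl[[res]]) idx("O_carboxyl")
      else if (a %in% sulfur[[res]]) idx("S")
      else if (substr(a, 1, 1) == "C") idx("C_sp3")
      else stop("unclassified atom ", res, ":", a)
    }
    rows[[res]] <- data.frame(residue_name = res, atom_name = atoms,
                              type = type, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.qa_atom_type_table <- .qa_build_type_table()

# fast lookup environment keyed "RES|ATOM"
.qa_type_lookup <- local({
  e <- new.env(parent = emptyenv(), size = 512L)
  t <- .qa_atom_type_table
  for (i in seq_len(nrow(t))) {
    assign(paste0(t$residue_name[i], "|", t$atom_name[i]), t$type[i], envir = e)
  }
  e
})

#' Assign each heavy atom of a structure to one of the 11 atom-type classes
#'
#' @param s A \code{qa_structure}.
#' @param table Atom-type table as returned by [atom_type_table()] (the
#'   default); supplied tables must have the same three columns.
#' @return Integer vector of category indices in 0..10, one per atom,
#'   aligned with \code{s$atoms}.  Unknown (residue, atom) pairs are an
#'   error, never silently dropped.
#' @export
assign_atom_types <- function(s, table = atom_type_table()) {
  stopifnot(inherits(s, "qa_structure"))
  if (identical(table, .qa_atom_type_table)) {
    key <- paste0(s$atoms$residue_name, "|", s$atoms$atom_name)
    out <- vapply(key, function(k) {
      v <- get0(k, envir = .qa_type_lookup, inherits = FALSE)
      if (is.null(v)) NA_integer_ else v
    }, integer(1), USE.NAMES = FALSE)
  } else {
    key_tab <- paste0(table$residue_name, "|", table$atom_name)
    key <- paste0(s$atoms$residue_name, "|", s$atoms$atom_name)
    out <- table$type[match(key, key_tab)]
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("no atom type for ", s$atoms$residue_name[bad], ":",
         s$atoms$atom_name[bad], " (atom ", bad, ")")
  }
  as.integer(out)
}
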