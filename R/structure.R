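#' @importFrom stats rnorm runif sd cor
#' @importFrom utils head write.table read.table
NULL

.qa_aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.qa_aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","W","Y","V")

# non-standard residues with a canonical standard parent
.qa_nonstd_map <- c(MSE = "MET", SEC = "CYS", PYL = "LYS")

#' Construct a validated single-chain structure
#'
#' @param atoms data.frame with columns \code{element}, \code{atom_name},
#'   \code{residue_index} (0-based, contiguous), \code{residue_name}
#'   (3-letter code), \code{x}, \code{y}, \code{z} (Angstrom).
#' @param chain_id chain identifier.
#' @return An object of class \code{qa_structure} with fields
#'   \code{chain_id}, \code{atoms}, \code{residues} (data.frame of
#'   \code{index}, \code{name}) and \code{length}.
#' @export
qa_structure <- function(atoms, chain_id = "A") {
  need <- c("element", "atom_name", "residue_index", "residue_name",
            "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  atoms <- atoms[, need]
  atoms$residue_index <- as.integer(atoms$residue_index)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!all(atoms$element %in% c("C", "N", "O", "S"))) {
    stop("unexpected element after heavy-atom filtering: ",
         paste(setdiff(unique(atoms$element), c("C","N","O","S")),
               collapse = ", "))
  }
  ridx <- sort(unique(atoms$residue_index))
  if (!identical(ridx, seq(0L, length(ridx) - 1L))) {
    stop("residue indices must be contiguous 0-based")
  }
  rname <- vapply(ridx, function(i) atoms$residue_name[
    match(i, atoms$residue_index)], character(1))
  residues <- data.frame(index = ridx, name = rname,
                         stringsAsFactors = FALSE)
  structure(
    list(chain_id = chain_id, atoms = atoms, residues = residues,
         length = length(ridx)),
    class = "qa_structure")
}

#' @export
print.qa_structure <- function(x, ...) {
  cat(sprintf("<qa_structure> chain %s: %d residues, %d heavy atoms\n",
              x$chain_id, x$length, nrow(x$atoms)))
  invisible(x)
}

#' Coordinates of a structure as an n_atoms x 3 matrix
#' @param s a \code{qa_structure}
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' One-letter amino-acid sequence of a structure
#' @param s a \code{qa_structure}
#' @return character scalar, length = residue count
#' @export
qa_sequence <- function(s) {
  paste(.qa_aa1[match(s$residues$name, .qa_aa3)], collapse = "")
}

#' Read a single protein chain from a PDB file
#'
#' Parses ATOM records (first MODEL only) through \pkg{bio3d}, keeping
#' heavy protein atoms: hydrogens, waters, HETATM ligands and all but the
#' highest-occupancy alternate location are discarded.  Selenomethionine
#' (MSE) and other residues with a canonical standard parent are renamed
#' to that parent; other non-standard residues are an error.  Residues
#' are re-indexed contiguously from 0 in chain order (insertion codes are
#' resolved by order of appearance); a gap in author numbering only
#' triggers a warning since the graphs downstream need relative adjacency
#' rather than author numbering.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; may be omitted when the file has a
#'   single chain.
#' @return A \code{qa_structure}.
#' @export
parse_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM" | at$resid %in% names(.qa_nonstd_map), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no parseable ATOM records in ", path)

  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L) {
      stop("chain ambiguous: file contains chains ",
           paste(chains, collapse = ", "), "; specify one")
    }
    chain <- chains[1L]
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain)

  # element symbol: prefer the element column, fall back to atom name
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  keep <- elem %in% c("C", "N", "O", "S")
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) stop("no heavy protein atoms for chain ", chain)

  # resolve alternate locations: keep highest occupancy, first on tie
  rkey <- paste(at$resno, at$insert, at$elety, sep = "|")
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(duplicated(rkey))) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(rkey, -occ, seq_len(nrow(at)))
    first <- !duplicated(rkey[ord])
    keep_rows <- sort(ord[first])
    at <- at[keep_rows, , drop = FALSE]
    elem <- elem[keep_rows]
  }

  # non-standard residue mapping
  resid <- at$resid
  mapped <- resid %in% names(.qa_nonstd_map)
  if (any(mapped)) {
    resid[mapped] <- .qa_nonstd_map[resid[mapped]]
    # selenium was filtered with the element screen (SE); remaining atoms fine
  }
  if (!all(resid %in% .qa_aa3)) {
    stop("non-standard residue(s) without a canonical mapping: ",
         paste(unique(setdiff(resid, .qa_aa3)), collapse = ", "))
  }

  # contiguous 0-based residue indexing in file order
  ukey <- paste(at$resno, at$insert, sep = "|")
  ridx <- match(ukey, unique(ukey)) - 1L
  resno <- at$resno[!duplicated(ukey)]
  if (any(diff(resno) != 1L)) {
    warning("author residue numbering is non-contiguous for chain ", chain,
            "; residues re-indexed 0..", max(ridx))
  }
  qa_structure(
    data.frame(element = elem,
               atom_name = trimws(at$elety),
               residue_index = ridx,
               residue_name = resid,
               x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    chain_id = chain)
}

#' Write a structure to a PDB file
#'
#' @param s a \code{qa_structure}
#' @param path output file path
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(s, path) {
  xyz <- as.vector(t(coords(s)))
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   resno = s$atoms$residue_index + 1L,
                   resid = s$atoms$residue_name,
                   elety = s$atoms$atom_name,
                   chain = rep(s$chain_id, nrow(s$atoms)),
                   elesy = s$atoms$element,
                   o = rep(1, nrow(s$atoms)),
                   b = rep(0, nrow(s$atoms)))
  invisible(path)
}

# apply a rigid transform (rotation matrix R, translation t) to a structure
.qa_transform <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
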