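#' Graph construction parameters
#'
#' Both graphs are directed nearest-neighbour graphs: node i aggregates
#' from its own up-to-k nearest neighbours whose distance is strictly
#' below the threshold.  Ties at the cap are broken by (distance, index)
#' ascending so graphs are reproducible bit for bit.
#'
#' @param distance_threshold neighbour distance cutoff in Angstrom
#'   (strict \code{<}); shared by the atom and residue graphs.
#' @param cap_same maximum same-residue atom neighbours per atom.
#' @param cap_other maximum cross-residue atom neighbours per atom.
#' @param cap_residue maximum residue neighbours per residue.
#' @return list of class \code{qa_graph_config}.
#' @export
graph_config <- function(distance_threshold = 6, cap_same = 20,
                         cap_other = 20, cap_residue = 20) {
  stopifnot(distance_threshold > 0, cap_same >= 1, cap_other >= 1,
            cap_residue >= 1)
  structure(list(distance_threshold = distance_threshold,
                 cap_same = cap_same, cap_other = cap_other,
                 cap_residue = cap_residue),
            class = "qa_graph_config")
}

# k nearest entries of a distance row below `thr`, excluding `self`;
# returns column indices ordered by (distance, index)
.qa_knn_row <- function(drow, self, thr, k, candidates = seq_along(drow)) {
  cand <- candidates[candidates != self]
  cand <- cand[drow[cand] < thr]
  if (length(cand) == 0L) return(integer(0))
  ord <- order(drow[cand], cand)
  cand[ord][seq_len(min(k, length(cand)))]
}

#' Build the atom-level graph with the same/cross-residue edge partition
#'
#' For each atom i the graph stores up to \code{cap_same} nearest atoms
#' of the same residue and up to \code{cap_other} nearest atoms of other
#' residues, all strictly within the distance threshold.  Edges are
#' directed into i (each node aggregates from its own neighbour lists);
#' reciprocity is not enforced.
#'
#' @param s a \code{qa_structure}.
#' @param cfg a [graph_config()].
#' @return list of class \code{qa_atom_graph} with \code{n_atoms},
#'   \code{same_residue_edges} and \code{cross_residue_edges} (2-column
#'   matrices \code{(target, neighbour)}, 1-based), and the per-atom
#'   neighbour counts \code{n_same}, \code{n_other}.
#' @export
build_atom_graph <- function(s, cfg = graph_config()) {
  xyz <- coords(s)
  n <- nrow(xyz)
  ri <- s$atoms$residue_index
  D <- as.matrix(stats::dist(xyz))
  same_list <- vector("list", n)
  other_list <- vector("list", n)
  for (i in seq_len(n)) {
    samer <- which(ri == ri[i])
    same_list[[i]] <- .qa_knn_row(D[i, ], i, cfg$distance_threshold,
                                  cfg$cap_same, samer)
    otherr <- which(ri != ri[i])
    other_list[[i]] <- .qa_knn_row(D[i, ], i, cfg$distance_threshold,
                                   cfg$cap_other, otherr)
  }
  mk_edges <- function(lst) {
    cnt <- lengths(lst)
    nb <- as.integer(unlist(lst, use.names = FALSE))
    if (length(nb) == 0L) {
      return(matrix(integer(0), 0, 2,
                    dimnames = list(NULL, c("target", "neighbor"))))
    }
    cbind(target = rep(seq_len(n), cnt), neighbor = nb)
  }
  structure(list(n_atoms = n,
                 same_residue_edges = mk_edges(same_list),
                 cross_residue_edges = mk_edges(other_list),
                 n_same = lengths(same_list),
                 n_other = lengths(other_list)),
            class = "qa_atom_graph")
}

#' Minimum heavy-atom distance between two residues
#' @param s a \code{qa_structure}
#' @param i,j distinct 0-based residue indices
#' @return distance in Angstrom
#' @export
min_residue_distance <- function(s, i, j) {
  if (i == j) stop("i and j must differ")
  xyz <- coords(s)
  a <- xyz[s$atoms$residue_index == i, , drop = FALSE]
  b <- xyz[s$atoms$residue_index == j, , drop = FALSE]
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(sq)))
}

# n_res x n_res matrix of minimum inter-residue heavy-atom distances
.qa_residue_dist <- function(s) {
  xyz <- coords(s)
  ri <- s$atoms$residue_index
  n_res <- s$length
  D <- as.matrix(stats::dist(xyz))
  groups <- split(seq_len(nrow(xyz)), ri)
  # stage 1: residue -> atom minima
  M1 <- matrix(NA_real_, n_res, nrow(xyz))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    M1[g, ] <- if (length(rows) == 1L) D[rows, ] else
      do.call(pmin, lapply(rows, function(r) D[r, ]))
  }
  # stage 2: residue -> residue minima
  R <- matrix(NA_real_, n_res, n_res)
  for (g in seq_along(groups)) {
    cols <- groups[[g]]
    R[, g] <- if (length(cols) == 1L) M1[, cols] else
      do.call(pmin, lapply(cols, function(cc) M1[, cc]))
  }
  diag(R) <- 0
  R
}

#' Build the residue-level nearest-neighbour graph
#'
#' Residue-residue distance is the minimum over their heavy-atom pairs;
#' each residue keeps its up-to-\code{cap_residue} nearest residues
#' strictly within the distance threshold, ties broken by
#' (distance, index).
#'
#' @param s a \code{qa_structure}.
#' @param cfg a [graph_config()].
#' @return list of class \code{qa_residue_graph} with \code{n_residues},
#'   \code{edges} (2-column matrix \code{(target, neighbour)}, 1-based)
#'   and per-residue neighbour counts \code{n_nbr}.
#' @export
build_residue_graph <- function(s, cfg = graph_config()) {
  R <- .qa_residue_dist(s)
  n <- s$length
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    nbr[[i]] <- .qa_knn_row(R[i, ], i, cfg$distance_threshold, cfg$cap_residue)
  }
  cnt <- lengths(nbr)
  nb <- as.integer(unlist(nbr, use.names = FALSE))
  edges <- if (length(nb) == 0L) {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("target", "neighbor")))
  } else {
    cbind(target = rep(seq_len(n), cnt), neighbor = nb)
  }
  structure(list(n_residues = n, edges = edges, n_nbr = cnt),
            class = "qa_residue_graph")
}

# mean-aggregation sparse operator from an edge matrix: row i of (S %*% H)
# is the mean of H over i's neighbours (zero row when i has none)
.qa_agg_matrix <- function(edges, counts, n) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  w <- 1 / counts[edges[, 1]]
  Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = w, dims = c(n, n))
}
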