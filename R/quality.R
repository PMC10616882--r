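#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' @param moving n x 3 matrix of coordinates to transform.
#' @param fixed n x 3 matrix of reference coordinates (same row order).
#' @return list with \code{rotation} (3x3 proper rotation, det = +1),
#'   \code{translation} (length-3), and \code{rmsd} in Angstrom; the
#'   transform maps \code{moving} onto \code{fixed} as
#'   \code{moving \%*\% t(rotation) + translation}.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  stopifnot(ncol(moving) == 3, ncol(fixed) == 3)
  if (nrow(moving) != nrow(fixed)) stop("point counts differ")
  if (nrow(moving) < 3) stop("need at least 3 points")
  if (!all(is.finite(moving)) || !all(is.finite(fixed))) {
    stop("non-finite coordinates")
  }
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)                      # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    warning("degenerate (collinear) point set; superposition not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)               # fixed ~ R %*% moving
  tr <- cf - as.vector(R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

# lean Kabsch for inner loops: no validation, rotation + translation only
.qa_kabsch <- function(P, Q) {
  cm <- colMeans(P); cf <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cm), sweep(Q, 2, cf))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cf - as.vector(R %*% cm))
}

# alpha-carbon coordinate matrices shared between decoy and native,
# matched on residue_index
.qa_shared_ca <- function(decoy, native) {
  ca_d <- decoy$atoms[decoy$atoms$atom_name == "CA", ]
  ca_n <- native$atoms[native$atoms$atom_name == "CA", ]
  shared <- intersect(ca_d$residue_index, ca_n$residue_index)
  if (length(shared) == 0L) stop("no shared residues with alpha-carbons")
  shared <- sort(shared)
  id <- match(shared, ca_d$residue_index)
  im <- match(shared, ca_n$residue_index)
  list(decoy = as.matrix(ca_d[id, c("x", "y", "z")]),
       native = as.matrix(ca_n[im, c("x", "y", "z")]),
       residue_index = shared)
}

#' Global distance test total score (GDT-TS)
#'
#' Mean over the distance thresholds 1, 2, 4 and 8 Angstrom of the
#' maximal fraction of alpha-carbons that can be placed within the
#' threshold of their native counterparts under a rigid superposition.
#' The (NP-hard) maximisation is approximated with the standard
#' seed-and-extend search: every contiguous window of length 3, 5, 7 and
#' the full chain seeds a superposition, which is then iteratively
#' refitted on the set of atoms currently under the threshold until that
#' set stabilises.  Exact for the identity and for rigid motions.
#'
#' @param decoy,native \code{qa_structure}s sharing residue indexing.
#' @return GDT-TS on the [0,1] scale.
#' @export
compute_gdtts <- function(decoy, native) {
  m <- .qa_shared_ca(decoy, native)
  n_total <- length(m$residue_index)
  ca_nat <- native$atoms[native$atoms$atom_name == "CA", ]
  if (n_total < 0.5 * nrow(ca_nat)) {
    stop("alpha-carbons missing for more than 50% of residues")
  }
  if (n_total < 3) stop("need at least 3 shared alpha-carbons")
  P <- m$decoy; Q <- m$native
  thresholds <- c(1, 2, 4, 8)
  win_lens <- unique(pmin(c(3L, 5L, 7L, n_total), n_total))

  # seed index sets: all contiguous windows of each length
  seeds <- list()
  for (w in win_lens) {
    for (start in seq_len(n_total - w + 1L)) {
      seeds[[length(seeds) + 1L]] <- start:(start + w - 1L)
    }
  }

  best <- numeric(length(thresholds))
  for (seed in seeds) {
    fit <- .qa_kabsch(P[seed, , drop = FALSE], Q[seed, , drop = FALSE])
    for (ti in seq_along(thresholds)) {
      t <- thresholds[ti]
      cur <- seed
      R <- fit$R; tr <- fit$t
      for (iter in 1:20) {
        moved <- P %*% t(R)
        moved[, 1] <- moved[, 1] + tr[1]
        moved[, 2] <- moved[, 2] + tr[2]
        moved[, 3] <- moved[, 3] + tr[3]
        d2 <- rowSums((moved - Q)^2)
        under <- which(d2 <= t * t)
        frac <- length(under) / n_total
        if (frac > best[ti]) best[ti] <- frac
        if (length(under) < 3L || identical(under, cur)) break
        cur <- under
        f2 <- .qa_kabsch(P[cur, , drop = FALSE], Q[cur, , drop = FALSE])
        R <- f2$R; tr <- f2$t
      }
    }
  }
  mean(best)
}

#' Local distance difference test (lDDT)
#'
#' Superposition-free local quality score.  The native structure defines
#' the reference pair set: every pair of heavy atoms in different
#' residues whose native distance is below \code{inclusion_radius}.  A
#' pair is preserved at tolerance t when the decoy reproduces its native
#' distance to within t; pairs with an atom missing from the decoy count
#' as not preserved.  The per-residue score is the mean over the four
#' tolerances of the fraction of that residue's pairs preserved; the
#' global score is the mean of the per-residue scores over residues that
#' have at least one qualifying pair (others are NA).
#'
#' @param decoy,native \code{qa_structure}s; atoms are matched by
#'   (residue_index, atom_name).
#' @param inclusion_radius native-distance cutoff defining the pair set
#'   (Angstrom).
#' @param thresholds preservation tolerances (Angstrom).
#' @return list with \code{lddt_global} and \code{lddt_per_residue}
#'   (length = native residue count; NA where a residue has no pairs).
#' @export
compute_lddt <- function(decoy, native, inclusion_radius = 15,
                         thresholds = c(0.5, 1, 2, 4)) {
  nat_xyz <- coords(native)
  n_res <- native$length
  key_n <- paste(native$atoms$residue_index, native$atoms$atom_name, sep = "|")
  key_d <- paste(decoy$atoms$residue_index, decoy$atoms$atom_name, sep = "|")
  dmatch <- match(key_n, key_d)                  # decoy row per native atom
  dec_xyz <- coords(decoy)

  Dn <- as.matrix(stats::dist(nat_xyz))
  ri <- native$atoms$residue_index
  qual <- Dn < inclusion_radius &
    outer(ri, ri, "!=") &
    upper.tri(Dn)
  idx <- which(qual, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no qualifying atom pairs within the inclusion radius")

  a <- idx[, 1]; b <- idx[, 2]
  dn <- Dn[idx]
  have <- !is.na(dmatch[a]) & !is.na(dmatch[b])
  dd <- rep(NA_real_, length(dn))
  if (any(have)) {
    pa <- dec_xyz[dmatch[a[have]], , drop = FALSE]
    pb <- dec_xyz[dmatch[b[have]], , drop = FALSE]
    dd[have] <- sqrt(rowSums((pa - pb)^2))
  }
  diffs <- abs(dn - dd)
  # fraction of the 4 tolerances satisfied per pair; missing atoms => 0
  frac <- rowMeans(outer(diffs, thresholds, "<"))
  frac[!have] <- 0

  ra <- ri[a]; rb <- ri[b]
  per_res <- rep(NA_real_, n_res)
  num <- den <- numeric(n_res)
  for (v in list(cbind(ra, frac), cbind(rb, frac))) {
    tt <- rowsum(v[, 2], v[, 1])
    cc <- rowsum(rep(1, nrow(v)), v[, 1])
    j <- as.integer(rownames(tt)) + 1L
    num[j] <- num[j] + tt[, 1]
    den[j] <- den[j] + cc[, 1]
  }
  has <- den > 0
  per_res[has] <- num[has] / den[has]
  list(lddt_global = mean(per_res[has]), lddt_per_residue = per_res)
}

#' Quality label of a decoy against its native structure
#'
#' @param decoy,native \code{qa_structure}s sharing residue indexing.
#' @return list with \code{gdtts}, \code{lddt_global} and
#'   \code{lddt_per_residue}, all on the [0,1] scale.
#' @export
quality_label <- function(decoy, native) {
  l <- compute_lddt(decoy, native)
  list(gdtts = compute_gdtts(decoy, native),
       lddt_global = l$lddt_global,
       lddt_per_residue = l$lddt_per_residue)
}
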