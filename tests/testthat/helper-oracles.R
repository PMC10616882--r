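# independent brute-force / loop oracles shared across test files

# dense quaternion-grid search for the optimal-rotation RMSD, with a
# local refinement stage around the best grid point
grid_rmsd <- function(P, Q, n = 10) {
  quat_rmsd <- function(q, Pc, Qc) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
                  2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
                  2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)),
                3, 3, byrow = TRUE)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  qs <- as.matrix(expand.grid(w = seq(-1, 1, length.out = n),
                              x = seq(-1, 1, length.out = n),
                              y = seq(-1, 1, length.out = n),
                              z = seq(-1, 1, length.out = n)))
  qs <- qs[rowSums(qs^2) > 1e-6, ]
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  vals <- apply(qs, 1, quat_rmsd, Pc = Pc, Qc = Qc)
  best_q <- qs[which.min(vals), ]
  best <- min(vals)
  set.seed(17)
  step <- 2 / (n - 1)
  for (k in 1:4000) {
    cand <- best_q + rnorm(4, sd = step / 2)
    r <- quat_rmsd(cand, Pc, Qc)
    if (r < best) { best <- r; best_q <- cand; step <- step * 0.9 }
  }
  best
}

# exhaustive pair-enumeration lDDT, independent of the package's
# vectorised implementation
brute_lddt <- function(decoy, native, radius = 15, thr = c(0.5, 1, 2, 4)) {
  an <- native$atoms; ad <- decoy$atoms
  n_res <- native$length
  num <- den <- matrix(0, n_res, length(thr))
  for (i in seq_len(nrow(an))) {
    for (j in seq_len(nrow(an))) {
      if (j <= i) next
      if (an$residue_index[i] == an$residue_index[j]) next
      dn <- sqrt(sum((c(an$x[i], an$y[i], an$z[i]) -
                        c(an$x[j], an$y[j], an$z[j]))^2))
      if (dn >= radius) next
      di <- which(ad$residue_index == an$residue_index[i] &
                    ad$atom_name == an$atom_name[i])
      dj <- which(ad$residue_index == an$residue_index[j] &
                    ad$atom_name == an$atom_name[j])
      for (t in seq_along(thr)) {
        ok <- 0
        if (length(di) == 1 && length(dj) == 1) {
          dd <- sqrt(sum((c(ad$x[di], ad$y[di], ad$z[di]) -
                            c(ad$x[dj], ad$y[dj], ad$z[dj]))^2))
          ok <- as.numeric(abs(dn - dd) < thr[t])
        }
        for (r in c(an$residue_index[i], an$residue_index[j]) + 1L) {
          num[r, t] <- num[r, t] + ok
          den[r, t] <- den[r, t] + 1
        }
      }
    }
  }
  per <- rep(NA_real_, n_res)
  has <- den[, 1] > 0
  per[has] <- rowMeans(num / den)[has]
  list(lddt_global = mean(per[has]), lddt_per_residue = per)
}

# straightforward independent re-implementation of the seed-and-extend
# GDT-TS search (same procedure, written against the documented steps)
brute_gdtts <- function(decoy, native) {
  ca_d <- decoy$atoms[decoy$atoms$atom_name == "CA", ]
  ca_n <- native$atoms[native$atoms$atom_name == "CA", ]
  shared <- sort(intersect(ca_d$residue_index, ca_n$residue_index))
  P <- as.matrix(ca_d[match(shared, ca_d$residue_index), c("x", "y", "z")])
  Q <- as.matrix(ca_n[match(shared, ca_n$residue_index), c("x", "y", "z")])
  n <- nrow(P)
  fit <- function(idx) {
    k <- kabsch_superpose(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    sweep(P %*% t(k$rotation), 2, k$translation, "+")
  }
  best <- c(0, 0, 0, 0)
  thr <- c(1, 2, 4, 8)
  for (w in unique(pmin(c(3, 5, 7, n), n))) {
    for (st in 1:(n - w + 1)) {
      seed <- st:(st + w - 1)
      for (t in seq_along(thr)) {
        cur <- seed
        repeat {
          moved <- suppressWarnings(fit(cur))
          under <- which(sqrt(rowSums((moved - Q)^2)) <= thr[t])
          best[t] <- max(best[t], length(under) / n)
          if (length(under) < 3 || identical(under, cur)) break
          cur <- under
        }
      }
    }
  }
  mean(best)
}

# O(n^2) brute-force graph construction used as the oracle
brute_atom_graph <- function(s, cfg) {
  xyz <- coords(s); n <- nrow(xyz); ri <- s$atoms$residue_index
  same <- other <- list()
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    pick <- function(mask, cap) {
      cand <- setdiff(which(mask & d < cfg$distance_threshold), i)
      cand <- cand[order(d[cand], cand)]
      head(cand, cap)
    }
    same[[i]] <- pick(ri == ri[i], cfg$cap_same)
    other[[i]] <- pick(ri != ri[i], cfg$cap_other)
  }
  list(same = same, other = other)
}

edges_to_list <- function(edges, n) {
  out <- rep(list(integer(0)), n)
  sp <- split(edges[, 2], edges[, 1])
  out[as.integer(names(sp))] <- lapply(sp, as.integer)
  out
}

# per-node loop oracle for the two convolution layers
loop_atom_conv <- function(v, g, p) {
  n <- nrow(v)
  out <- matrix(0, n, ncol(p$W_c))
  for (i in seq_len(n)) {
    acc <- as.vector(v[i, ] %*% p$W_c) + p$b
    ns <- g$same_residue_edges[g$same_residue_edges[, 1] == i, 2]
    if (length(ns) > 0) {
      acc <- acc + as.vector(colMeans(v[ns, , drop = FALSE]) %*% p$W_s)
    }
    no <- g$cross_residue_edges[g$cross_residue_edges[, 1] == i, 2]
    if (length(no) > 0) {
      acc <- acc + as.vector(colMeans(v[no, , drop = FALSE]) %*% p$W_o)
    }
    out[i, ] <- pmax(acc, 0)
  }
  out
}

loop_res_conv <- function(r, g, p) {
  n <- nrow(r)
  out <- matrix(0, n, ncol(p$W_cr))
  for (i in seq_len(n)) {
    acc <- as.vector(r[i, ] %*% p$W_cr) + p$b
    nb <- g$edges[g$edges[, 1] == i, 2]
    if (length(nb) > 0) {
      acc <- acc + as.vector(colMeans(r[nb, , drop = FALSE]) %*% p$W_r)
    }
    out[i, ] <- pmax(acc, 0)
  }
  out
}
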