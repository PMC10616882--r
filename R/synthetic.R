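# run fun() under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
.qa_with_seed <- function(seed, fun) {
  had <- exists(".Random.seed", globalenv())
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv()) else
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

# NeRF atom placement: position D bonded to C, with |CD| = r, angle
# B-C-D = theta and dihedral A-B-C-D = chi (degrees)
.qa_place_atom <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(chi),
          r * sin(theta) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# virtual C-beta from the backbone N, CA, C positions
.qa_place_cb <- function(N, CA, C) {
  b <- CA - N; c <- C - CA
  a <- c(b[2] * c[3] - b[3] * c[2],
         b[3] * c[1] - b[1] * c[3],
         b[1] * c[2] - b[2] * c[1])
  CA - 0.58273431 * a + 0.56802827 * b - 0.54067466 * c
}

# heavy-atom pairs in different residues closer than `cutoff`, excluding
# the peptide-bond pair C(i)-N(i+1) which is covalent by construction
.qa_count_clashes <- function(s, cutoff = 2.0) {
  xyz <- coords(s)
  ri <- s$atoms$residue_index
  D <- as.matrix(stats::dist(xyz))
  bad <- D < cutoff & outer(ri, ri, "!=") & upper.tri(D)
  if (!any(bad)) return(0L)
  idx <- which(bad, arr.ind = TRUE)
  pept <- (s$atoms$atom_name[idx[, 1]] == "C" &
             s$atoms$atom_name[idx[, 2]] == "N" &
             ri[idx[, 2]] - ri[idx[, 1]] == 1L) |
    (s$atoms$atom_name[idx[, 2]] == "C" &
       s$atoms$atom_name[idx[, 1]] == "N" &
       ri[idx[, 1]] - ri[idx[, 2]] == 1L)
  sum(!pept)
}

# build backbone coordinates from per-residue (phi, psi) with ideal
# bond geometry; returns list of per-residue N/CA/C/O positions
.qa_build_backbone <- function(phi, psi) {
  n <- length(phi)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  N <- CA <- C <- O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCA, 0, 0)
  C[1, ] <- .qa_place_atom(c(0, 0, 1), N[1, ], CA[1, ], b_CAC, a_NCAC, phi[1])
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- .qa_place_atom(N[i, ], CA[i, ], C[i, ], b_CN, a_CACN, psi[i])
    CA[i + 1L, ] <- .qa_place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                   b_NCA, a_CNCA, 180)
    C[i + 1L, ] <- .qa_place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                                  b_CAC, a_NCAC, phi[i + 1L])
  }
  for (i in seq_len(n)) {
    O[i, ] <- .qa_place_atom(N[i, ], CA[i, ], C[i, ], b_CO, a_CACO,
                             psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Generate an idealised synthetic native structure
#'
#' Builds a self-clash-free single-chain backbone (N, CA, C, O plus a
#' virtual CB for non-glycine residues) from ideal bond geometry, as
#' alternating helical segments and extended linkers with small
#' dihedral jitter, under a random standard-amino-acid sequence.  These
#' are idealised geometries, not physically realistic folds: the
#' network consumes only geometry and sequence, so they exercise every
#' code path.
#'
#' @param length residue count (>= 5).
#' @param seed RNG seed; the same seed reproduces identical coordinates.
#' @return a \code{qa_structure}.
#' @export
make_native <- function(length, seed = 1L) {
  stopifnot(length >= 5)
  .qa_with_seed(seed, function() {
    for (attempt in 1:25) {
      # alternating segment types: helix / extended (PPII-like) linker
      phi <- psi <- numeric(0)
      helix <- runif(1) < 0.7
      while (base::length(phi) < length) {
        seg <- if (helix) sample(6:14, 1) else sample(3:6, 1)
        if (helix) {
          phi <- c(phi, rnorm(seg, -57, 4)); psi <- c(psi, rnorm(seg, -47, 4))
        } else {
          phi <- c(phi, rnorm(seg, -75, 8)); psi <- c(psi, rnorm(seg, 145, 8))
        }
        helix <- !helix
      }
      phi <- phi[seq_len(length)]; psi <- psi[seq_len(length)]
      bb <- .qa_build_backbone(phi, psi)
      seq3 <- sample(.qa_aa3, length, replace = TRUE)
      rows <- vector("list", length)
      for (i in seq_len(length)) {
        nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
        xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
        if (seq3[i] != "GLY") {
          nm <- c(nm, "CB"); el <- c(el, "C")
          xyz <- rbind(xyz, .qa_place_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ]))
        }
        rows[[i]] <- data.frame(element = el, atom_name = nm,
                                residue_index = i - 1L,
                                residue_name = seq3[i],
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                stringsAsFactors = FALSE)
      }
      s <- qa_structure(do.call(rbind, rows))
      if (.qa_count_clashes(s) == 0L) return(s)
    }
    stop("could not generate a clash-free structure; try another seed")
  })
}

#' Perturb a native structure into a decoy
#'
#' \code{global_noise} adds i.i.d. Gaussian noise of standard deviation
#' \code{sigma} to every coordinate.  \code{segment_shift} rigidly
#' displaces a contiguous residue segment by \code{sigma} Angstrom in a
#' random direction (emulating domain misplacement, which decouples
#' superposition-based and superposition-free scores).  \code{mixed}
#' composes global noise \code{sigma} with a segment shift of
#' \code{3 * sigma}.
#'
#' @param native a \code{qa_structure}.
#' @param sigma perturbation scale in Angstrom (see above).
#' @param mode \code{"global_noise"}, \code{"segment_shift"} or
#'   \code{"mixed"}.
#' @param seed RNG seed.
#' @param segment optional integer range of 0-based residue indices for
#'   the shifted segment (random when NULL).
#' @return a decoy \code{qa_structure} with identical sequence/topology.
#' @export
perturb_decoy <- function(native, sigma,
                          mode = c("global_noise", "segment_shift", "mixed"),
                          seed = 1L, segment = NULL) {
  mode <- match.arg(mode)
  stopifnot(sigma >= 0)
  .qa_with_seed(seed, function() {
    s <- native
    xyz <- coords(s)
    shift_seg <- function(xyz, dist_A) {
      n_res <- s$length
      if (is.null(segment)) {
        w <- max(3L, round(n_res / 4))
        st <- sample.int(n_res - w + 1L, 1) - 1L
        seg <- st:(st + w - 1L)
      } else seg <- segment
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rows <- s$atoms$residue_index %in% seg
      xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2, dir * dist_A, "+")
      xyz
    }
    if (mode %in% c("global_noise", "mixed") && sigma > 0) {
      xyz <- xyz + matrix(rnorm(base::length(xyz), 0, sigma), nrow(xyz), 3)
    }
    if (mode == "segment_shift" && sigma > 0) xyz <- shift_seg(xyz, sigma)
    if (mode == "mixed" && sigma > 0) xyz <- shift_seg(xyz, 3 * sigma)
    s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
    s
  })
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the statistical structure of CASP-style training
#' pools at desk scale: decoys span the full quality range, with an
#' imbalanced, sparse high-quality tail (\code{high_quality_fraction}
#' of decoys drawn from the mildest noise grades).
#'
#' @param n_targets number of targets (native structures).
#' @param chain_length_range min/max residues per target.
#' @param decoys_per_target decoys generated per target.
#' @param noise_grades coordinate-noise standard deviations (Angstrom)
#'   decoys are drawn from.
#' @param high_quality_fraction fraction of decoys drawn from the
#'   low-noise (high-quality) grades.
#' @param seed master RNG seed.
#' @return list of class \code{qa_synthetic_config}.
#' @export
synthetic_config <- function(n_targets = 30L, chain_length_range = c(30L, 60L),
                             decoys_per_target = 25L,
                             noise_grades = c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                             high_quality_fraction = 0.1, seed = 1L) {
  stopifnot(chain_length_range[1] >= 5, all(noise_grades >= 0),
            high_quality_fraction > 0, high_quality_fraction < 1)
  structure(list(n_targets = as.integer(n_targets),
                 chain_length_range = as.integer(chain_length_range),
                 decoys_per_target = as.integer(decoys_per_target),
                 noise_grades = noise_grades,
                 high_quality_fraction = high_quality_fraction,
                 seed = as.integer(seed)),
            class = "qa_synthetic_config")
}

#' Generate a labelled synthetic decoy dataset
#'
#' For each target a synthetic native is built and perturbed into
#' decoys across the configured noise grades; grades at or below 0.5
#' Angstrom count as the high-quality pool and receive only
#' \code{high_quality_fraction} of the draws, reproducing the
#' label imbalance of real training pools.  Labels (GDT-TS, global and
#' per-residue lDDT) are always recomputed from the structures with the
#' scoring functions, never trusted from the generator.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir optional directory; when given, natives and decoys
#'   are written as PDB files together with a TSV manifest and a
#'   per-residue lDDT TSV.
#' @return list of class \code{qa_dataset}: \code{natives} (list by
#'   target), \code{decoys} (list by "target/decoy" id),
#'   \code{manifest} (data.frame with target, decoy, sigma, mode,
#'   gdtts, lddt_global) and \code{lddt_local} (list of per-residue
#'   vectors, same order as manifest rows).
#' @export
generate_dataset <- function(cfg = synthetic_config(), out_dir = NULL) {
  hq <- cfg$noise_grades <= 0.5
  if (!any(hq)) hq[which.min(cfg$noise_grades)] <- TRUE
  if (all(hq)) hq[which.max(cfg$noise_grades)] <- FALSE
  natives <- list()
  decoys <- list()
  lddt_local <- list()
  rows <- list()
  base_seed <- cfg$seed
  for (t in seq_len(cfg$n_targets)) {
    tid <- sprintf("T%03d", t)
    len <- .qa_with_seed(base_seed * 1000L + t, function()
      sample(cfg$chain_length_range[1]:cfg$chain_length_range[2], 1))
    nat <- make_native(len, seed = base_seed * 1000L + t)
    natives[[tid]] <- nat
    draws <- .qa_with_seed(base_seed * 2000L + t, function() {
      n <- cfg$decoys_per_target
      use_hq <- runif(n) < cfg$high_quality_fraction
      sig <- numeric(n)
      sig[use_hq] <- sample(cfg$noise_grades[hq], sum(use_hq), replace = TRUE)
      sig[!use_hq] <- sample(cfg$noise_grades[!hq], sum(!use_hq),
                             replace = TRUE)
      mode <- sample(c("global_noise", "mixed"), n, replace = TRUE,
                     prob = c(0.7, 0.3))
      list(sig = sig, mode = mode)
    })
    for (d in seq_len(cfg$decoys_per_target)) {
      did <- sprintf("%s/D%03d", tid, d)
      dec <- perturb_decoy(nat, draws$sig[d], draws$mode[d],
                           seed = base_seed * 4000L + t * 100L + d)
      lab <- quality_label(dec, nat)
      decoys[[did]] <- dec
      lddt_local[[did]] <- lab$lddt_per_residue
      rows[[did]] <- data.frame(target = tid, decoy = did,
                                sigma = draws$sig[d], mode = draws$mode[d],
                                gdtts = lab$gdtts,
                                lddt_global = lab$lddt_global,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  out <- structure(list(natives = natives, decoys = decoys,
                        manifest = manifest, lddt_local = lddt_local,
                        config = cfg),
                   class = "qa_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tid in names(natives)) {
      write_pdb(natives[[tid]], file.path(out_dir, paste0(tid, "_native.pdb")))
    }
    for (did in names(decoys)) {
      write_pdb(decoys[[did]],
                file.path(out_dir, paste0(gsub("/", "_", did), ".pdb")))
    }
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    ll <- data.frame(decoy = rep(manifest$decoy, lengths(lddt_local)),
                     residue_index = unlist(lapply(lddt_local, function(v)
                       seq_along(v) - 1L)),
                     lddt = unlist(lddt_local))
    write.table(ll, file.path(out_dir, "lddt_local.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  out
}

#' Split a dataset by target and prepare network inputs
#'
#' Targets (never individual decoys) are partitioned into training and
#' validation groups, and each decoy is converted to the precomputed
#' network input bundle.
#'
#' @param ds a \code{qa_dataset} from [generate_dataset()].
#' @param score which label to train on: \code{"gdtts"} or
#'   \code{"lddt_global"}.
#' @param val_fraction fraction of targets held out for validation.
#' @param provider residue [embedding_provider()].
#' @param gcfg a [graph_config()].
#' @param seed seed for the target split.
#' @return list with \code{train} and \code{val}, each a list of
#'   \code{inputs}, \code{labels}, \code{targets}, \code{decoy_ids}.
#' @export
prepare_training_data <- function(ds, score = c("gdtts", "lddt_global"),
                                  val_fraction = 0.2,
                                  provider = embedding_provider("onehot"),
                                  gcfg = graph_config(), seed = 1L) {
  score <- match.arg(score)
  targets <- unique(ds$manifest$target)
  n_val <- max(1L, round(length(targets) * val_fraction))
  val_t <- .qa_with_seed(seed, function() sample(targets, n_val))
  inputs <- lapply(ds$manifest$decoy, function(did)
    prepare_decoy(ds$decoys[[did]], provider, gcfg))
  mk <- function(sel) {
    list(inputs = inputs[sel], labels = ds$manifest[[score]][sel],
         targets = ds$manifest$target[sel],
         decoy_ids = ds$manifest$decoy[sel])
  }
  is_val <- ds$manifest$target %in% val_t
  list(train = mk(which(!is_val)), val = mk(which(is_val)))
}
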