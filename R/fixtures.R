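#' Synthetic fixture generators
#'
#' Configurations and trajectories with planted, known structure so that
#' every analysis can be validated without running molecular dynamics.  The
#' fixtures emulate geometric and statistical structure only, never
#' force-field physics; all of them are deterministic under their seed, which
#' is recorded in the returned object.
#'
#' @name fixtures
NULL

# minimal annotated protein-like chain for fixtures
fixture_chain <- function(n_ntd = 6, n_dbd = 4, n_ctd = 10, n_wr = 4,
                          kind = "protein") {
  n <- n_ntd + n_dbd + n_ctd
  dom <- c(rep("NTD", n_ntd), rep("DBD", n_dbd), rep("CTD", n_ctd))
  wr <- rep(FALSE, n)
  if (n_wr > 0) wr[(n - n_wr + 1):n] <- TRUE
  structure(list(kind = kind, variant = "fixture", sequence = strrep("G", n),
                 beads = data.frame(resid = seq_len(n), code = "G", mass = 100,
                                    charge = 0, sigma = 5, lam = 0.5,
                                    domain = dom, wr = wr,
                                    disordered = dom != "DBD",
                                    stringsAsFactors = FALSE),
                 bonds = data.frame(i = integer(0), j = integer(0),
                                    k = numeric(0), b0 = numeric(0)),
                 epairs = data.frame(i = integer(0), j = integer(0),
                                     k = numeric(0), r0 = numeric(0)),
                 domains = NULL, wr_spans = NULL, ref_coords = NULL),
            class = "cg_chain")
}

fixture_system <- function(n_mol, box, chain = fixture_chain()) {
  build_system(list(list(topology = chain, count = n_mol)), box = box)
}

#' Two-phase slab configuration with known extent
#'
#' `n_condensed` molecules form a connected slab of width `slab_width`
#' centred in z (consecutive molecules stay within interaction range, so the
#' slab is a single 50 A cluster by construction), and `n_dilute` molecules
#' sit isolated outside it, at least `margin` from the slab and from each
#' other.  Beads are spread uniformly over a small cube per molecule.
#'
#' @param n_condensed,n_dilute Molecule counts.
#' @param slab_width Planted slab breadth (A).
#' @param box Box side lengths.
#' @param seed RNG seed.
#' @param beads_per_mol Beads per fixture molecule.
#' @param margin Clearance of dilute molecules from the slab and each other.
#' @return A one-frame `cg_trajectory` with attribute `truth` (list with
#'   `slab_width`, `n_condensed`, `n_dilute`, `density`).
#' @export
make_two_phase <- function(n_condensed, n_dilute, slab_width = 400,
                           box = c(300, 300, 3000), seed = 1,
                           beads_per_mol = 10, margin = 120) {
  set.seed(seed)
  if (slab_width >= box[3]) stop("packing error: slab exceeds the box")
  n <- n_condensed + n_dilute
  sys <- fixture_system(n, box,
                        fixture_chain(n_ntd = 0, n_dbd = 0,
                                      n_ctd = beads_per_mol, n_wr = 0))
  zc <- box[3] / 2
  cents <- matrix(0, n, 3)
  if (n_condensed > 0) {
    # connected ladder spanning the slab: consecutive centroids < 50 A apart
    # (each molecule's first bead sits exactly at its centroid, so consecutive
    # molecules are guaranteed within the 50 A interaction cutoff)
    z <- seq(zc - slab_width / 2 + 5, zc + slab_width / 2 - 5,
             length.out = n_condensed)
    if (n_condensed > 1 && any(diff(z) > 49)) {
      stop("packing error: too few molecules to span the requested slab")
    }
    xy <- matrix(box[1] / 2, n_condensed, 2)
    for (i in seq_len(n_condensed)[-1]) {
      step <- stats::runif(2, -1, 1)
      step <- 5 * step / max(1, sqrt(sum(step^2)))
      xy[i, ] <- pmin(pmax(xy[i - 1, ] + step, 40), box[1] - 40)
    }
    cents[seq_len(n_condensed), ] <- cbind(xy, z)
  }
  if (n_dilute > 0) {
    placed <- 0
    while (placed < n_dilute) {
      cand <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
                stats::runif(1, 0, box[3]))
      dz <- abs(min_image(cand[3] - zc, box[3]))
      if (dz < slab_width / 2 + margin) next
      prev <- cents[seq_len(n_condensed + placed), , drop = FALSE]
      if (n_condensed + placed > 0) {
        dd <- sqrt(min_image(prev[, 1] - cand[1], box[1])^2 +
                   min_image(prev[, 2] - cand[2], box[2])^2 +
                   min_image(prev[, 3] - cand[3], box[3])^2)
        if (any(dd < margin)) next
      }
      placed <- placed + 1
      cents[n_condensed + placed, ] <- cand
    }
  }
  coords <- matrix(0, n * beads_per_mol, 3)
  for (m in seq_len(n)) {
    idx <- (m - 1) * beads_per_mol + seq_len(beads_per_mol)
    blob <- matrix(stats::runif(3 * beads_per_mol, -10, 10), ncol = 3)
    blob[1, ] <- 0   # first bead at the centroid (connectivity guarantee)
    coords[idx, ] <- sweep(blob, 2, cents[m, ], "+")
  }
  traj <- as_cg_trajectory(coords, sys, box)
  attr(traj, "truth") <- list(
    slab_width = slab_width, n_condensed = n_condensed, n_dilute = n_dilute,
    density = n_condensed * beads_per_mol / (box[1] * box[2] * slab_width),
    seed = seed)
  traj
}

#' Planted micelle with prescribed domain radial ordering
#'
#' Each molecule's WR beads sit in a tight blob at the micelle core (all
#' cross-molecule WR pairs within the 6.5 A contact cutoff), its remaining
#' CTD beads on a shell placed so the CTD centroid lands at `r_ctd`, and its
#' DBD and NTD blobs at `r_dbd` and `r_ntd` along the molecule's own radial
#' direction.  Requires `r_ctd < r_dbd < r_ntd`.
#'
#' @param n_mol Number of molecules.
#' @param r_ctd,r_dbd,r_ntd Planted domain centroid radii (A).
#' @param box Box side lengths.
#' @param seed RNG seed.
#' @param center Micelle centre; defaults to the box centre.
#' @return A one-frame `cg_trajectory` with attribute `truth`.
#' @export
make_planted_micelle <- function(n_mol, r_ctd = 10, r_dbd = 40, r_ntd = 60,
                                 box = c(300, 300, 300), seed = 1,
                                 center = box / 2) {
  if (!(r_ctd < r_dbd && r_dbd < r_ntd)) stop("need r_ctd < r_dbd < r_ntd")
  if (2 * r_ntd >= min(box)) stop("geometry error: shell radius exceeds the box")
  set.seed(seed)
  chain <- fixture_chain(n_ntd = 6, n_dbd = 4, n_ctd = 10, n_wr = 4)
  sys <- fixture_system(n_mol, box, chain)
  nb <- nrow(chain$beads)
  n_wr <- sum(chain$beads$wr)
  n_ctd <- sum(chain$beads$domain == "CTD")
  # shell radius for non-WR CTD beads so the CTD centroid sits at r_ctd
  # (WR beads are at radius ~0): s = r_ctd * n_ctd / (n_ctd - n_wr)
  s_ctd <- r_ctd * n_ctd / (n_ctd - n_wr)
  coords <- matrix(0, n_mol * nb, 3)
  for (m in seq_len(n_mol)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    idx0 <- (m - 1) * nb
    for (i in seq_len(nb)) {
      b <- chain$beads[i, ]
      pos <- if (b$wr) {
        stats::rnorm(3, sd = 1.2)
      } else if (b$domain == "CTD") {
        s_ctd * u + stats::rnorm(3, sd = 1.5)
      } else if (b$domain == "DBD") {
        r_dbd * u + stats::rnorm(3, sd = 2)
      } else {
        r_ntd * u + stats::rnorm(3, sd = 2)
      }
      coords[idx0 + i, ] <- center + pos
    }
  }
  traj <- as_cg_trajectory(coords, sys, box)
  attr(traj, "truth") <- list(r_ctd = r_ctd, r_dbd = r_dbd, r_ntd = r_ntd,
                              n_mol = n_mol, seed = seed)
  traj
}

#' Independent Brownian walkers with a known diffusion coefficient
#'
#' Single-bead molecules taking independent Gaussian increments of variance
#' `2 D` per axis per step; coordinates are kept unwrapped, so the planted
#' `D` is exactly the MSD slope / 6.
#'
#' @param n Number of walkers.
#' @param D Diffusion coefficient (A^2/step).
#' @param n_steps Number of steps (the trajectory has `n_steps + 1` frames).
#' @param seed RNG seed.
#' @param box Box side lengths (start positions uniform inside).
#' @return A `cg_trajectory` with attribute `truth`.
#' @export
make_brownian_walkers <- function(n, D, n_steps, seed = 1,
                                  box = c(1000, 1000, 1000)) {
  stopifnot(D >= 0)
  set.seed(seed)
  chain <- fixture_chain(n_ntd = 0, n_dbd = 0, n_ctd = 1, n_wr = 0)
  sys <- fixture_system(n, box, chain)
  frames <- array(0, c(n, 3, n_steps + 1))
  frames[, , 1] <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                         stats::runif(n, 0, box[3]))
  sd_step <- sqrt(2 * D)
  for (t in seq_len(n_steps)) {
    frames[, , t + 1] <- frames[, , t] +
      matrix(stats::rnorm(3 * n, sd = sd_step), n, 3)
  }
  traj <- as_cg_trajectory(frames, sys, box)
  attr(traj, "truth") <- list(D = D, seed = seed)
  traj
}

#' Pair of pinned DNA duplexes at a fixed separation
#'
#' Two rigid duplexes whose centroids sit `separation` apart along x, with
#' optional per-frame rigid-body Gaussian jitter.
#'
#' @param separation Centroid separation (A).
#' @param n_frames Number of frames.
#' @param n_bp Base pairs per duplex.
#' @param jitter Rigid-body jitter standard deviation per axis (A); 0 gives a
#'   delta-like distance histogram.
#' @param box Box side lengths.
#' @param seed RNG seed.
#' @return A `cg_trajectory` with attribute `truth`.
#' @export
make_pinned_dna_pair <- function(separation, n_frames = 20, n_bp = 10,
                                 jitter = 0, box = c(500, 500, 500), seed = 1) {
  if (separation >= sqrt(sum(box^2)) / 2) {
    stop("separation too large for the box")
  }
  set.seed(seed)
  duplex <- build_dna_duplex(n_bp)
  sys <- build_system(list(list(topology = duplex, count = 2)), box = box)
  nb <- nrow(duplex$beads)
  template <- sweep(duplex$ref_coords, 2, colMeans(duplex$ref_coords))
  c1 <- box / 2 - c(separation / 2, 0, 0)
  c2 <- box / 2 + c(separation / 2, 0, 0)
  frames <- array(0, c(2 * nb, 3, n_frames))
  for (f in seq_len(n_frames)) {
    j1 <- stats::rnorm(3, sd = jitter); j2 <- stats::rnorm(3, sd = jitter)
    frames[seq_len(nb), , f] <- sweep(template, 2, c1 + j1, "+")
    frames[nb + seq_len(nb), , f] <- sweep(template, 2, c2 + j2, "+")
  }
  traj <- as_cg_trajectory(frames, sys, box)
  attr(traj, "truth") <- list(separation = separation, jitter = jitter,
                              seed = seed)
  traj
}

#' Slow micelle in a fast gas (tracking fixture)
#'
#' A planted micelle whose molecules share one slowly diffusing rigid frame
#' (plus per-molecule wobble), surrounded by independent fast Brownian
#' walker molecules.  Emulates the contrast between tracking the members of
#' one micelle and tracking a z window of the condensate.
#'
#' @param n_micelle,n_gas Molecule counts.
#' @param D_micelle,D_gas Centroid diffusion coefficients (A^2/step).
#' @param n_frames Number of frames.
#' @param box Box side lengths.
#' @param seed RNG seed.
#' @return A `cg_trajectory` with attribute `truth`.
#' @export
make_slow_micelle_fast_gas <- function(n_micelle = 8, n_gas = 12,
                                       D_micelle = 0.05, D_gas = 5,
                                       n_frames = 50, box = c(400, 400, 400),
                                       seed = 1) {
  set.seed(seed)
  chain <- fixture_chain()
  sys <- fixture_system(n_micelle + n_gas, box, chain)
  nb <- nrow(chain$beads)
  mic0 <- make_planted_micelle(n_micelle, box = box, seed = seed)
  mic_template <- mic0$frames[, , 1]
  frames <- array(0, c((n_micelle + n_gas) * nb, 3, n_frames))
  mic_shift <- c(0, 0, 0)
  gas_pos <- cbind(stats::runif(n_gas, 0, box[1]), stats::runif(n_gas, 0, box[2]),
                   stats::runif(n_gas, 0, box[3]))
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      mic_shift <- mic_shift + stats::rnorm(3, sd = sqrt(2 * D_micelle))
      gas_pos <- gas_pos + matrix(stats::rnorm(3 * n_gas, sd = sqrt(2 * D_gas)),
                                  n_gas, 3)
    }
    frames[seq_len(n_micelle * nb), , f] <- sweep(mic_template, 2, mic_shift, "+")
    for (g in seq_len(n_gas)) {
      idx <- (n_micelle + g - 1) * nb + seq_len(nb)
      blob <- matrix(stats::rnorm(3 * nb, sd = 3), nb, 3)
      frames[idx, , f] <- sweep(blob, 2, gas_pos[g, ], "+")
    }
  }
  traj <- as_cg_trajectory(frames, sys, box)
  attr(traj, "truth") <- list(n_micelle = n_micelle, n_gas = n_gas,
                              D_micelle = D_micelle, D_gas = D_gas, seed = seed)
  traj
}

#' Uniform ideal-gas configuration
#'
#' Molecules (bead blobs) placed uniformly at random in the box; the flat
#' reference for density-profile checks.
#'
#' @param n_mol Number of molecules.
#' @param box Box side lengths.
#' @param seed RNG seed.
#' @param beads_per_mol Beads per molecule.
#' @param n_frames Number of independent frames.
#' @return A `cg_trajectory`.
#' @export
make_ideal_gas <- function(n_mol, box = c(300, 300, 3000), seed = 1,
                           beads_per_mol = 5, n_frames = 1) {
  set.seed(seed)
  sys <- fixture_system(n_mol, box,
                        fixture_chain(n_ntd = 0, n_dbd = 0,
                                      n_ctd = beads_per_mol, n_wr = 0))
  nb_chain <- nrow(sys$molecules[[1]]$beads)
  frames <- array(0, c(n_mol * nb_chain, 3, n_frames))
  for (f in seq_len(n_frames)) {
    cents <- cbind(stats::runif(n_mol, 0, box[1]), stats::runif(n_mol, 0, box[2]),
                   stats::runif(n_mol, 0, box[3]))
    for (m in seq_len(n_mol)) {
      idx <- (m - 1) * nb_chain + seq_len(nb_chain)
      frames[idx, , f] <- sweep(matrix(stats::rnorm(3 * nb_chain, sd = 3),
                                       nb_chain, 3), 2, cents[m, ], "+")
    }
  }
  traj <- as_cg_trajectory(frames, sys, box)
  attr(traj, "truth") <- list(seed = seed)
  traj
}
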