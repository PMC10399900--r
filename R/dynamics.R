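#' Simulation configuration
#'
#' Collects box geometry, thermodynamic state and integrator settings.  The
#' defaults are the slab-box study conditions: 300 x 300 x 3000 A box, 300 K,
#' 125 mM monovalent salt.  The timestep is in model time units
#' (~48.9 fs each); friction is the Langevin collision rate in inverse time
#' units.
#'
#' @param box Side lengths (Lx, Ly, Lz) in Angstrom.
#' @param temperature Kelvin.
#' @param ionic_strength mol/L.
#' @param timestep Integration step, model time units.
#' @param friction Langevin friction, 1/time unit.
#' @param n_steps Number of MD steps.
#' @param seed Integer RNG seed (the run is bit-reproducible under it).
#' @param save_interval Steps between saved frames.
#' @param electrostatics,hps_scope Interaction-scope flags passed to
#'   [forcefield()].
#' @param hps_cutoff,dh_cutoff Nonbonded truncations in Angstrom.
#' @return A list of class `cg_config`.
#' @export
sim_config <- function(box = c(300, 300, 3000), temperature = 300,
                       ionic_strength = 0.125, timestep = 0.5, friction = 0.05,
                       n_steps = 1000, seed = 1, save_interval = 100,
                       electrostatics = TRUE, hps_scope = "disordered_only",
                       hps_cutoff = 25, dh_cutoff = 50) {
  if (any(box <= 0)) stop("box sides must be positive")
  if (timestep <= 0) stop("timestep must be positive")
  if (friction <= 0) stop("friction must be positive")
  if (n_steps < 0 || save_interval <= 0) stop("invalid step counts")
  structure(as.list(environment()), class = "cg_config")
}

config_forcefield <- function(config, nonbonded = TRUE) {
  forcefield(ionic_strength = config$ionic_strength,
             temperature = config$temperature,
             hps_cutoff = config$hps_cutoff, dh_cutoff = config$dh_cutoff,
             electrostatics = config$electrostatics,
             hps_scope = config$hps_scope, nonbonded = nonbonded)
}

#' Initial coordinates for a single chain
#'
#' Proteins are grown as a persistent random walk with 3.8 A steps and a soft
#' self-avoidance check; folded-domain beads follow the elastic-network
#' reference rigidly (randomly oriented).  DNA duplexes and crowders use their
#' reference geometry.
#'
#' @param topology A `cg_chain`.
#' @param seed RNG seed.
#' @return n x 3 coordinate matrix centred on the origin.
#' @export
chain_init_coords <- function(topology, seed = 1) {
  set.seed(seed)
  b <- topology$beads
  n <- nrow(b)
  if (topology$kind != "protein") {
    ref <- topology$ref_coords
    if (is.null(ref)) ref <- matrix(0, n, 3)
    return(sweep(ref, 2, colMeans(ref)))
  }
  coords <- matrix(0, n, 3)
  dbd <- which(b$domain == "DBD")
  rot <- random_rotation()
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  for (i in seq_len(n)) {
    if (i == 1) next
    if (i %in% dbd && !is.null(topology$ref_coords)) {
      k <- match(i, dbd)
      anchor <- dbd[1]
      base <- if (anchor == 1) c(0, 0, 0) else coords[anchor - 1, ]
      ref <- topology$ref_coords
      coords[i, ] <- base + drop(rot %*% (ref[k, ] - ref[1, ])) +
        if (anchor > 1) 3.8 * dir else 0
      next
    }
    for (try in 1:60) {
      step <- 0.75 * dir + rnorm(3, sd = 0.6)
      step <- 3.8 * step / sqrt(sum(step^2))
      cand <- coords[i - 1, ] + step
      prev <- coords[seq_len(max(1, i - 2)), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (all(d2 > 9) || try == 60) {
        coords[i, ] <- cand
        dir <- step / 3.8
        break
      }
    }
  }
  sweep(coords, 2, colMeans(coords))
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    nq <- sqrt(sum(q^2))
    if (nq > 1e-8) { q <- q / nq; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Place molecules at random without steric overlap
#'
#' Molecule templates are randomly rotated and their centroids drawn
#' uniformly in the box (optionally restricted to a z-window, for condensed
#' starting states); a candidate is rejected while any inter-molecular bead
#' distance falls below `min_separation`.  Deterministic under `seed`.
#'
#' @param system A `cg_system`.
#' @param box Box side lengths; defaults to the system box.
#' @param min_separation Minimum allowed inter-molecular bead distance (A).
#' @param seed RNG seed.
#' @param region_z Optional `c(zlo, zhi)` window for molecule centroids.
#' @param max_tries Retries per molecule before a packing error.
#' @return n x 3 coordinate matrix (unwrapped; molecules are contiguous).
#' @export
random_placement <- function(system, box = system$box, min_separation = 3.5,
                             seed = 1, region_z = NULL, max_tries = 200) {
  set.seed(seed)
  mols <- system$molecules
  templates <- lapply(seq_along(mols), function(m) {
    chain_init_coords(mols[[m]], seed = seed + m)
  })
  placed <- matrix(numeric(0), 0, 3)
  out <- vector("list", length(mols))
  zlo <- if (is.null(region_z)) 0 else region_z[1]
  zhi <- if (is.null(region_z)) box[3] else region_z[2]
  for (m in seq_along(mols)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      rot <- random_rotation()
      cand <- templates[[m]] %*% t(rot)
      center <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
                  stats::runif(1, zlo, zhi))
      cand <- sweep(cand, 2, center, "+")
      if (nrow(placed) == 0 ||
          !.cpp_any_within(cand, placed, as.numeric(box), min_separation)) {
        out[[m]] <- cand
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("packing error: could not place molecule ", m,
                  " after ", max_tries, " tries")
  }
  do.call(rbind, out)
}

#' Micelle-seeded placement of protein chains
#'
#' Arranges protein chains on a sphere with their tryptophan-repeat regions
#' pointing inward: each template conformation is rotated so the vector from
#' its centroid to its WR centroid aims at the cluster centre, and its WR
#' centroid is placed at `r_core` from the centre.  Produces a micelle-like
#' starting state (hydrophobic core inside, NTD/DBD outside) from which
#' dynamics decides whether the core persists or dissolves.
#'
#' @param system A `cg_system` of protein chains.
#' @param template n_beads x 3 conformation used for every chain (e.g. the
#'   final frame of a single-chain run), or a list of per-chain matrices.
#' @param r_core Target radius of the WR centroids from the cluster centre
#'   (A).
#' @param center Cluster centre; defaults to the box centre.
#' @param seed RNG seed (molecule directions).
#' @return n x 3 coordinate matrix.
#' @export
micelle_seed_placement <- function(system, template, r_core = 12,
                                   center = system$box / 2, seed = 1) {
  set.seed(seed)
  mols <- system$molecules
  out <- vector("list", length(mols))
  for (m in seq_along(mols)) {
    tpl <- if (is.list(template)) template[[m]] else template
    b <- mols[[m]]$beads
    stopifnot(nrow(tpl) == nrow(b))
    wr_idx <- which(b$wr)
    if (length(wr_idx) == 0) wr_idx <- which(b$domain == "CTD")
    cen_all <- colMeans(tpl)
    cen_wr <- colMeans(tpl[wr_idx, , drop = FALSE])
    v <- cen_wr - cen_all
    # outward direction for this molecule (quasi-uniform on the sphere)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    rot <- rotation_between(v / sqrt(sum(v^2)), -u)
    placed <- sweep(tpl, 2, cen_wr) %*% t(rot)   # WR centroid at origin
    out[[m]] <- sweep(placed, 2, center + r_core * u, "+")
  }
  do.call(rbind, out)
}

# rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) return(-diag(3))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Run Langevin dynamics
#'
#' Integrates the underdamped Langevin equation with the BAOAB splitting at
#' the configured temperature, with periodic minimum-image interactions in
#' all three axes.  Coordinates are integrated unwrapped (wrap on demand with
#' [wrap_coords()]); identical `(seed, config, initial)` give bit-identical
#' trajectories.
#'
#' @param system A `cg_system`.
#' @param config A `cg_config`.
#' @param initial n x 3 initial coordinates.
#' @param tether Optional harmonic tether list (`k`, `ref`), see
#'   [total_energy_forces()].
#' @param zero_velocities Start from zero velocities instead of a
#'   Maxwell-Boltzmann draw.
#' @param nonbonded Evaluate nonbonded interactions (`FALSE` leaves only
#'   bonded terms and tethers; used for ideal-chain and free-particle
#'   reference runs).
#' @return A `cg_trajectory`: `frames` (n x 3 x n_frames array, unwrapped),
#'   `steps`, per-frame `box` and `kinetic_temperature`, the `config`,
#'   `system` and `seed`.
#' @export
langevin_run <- function(system, config, initial, tether = NULL,
                         zero_velocities = FALSE, nonbonded = TRUE) {
  initial <- as.matrix(initial)
  stopifnot(nrow(initial) == nrow(system$beads))
  ff <- config_forcefield(config, nonbonded = nonbonded)
  sys <- system
  sys$box <- config$box
  run <- list(dt = config$timestep, friction = config$friction,
              temperature = config$temperature, n_steps = config$n_steps,
              save_interval = config$save_interval, seed = config$seed,
              zero_velocities = zero_velocities)
  res <- .cpp_langevin(initial, pack_system(sys, ff, tether), pack_ff(ff), run)
  structure(list(frames = res$frames, steps = res$steps,
                 box = res$box, kinetic_temperature = res$kinetic_temperature,
                 final_coords = res$final_coords,
                 final_velocities = res$final_velocities,
                 config = config, system = system, seed = config$seed),
            class = "cg_trajectory")
}

#' Shrink-to-condensate schedule
#'
#' Number of shrink events and MD steps needed to take the box from
#' `initial_lz` to `target_lz` at `dz_per_event` Angstrom every
#' `steps_per_event` steps.
#'
#' @param initial_lz,target_lz Initial and final z side lengths (A).
#' @param dz_per_event Shrink amount per event (A).
#' @param steps_per_event MD steps between events.
#' @return List with `n_events` and `n_steps`.
#' @export
shrink_schedule <- function(initial_lz, target_lz, dz_per_event = 0.1,
                            steps_per_event = 100) {
  if (target_lz > initial_lz) stop("target box must not exceed the initial box")
  n_events <- ceiling((initial_lz - target_lz) / dz_per_event - 1e-9)
  list(n_events = n_events, n_steps = n_events * steps_per_event)
}

#' Shrink-to-condensate protocol
#'
#' Runs Langevin dynamics while the z side of the box decreases by
#' `dz_per_event` every `steps_per_event` steps until `target_lz`, rescaling
#' z coordinates affinely at each event so that interactions relax locally as
#' the box closes.  With `target_lz` equal to the initial Lz this is a plain
#' run with zero shrink events.
#'
#' @inheritParams langevin_run
#' @param dz_per_event Shrink per event (A; 0.1 in the reference protocol).
#' @param steps_per_event Steps between events (100 in the reference
#'   protocol).
#' @param target_lz Final z side length (A).
#' @return A `cg_trajectory` whose per-frame `box` records the shrinking Lz.
#' @export
shrink_protocol <- function(system, config, initial, dz_per_event = 0.1,
                            steps_per_event = 100, target_lz) {
  sched <- shrink_schedule(config$box[3], target_lz, dz_per_event, steps_per_event)
  config$n_steps <- max(sched$n_steps, config$n_steps)
  ff <- config_forcefield(config)
  sys <- system
  sys$box <- config$box
  run <- list(dt = config$timestep, friction = config$friction,
              temperature = config$temperature, n_steps = config$n_steps,
              save_interval = config$save_interval, seed = config$seed,
              shrink_dz = dz_per_event, shrink_every = steps_per_event,
              target_lz = target_lz)
  res <- .cpp_langevin(as.matrix(initial), pack_system(sys, ff), pack_ff(ff), run)
  config$schedule <- sched
  structure(list(frames = res$frames, steps = res$steps,
                 box = res$box, kinetic_temperature = res$kinetic_temperature,
                 final_coords = res$final_coords,
                 final_velocities = res$final_velocities,
                 config = config, system = system, seed = config$seed),
            class = "cg_trajectory")
}

#' Relax a configuration by capped steepest descent
#'
#' Removes steric clashes left by random placement before dynamics: moves
#' every bead along the force direction, capping the per-bead displacement at
#' `max_step`, until the largest force falls below `fmax` or `n_iter`
#' iterations are spent.
#'
#' @param system A `cg_system`.
#' @param coords n x 3 starting coordinates.
#' @param ff A `cg_forcefield`.
#' @param n_iter Maximum iterations.
#' @param max_step Per-bead displacement cap (A).
#' @param fmax Convergence threshold on the largest force (kcal/mol/A).
#' @return Relaxed n x 3 coordinate matrix.
#' @export
minimize_coords <- function(system, coords, ff = forcefield(), n_iter = 300,
                            max_step = 0.3, fmax = 10) {
  coords <- as.matrix(coords)
  for (it in seq_len(n_iter)) {
    ef <- total_energy_forces(coords, system, ff)
    fnorm <- sqrt(rowSums(ef$forces^2))
    if (max(fnorm) < fmax) break
    scale <- pmin(0.02, max_step / pmax(fnorm, 1e-12))
    coords <- coords + ef$forces * scale
  }
  coords
}

#' Candidate interacting pairs within a cutoff
#'
#' All bead pairs within `cutoff` under the minimum-image convention.  The
#' cutoff must not exceed half the smallest box side (minimum-image
#' validity).
#'
#' @param frame n x 3 coordinate matrix.
#' @param box Box side lengths.
#' @param cutoff Distance cutoff (A).
#' @return Two-column integer matrix of 1-based pair indices (i < j).
#' @export
neighbor_list <- function(frame, box, cutoff) {
  if (cutoff > min(box) / 2) {
    stop("geometry error: cutoff exceeds half the smallest box side")
  }
  .cpp_pairs_within(as.matrix(frame), as.numeric(box), cutoff)
}

#' Wrap coordinates into the primary periodic box
#'
#' @param coords n x 3 matrix.
#' @param box Box side lengths.
#' @return Wrapped coordinates in `[0, L)` per axis.
#' @export
wrap_coords <- function(coords, box) {
  coords <- as.matrix(coords)
  for (d in 1:3) coords[, d] <- coords[, d] - box[d] * floor(coords[, d] / box[d])
  coords
}

#' Wrap whole molecules into the primary box
#'
#' Translates each molecule by integer box vectors so its centroid lies in
#' `[0, L)` per axis, preserving intra-molecular contiguity (unlike bead-wise
#' wrapping, which splits molecules across boundaries).  Needed when
#' re-embedding a configuration into a different box, e.g. after the shrink
#' protocol.
#'
#' @param coords n x 3 unwrapped coordinates (molecules contiguous).
#' @param system The `cg_system`.
#' @param box Box side lengths.
#' @return Translated n x 3 coordinate matrix.
#' @export
wrap_molecules <- function(coords, system, box = system$box) {
  coords <- as.matrix(coords)
  cents <- mol_centroids(coords, system)
  shift <- -sweep(floor(sweep(cents, 2, box, "/")), 2, box, "*")
  coords + shift[system$beads$mol, ]
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame as a coordinate matrix
#' @param traj A `cg_trajectory`.
#' @param f Frame index (1-based).
#' @return n x 3 matrix.
#' @export
get_frame <- function(traj, f) traj$frames[, , f]

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory: %d beads, %d frames, %d steps>\n",
              dim(x$frames)[1], n_frames(x), max(x$steps)))
  invisible(x)
}
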