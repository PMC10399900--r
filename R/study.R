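#' Collapsed single-chain conformation template
#'
#' Runs one chain from a self-avoiding-walk start through minimization and a
#' short Langevin relaxation, returning the final conformation.  Used as the
#' per-chain template for condensed and micelle-seeded starting states (the
#' reference protocol likewise packs compact single-chain conformations).
#'
#' @param topology A `cg_chain`.
#' @param seed RNG seed.
#' @param n_steps Relaxation steps.
#' @param ionic_strength mol/L.
#' @return n_beads x 3 coordinate matrix.
#' @export
chain_collapse_template <- function(topology, seed = 1, n_steps = 15000,
                                    ionic_strength = 0.125) {
  box <- c(400, 400, 400)
  sys <- build_system(list(list(topology = topology, count = 1)), box = box)
  ff <- forcefield(ionic_strength = ionic_strength,
                   hps_cutoff = 25, dh_cutoff = 35)
  co <- minimize_coords(sys, random_placement(sys, seed = seed), ff)
  cfg <- sim_config(box = box, ionic_strength = ionic_strength,
                    timestep = 0.5, friction = 0.01, n_steps = n_steps,
                    save_interval = n_steps, seed = seed,
                    hps_cutoff = 25, dh_cutoff = 35)
  langevin_run(sys, cfg, co)$final_coords
}

#' Desk-scale condensate study run
#'
#' The reduced condensate experiment used throughout the package's validation
#' studies: `n_chains` copies of a Nanog variant are seeded as a micelle
#' (WR cores inward, from a collapsed single-chain template) in a
#' 140 x 140 x 560 A slab and evolved by Langevin dynamics.  The seeded start
#' mirrors the reference design in which mutant runs begin from the
#' wild-type phase-separated configuration and the readout is retention
#' versus dissolution of the micelle core.  Optionally adds poly-CG DNA
#' duplexes just outside the droplet.
#'
#' @param variant A [build_nanog()] variant name, or a `cg_chain`.
#' @param n_chains Number of protein chains.
#' @param seed RNG seed for the whole protocol.
#' @param ionic_strength mol/L.
#' @param n_steps Production steps.
#' @param friction Langevin friction (1/time unit).
#' @param box Slab box (A).
#' @param r_core Seed radius of the WR centroids (A).
#' @param n_dna Number of 50 bp poly-CG duplexes placed outside the droplet.
#' @param save_interval Steps between saved frames.
#' @return List with `trajectory` (a `cg_trajectory`) and `system`.
#' @export
desk_condensate <- function(variant = "WT", n_chains = 8, seed = 1,
                            ionic_strength = 0.125, n_steps = 40000,
                            friction = 0.005, box = c(140, 140, 560),
                            r_core = 18, n_dna = 0, save_interval = 1000) {
  chain <- if (inherits(variant, "cg_chain")) variant else build_nanog(variant)
  ff <- forcefield(ionic_strength = ionic_strength,
                   hps_cutoff = 25, dh_cutoff = 35)
  tpl <- chain_collapse_template(chain, seed = seed,
                                 ionic_strength = ionic_strength)
  chains <- list(list(topology = chain, count = n_chains))
  if (n_dna > 0) {
    chains[[2]] <- list(topology = build_dna_duplex(50), count = n_dna)
  }
  sys <- build_system(chains, box = box)
  prot_sys <- build_system(list(list(topology = chain, count = n_chains)),
                           box = box)
  co_prot <- micelle_seed_placement(prot_sys, tpl, r_core = r_core,
                                    seed = seed)
  co <- co_prot
  if (n_dna > 0) {
    # duplexes just outside the droplet, alternating sides along z
    dna_tpl <- chain_init_coords(build_dna_duplex(50), seed = seed)
    extra <- lapply(seq_len(n_dna), function(k) {
      side <- if (k %% 2 == 0) 1 else -1
      sweep(dna_tpl, 2, box / 2 + c(0, 0, side * (r_core + 110 + 15 * k)), "+")
    })
    co <- rbind(co_prot, do.call(rbind, extra))
  }
  co <- minimize_coords(sys, co, ff, n_iter = 400)
  cfg <- sim_config(box = box, ionic_strength = ionic_strength,
                    timestep = 0.5, friction = friction, n_steps = n_steps,
                    save_interval = save_interval, seed = seed,
                    hps_cutoff = 25, dh_cutoff = 35)
  list(trajectory = langevin_run(sys, cfg, co), system = sys, chain = chain,
       template = tpl)
}

#' WR micelle retention statistic
#'
#' Fraction of the selected frames whose largest WR-contact cluster has at
#' least `min_size` molecules — the readout separating a stable micelle core
#' (retention near 1) from a dissolving one.
#'
#' @param traj A `cg_trajectory`.
#' @param frames Frame indices (default: the final third of the run).
#' @param min_size Cluster size threshold (5: the condensed-phase
#'   definition).
#' @param params An [analysis_params()] list.
#' @return List with `retention` (fraction) and `max_sizes` per frame.
#' @export
wr_retention <- function(traj, frames = NULL, min_size = 5,
                         params = analysis_params()) {
  nf <- n_frames(traj)
  if (is.null(frames)) frames <- seq(ceiling(2 * nf / 3), nf)
  mx <- vapply(frames, function(f) {
    max(wr_micelle_clusters(traj$frames[, , f], traj$system, traj$box[f, ],
                            cutoff = params$contact_cutoff_residue)$sizes)
  }, numeric(1))
  list(retention = mean(mx >= min_size), max_sizes = mx, frames = frames)
}
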