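# Desk-scale study runs shared across test files, computed lazily and cached
# for the session.  Protocols and sizes are the package's study conditions
# (see the methods vignette): 8 chains, 140 x 140 x 560 A slab, micelle
# seeded start, friction 0.005, HPS cutoff 25 A / DH cutoff 35 A.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, builder) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, builder(), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

sim_wt125 <- function() cached_sim("wt125", function() {
  desk_condensate("WT", n_chains = 8, seed = 101, ionic_strength = 0.125,
                  n_steps = 50000, save_interval = 500)
})

sim_w8a <- function() cached_sim("w8a", function() {
  desk_condensate("W8A", n_chains = 8, seed = 101, ionic_strength = 0.125,
                  n_steps = 60000)
})

# 16 half-length chains: same total residue count as 8 full-length chains,
# so peak z-density profiles compare raw bead counts at matched mass
sim_octd <- function() cached_sim("octd", function() {
  desk_condensate("OnlyCTD", n_chains = 16, seed = 101,
                  ionic_strength = 0.125, n_steps = 40000)
})

sim_wt50 <- function() cached_sim("wt50", function() {
  desk_condensate("WT", n_chains = 8, seed = 101, ionic_strength = 0.05,
                  n_steps = 40000)
})

sim_dna <- function() cached_sim("dna", function() {
  desk_condensate("WT", n_chains = 8, seed = 101, ionic_strength = 0.125,
                  n_steps = 50000, n_dna = 2)
})

# isolated chains at the condensate friction (dilute-phase reference);
# three independent runs because a single chain's MSD estimate is noisy
sim_single_dilute <- function() cached_sim("single_dilute", function() {
  wt <- build_nanog("WT")
  box <- c(700, 700, 700)
  sys <- build_system(list(list(topology = wt, count = 1)), box = box)
  ff <- forcefield(hps_cutoff = 25, dh_cutoff = 35)
  lapply(101:103, function(s) {
    co <- minimize_coords(sys, random_placement(sys, seed = s), ff)
    cfg <- sim_config(box = box, timestep = 0.5, friction = 0.005,
                      n_steps = 40000, save_interval = 500, seed = s,
                      hps_cutoff = 25, dh_cutoff = 35)
    langevin_run(sys, cfg, co)
  })
})

# single-chain expansion run (faster friction, longer: samples extension)
sim_single_expansion <- function() cached_sim("single_expansion", function() {
  wt <- build_nanog("WT")
  box <- c(700, 700, 700)
  sys <- build_system(list(list(topology = wt, count = 1)), box = box)
  ff <- forcefield(hps_cutoff = 25, dh_cutoff = 35)
  co <- minimize_coords(sys, random_placement(sys, seed = 101), ff)
  cfg <- sim_config(box = box, timestep = 0.5, friction = 0.01,
                    n_steps = 2e5, save_interval = 500, seed = 101,
                    hps_cutoff = 25, dh_cutoff = 35)
  list(trajectory = langevin_run(sys, cfg, co), system = sys)
})

late_frames <- function(tr) {
  nf <- n_frames(tr)
  seq(ceiling(2 * nf / 3), nf)
}

peak_profile_density <- function(tr) {
  dp <- density_profile_z(tr, z_bin = 10, frames = late_frames(tr),
                          center = TRUE)
  max(dp$counts)
}
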