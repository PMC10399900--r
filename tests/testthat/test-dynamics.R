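# a non-interacting single-bead chain for integrator checks
free_bead_system <- function(n, box = c(500, 500, 500)) {
  chain <- nanogmicelle:::fixture_chain(n_ntd = 0, n_dbd = 0, n_ctd = 1,
                                        n_wr = 0)
  build_system(list(list(topology = chain, count = n)), box = box)
}

test_that("zero-temperature zero-velocity dynamics leaves coordinates fixed", {
  sys <- free_bead_system(5)
  # beads far beyond every cutoff: all forces are zero
  co <- cbind(seq(50, 450, by = 100), seq(50, 450, by = 100), 250)
  cfg <- sim_config(box = sys$box, temperature = 0, n_steps = 200,
                    save_interval = 50, seed = 1)
  tr <- langevin_run(sys, cfg, co, zero_velocities = TRUE)
  expect_equal(tr$final_coords, co, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(n_frames(tr), 200 / 50 + 1)
})

test_that("trajectories are bit-reproducible under the seed", {
  sys <- free_bead_system(20)
  set.seed(9); co <- matrix(runif(60) * 400 + 50, 20, 3)
  cfg <- sim_config(box = sys$box, n_steps = 500, save_interval = 100, seed = 42)
  t1 <- langevin_run(sys, cfg, co)
  t2 <- langevin_run(sys, cfg, co)
  expect_identical(t1$frames, t2$frames)
  cfg2 <- cfg; cfg2$seed <- 43
  t3 <- langevin_run(sys, cfg2, co)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("free diffusion matches the Langevin closed form", {
  # D = kB T / (m gamma); MSD slope = 6 D
  n <- 100
  sys <- free_bead_system(n)
  set.seed(2); co <- matrix(runif(3 * n) * 400 + 50, n, 3)
  cfg <- sim_config(box = sys$box, timestep = 0.2, friction = 0.5,
                    n_steps = 20000, save_interval = 20, seed = 7)
  traj <- langevin_run(sys, cfg, co, nonbonded = FALSE)
  m <- msd_diffusion(traj, "all", max_lag = 300, lag_stride = 10,
                     origin_stride = 10)
  d_expected <- 0.0019872041 * 300 / (100 * 0.5) * 0.2  # A^2 per MD step
  expect_equal(m$D, d_expected, tolerance = 0.05)
  # equipartition: kinetic temperature within 2 %
  expect_equal(mean(traj$kinetic_temperature[-1]), 300, tolerance = 0.02)
})

test_that("harmonic tether sampling satisfies equipartition", {
  n <- 50
  sys <- free_bead_system(n)
  ref <- matrix(250, n, 3)
  k <- 0.5
  cfg <- sim_config(box = sys$box, timestep = 0.2, friction = 0.5,
                    n_steps = 30000, save_interval = 30, seed = 5)
  tr <- langevin_run(sys, cfg, ref, tether = list(k = rep(k, n), ref = ref),
                     nonbonded = FALSE)
  # discard equilibration, pool squared displacements over beads and frames
  fr <- tr$frames[, , -(1:200)]
  v <- mean((fr - 250)^2)
  expect_equal(v, 0.0019872041 * 300 / k, tolerance = 0.05)
})

test_that("shrink schedule arithmetic matches the printed protocol", {
  s <- shrink_schedule(6000, 3000, 0.1, 100)
  expect_equal(s$n_events, 30000)
  expect_equal(s$n_steps, 3e6)
  expect_equal(shrink_schedule(3000, 3000)$n_steps, 0)
  expect_error(shrink_schedule(3000, 4000), "target")
})

test_that("shrink protocol reaches the target box and keeps beads inside", {
  sys <- free_bead_system(30, box = c(150, 150, 600))
  set.seed(4)
  co <- cbind(runif(30, 0, 150), runif(30, 0, 150), runif(30, 0, 600))
  cfg <- sim_config(box = c(150, 150, 600), n_steps = 100, save_interval = 100,
                    seed = 3)
  tr <- shrink_protocol(sys, cfg, co, dz_per_event = 2, steps_per_event = 10,
                        target_lz = 400)
  expect_equal(tail(tr$box[, 3], 1), 400)
  expect_equal(tr$config$schedule$n_steps, 100 * 10)
  # wrapped coordinates lie inside the instantaneous box in every frame
  for (f in seq_len(n_frames(tr))) {
    z <- wrap_coords(tr$frames[, , f], tr$box[f, ])[, 3]
    expect_true(all(z >= 0 & z < tr$box[f, 3]))
  }
  # target equal to initial Lz is a plain run
  tr0 <- shrink_protocol(sys, cfg, co, target_lz = 600)
  expect_equal(unique(tr0$box[, 3]), 600)
})

test_that("random placement respects the separation and the seed", {
  wt <- build_nanog("OnlyCTD")
  sys <- build_system(list(list(topology = wt, count = 4)),
                      box = c(250, 250, 250))
  f1 <- random_placement(sys, min_separation = 4, seed = 8)
  f2 <- random_placement(sys, min_separation = 4, seed = 8)
  expect_identical(f1, f2)
  # min inter-molecular bead distance >= min_separation
  b <- sys$beads
  dmin <- Inf
  for (a in 1:3) for (bb in (a + 1):4) {
    ia <- which(b$mol == a); ib <- which(b$mol == bb)
    for (i in ia) {
      d <- sweep(f1[ib, , drop = FALSE], 2, f1[i, ])
      d <- d - sweep(round(sweep(d, 2, sys$box, "/")), 2, sys$box, "*")
      dmin <- min(dmin, sqrt(min(rowSums(d^2))))
    }
  }
  expect_gte(dmin, 4)
  # single-molecule centroids are uniform across seeds (coarse check)
  one <- build_system(list(list(topology = wt, count = 1)),
                      box = c(200, 200, 200))
  cents <- t(vapply(1:40, function(s) {
    colMeans(random_placement(one, seed = s))
  }, numeric(3)))
  expect_true(all(apply(cents, 2, sd) > 20))
})

test_that("neighbor list equals brute force and honors periodic images", {
  set.seed(6)
  box <- c(100, 100, 100)
  co <- matrix(runif(600) * 100, 200, 3)
  nl <- neighbor_list(co, box, 15)
  # brute-force oracle
  oracle <- c()
  for (i in 1:199) for (j in (i + 1):200) {
    d <- co[i, ] - co[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= 15) oracle <- c(oracle, paste(i, j))
  }
  expect_setequal(paste(nl[, 1], nl[, 2]), oracle)
  # x-boundary image pair
  two <- rbind(c(1, 50, 50), c(99, 50, 50))
  nl2 <- neighbor_list(two, box, 5)
  expect_equal(nrow(nl2), 1)
  expect_equal(nrow(neighbor_list(matrix(numeric(0), 0, 3), box, 5)), 0)
  expect_error(neighbor_list(two, box, 60), "geometry")
})

test_that("wrap helpers preserve minimum-image energies and contiguity", {
  wt <- build_nanog("OnlyCTD")
  sys <- build_system(list(list(topology = wt, count = 2)),
                      box = c(150, 150, 150))
  co <- minimize_coords(sys, random_placement(sys, seed = 2), forcefield(),
                        n_iter = 30)
  w <- wrap_coords(co, sys$box)
  expect_true(all(w >= 0 & w < 151))
  wm <- wrap_molecules(co + 450, sys)
  cents <- nanogmicelle:::mol_centroids(wm, sys)
  expect_true(all(cents >= 0 & cents < 150))
  # molecule-wise wrap preserves all intra-molecular distances exactly
  expect_equal(as.numeric(dist(wm[1:151, ])), as.numeric(dist(co[1:151, ])),
               tolerance = 1e-9)
})
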