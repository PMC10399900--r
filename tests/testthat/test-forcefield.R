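test_that("HPS pair energy reduces to plain Lennard-Jones at lambda 1", {
  r <- seq(4, 20, by = 0.5)
  lj <- 4 * 0.2 * ((6 / r)^12 - (6 / r)^6)
  expect_equal(hps_pair_energy(r, 6, 1, 0.2), lj, tolerance = 1e-12)
})

test_that("both HPS branches agree at the branch point", {
  set.seed(1)
  for (k in 1:100) {
    sig <- runif(1, 4, 8); lam <- runif(1); eps <- runif(1, 0.05, 0.5)
    rmin <- 2^(1 / 6) * sig
    below <- hps_pair_energy(rmin * (1 - 1e-9), sig, lam, eps)
    above <- hps_pair_energy(rmin * (1 + 1e-9), sig, lam, eps)
    expect_equal(below, above, tolerance = 1e-6)
    expect_equal(hps_pair_energy(rmin, sig, lam, eps), -lam * eps,
                 tolerance = 1e-12)
  }
})

test_that("lambda 0 pairs are purely repulsive", {
  expect_equal(hps_pair_energy(c(8, 12, 20), 6, 0, 0.2), c(0, 0, 0))
  expect_gt(hps_pair_energy(5, 6, 0, 0.2), 0)
})

test_that("HPS energy is zero beyond a finite cutoff and continuous there", {
  u_at <- hps_pair_energy(24.9999, 6, 0.7, 0.2, cutoff = 25)
  expect_equal(u_at, 0, tolerance = 1e-6)
  expect_equal(hps_pair_energy(26, 6, 0.7, 0.2, cutoff = 25), 0)
})

test_that("Debye length follows the closed form and its power law", {
  # closed-form oracle evaluated from SI constants
  dl_oracle <- function(I, T, epsr) {
    sqrt(8.8541878128e-12 * epsr * 1.380649e-23 * T /
           (2 * 6.02214076e23 * 1.602176634e-19^2 * I * 1000)) * 1e10
  }
  expect_equal(debye_length(0.125, 300, 78), dl_oracle(0.125, 300, 78))
  expect_equal(debye_length(0.125, 300, 78), 8.6, tolerance = 0.02)
  expect_equal(debye_length(2, 300, 78), 2.2, tolerance = 0.03)
  expect_equal(debye_length(0.5, 300, 78), debye_length(0.125, 300, 78) / 2,
               tolerance = 1e-12)
  expect_error(debye_length(0), "ionic strength")
})

test_that("Debye-Hueckel energy obeys the screening identity", {
  ld <- debye_length(0.125, 300, 78)
  u1 <- dh_pair_energy(ld, 1, 1)
  u2 <- dh_pair_energy(2 * ld, 1, 1)
  expect_equal(u2 * 2 / u1, exp(-1), tolerance = 1e-12)
  expect_equal(dh_pair_energy(c(5, 10, 30), 0, 1), c(0, 0, 0))
  # independent constant-by-constant evaluation: opposite unit charges, 10 A
  oracle <- 332.0637 * (-1) / (78 * 10) * exp(-10 / ld)
  expect_equal(dh_pair_energy(10, 1, -1), oracle, tolerance = 1e-12)
  expect_lt(dh_pair_energy(10, 1, -1), 0)
  expect_error(dh_pair_energy(0, 1, 1), "singular")
})

test_that("excluded volume is repulsive, monotone, and truncated", {
  sig <- 6.2
  expect_equal(excluded_volume_energy(2^(1 / 6) * sig, sig), 0)
  expect_equal(excluded_volume_energy(10, sig), 0)
  expect_equal(excluded_volume_energy(sig, sig, epsilon = 0.2), 0.2,
               tolerance = 1e-12)
  r <- seq(0.5 * sig, 2^(1 / 6) * sig, length.out = 50)
  expect_true(all(diff(excluded_volume_energy(r, sig)) < 0))
})

test_that("elastic network building enumerates cutoff pairs", {
  ref <- cbind(0, 0, c(0, 5, 10))
  en <- elastic_network_build(ref, cutoff = 8, k = 2)
  expect_equal(nrow(en), 2)
  expect_equal(en[, c("i", "j")], data.frame(i = c(1, 2), j = c(2, 3)),
               ignore_attr = TRUE)
  expect_equal(en$r0, c(5, 5))
  expect_error(elastic_network_build(ref[1, , drop = FALSE], 8, 2), "at least 2")
})

test_that("elastic network energy is zero at reference and harmonic away", {
  # 3 collinear beads 5 A apart, network cutoff 8: restraints (1,2) and (2,3)
  ref <- cbind(0, 0, c(0, 5, 10))
  chain <- nanogmicelle:::fixture_chain(n_ntd = 0, n_dbd = 3, n_ctd = 0,
                                        n_wr = 0)
  chain$epairs <- elastic_network_build(ref, cutoff = 8, k = 2)
  names(chain$epairs)[4] <- "r0"
  sys <- build_system(list(list(topology = chain, count = 1)),
                      box = c(500, 500, 500))
  co <- sweep(ref, 2, c(250, 250, 250), "+")
  ff <- forcefield(nonbonded = FALSE)
  expect_equal(total_energy_forces(co, sys, ff)$terms[["elastic"]], 0,
               tolerance = 1e-12)
  # stretch the terminal bead along the bond: only restraint (2,3) engaged
  co2 <- co; co2[3, 3] <- co2[3, 3] + 0.25
  e1 <- total_energy_forces(co2, sys, ff)$terms[["elastic"]]
  expect_equal(e1, 2 * 0.25^2, tolerance = 1e-12)
  # displacing the middle bead along the axis engages both restraints
  co3 <- co; co3[2, 3] <- co3[2, 3] + 0.25
  expect_equal(total_energy_forces(co3, sys, ff)$terms[["elastic"]],
               2 * 2 * 0.25^2, tolerance = 1e-12)
})

test_that("forces are exact gradients and sum to zero", {
  # random 20-bead chain, relaxed enough to avoid steep-core cancellation
  set.seed(7)
  chain <- build_nanog("WT", sequence = paste(sample(c("A", "W", "E", "K", "S"),
                                                     20, TRUE), collapse = ""),
                       domains = nanog_domains(c(1, 7), c(8, 13), c(14, 20)))
  sys <- build_system(list(list(topology = chain, count = 1)),
                      box = c(120, 120, 120))
  ff <- forcefield()
  co <- minimize_coords(sys, chain_init_coords(chain, seed = 2) + 60, ff,
                        n_iter = 50)
  ef <- total_energy_forces(co, sys, ff)
  h <- 1e-4
  for (i in seq_len(nrow(co))) {
    for (d in 1:3) {
      cp <- co; cm <- co
      cp[i, d] <- cp[i, d] + h; cm[i, d] <- cm[i, d] - h
      fd <- -(total_energy_forces(cp, sys, ff)$energy -
                total_energy_forces(cm, sys, ff)$energy) / (2 * h)
      expect_equal(fd, ef$forces[i, d], tolerance = 1e-5)
    }
  }
  expect_equal(colSums(ef$forces), c(0, 0, 0), tolerance = 1e-9)
})

test_that("energy is invariant under rigid translation and box wrapping", {
  wt <- build_nanog("WT")
  sys <- build_system(list(list(topology = wt, count = 2)),
                      box = c(200, 200, 200))
  ff <- forcefield()
  co <- minimize_coords(sys, random_placement(sys, seed = 4), ff, n_iter = 50)
  e0 <- total_energy_forces(co, sys, ff)$energy
  e1 <- total_energy_forces(sweep(co, 2, c(13.7, -8.1, 44.4), "+"), sys, ff)$energy
  expect_equal(e1, e0, tolerance = 1e-7 * max(1, abs(e0)))
  # wrap molecule 2 by one box vector in each axis
  shift <- cbind(c(rep(0, 305), rep(200, 305)),
                 c(rep(0, 305), rep(-200, 305)),
                 c(rep(0, 305), rep(400, 305)))
  e2 <- total_energy_forces(co + shift, sys, ff)$energy
  expect_equal(e2, e0, tolerance = 1e-7 * max(1, abs(e0)))
  # far-separated molecules do not interact
  far <- co
  far[306:610, ] <- sweep(chain_init_coords(wt, 9), 2, c(100, 100, 100), "+")
  sys_big <- build_system(list(list(topology = wt, count = 2)),
                          box = c(1000, 1000, 1000))
  far[1:305, ] <- sweep(chain_init_coords(wt, 8), 2, c(500, 500, 800), "+")
  far[306:610, ] <- sweep(chain_init_coords(wt, 9), 2, c(500, 500, 200), "+")
  ef <- total_energy_forces(far, sys_big, forcefield(nonbonded = TRUE))
  # interaction terms vanish; only intra-molecular contributions remain,
  # so cross-molecule forces must be zero: compare with single-molecule runs
  one <- build_system(list(list(topology = wt, count = 1)),
                      box = c(1000, 1000, 1000))
  e_a <- total_energy_forces(far[1:305, ], one, ff)$energy
  e_b <- total_energy_forces(far[306:610, ], one, ff)$energy
  expect_equal(ef$energy, e_a + e_b, tolerance = 1e-9 * max(1, abs(ef$energy)))
})

test_that("HPS scope flags change only folded-domain pair terms", {
  wt <- build_nanog("WT")
  sys <- build_system(list(list(topology = wt, count = 2)),
                      box = c(200, 200, 200))
  co <- minimize_coords(sys, random_placement(sys, seed = 12), forcefield(),
                        n_iter = 30)
  e_dis <- total_energy_forces(co, sys, forcefield(hps_scope = "disordered_only"))
  e_all <- total_energy_forces(co, sys, forcefield(hps_scope = "all_residues"))
  e_any <- total_energy_forces(co, sys, forcefield(hps_scope = "disordered_any"))
  # bonded and electrostatic terms identical; only hps/ev redistribute
  expect_equal(e_dis$terms[["dh"]], e_all$terms[["dh"]])
  expect_equal(e_dis$terms[["bond"]], e_all$terms[["bond"]])
  expect_false(isTRUE(all.equal(e_dis$terms[["hps"]], e_all$terms[["hps"]])))
  # recompute the scope difference with a brute-force R oracle over DBD pairs
  b <- sys$beads
  ff <- forcefield()
  pairs <- neighbor_list(co, sys$box, ff$hps_cutoff)
  bonded <- paste(sys$bonds$i, sys$bonds$j)
  epair <- paste(sys$epairs$i, sys$epairs$j)
  dis <- b$disordered
  delta <- 0
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (paste(i, j) %in% c(bonded, epair)) next
    involves_dbd <- !(dis[i] && dis[j])
    if (!involves_dbd) next
    d <- co[i, ] - co[j, ]
    d <- d - sys$box * round(d / sys$box)
    r <- sqrt(sum(d^2))
    sig <- (b$sigma[i] + b$sigma[j]) / 2
    lam <- (b$lam[i] + b$lam[j]) / 2
    delta <- delta + hps_pair_energy(r, sig, lam, 0.2, cutoff = ff$hps_cutoff) -
      excluded_volume_energy(r, sig, 0.2)
  }
  expect_equal(e_all$energy - e_dis$energy, delta,
               tolerance = 1e-6 * max(1, abs(delta)))
  # "disordered_any" sits between the two scopes by construction
  expect_gte(e_any$terms[["hps"]], min(e_dis$terms[["hps"]], e_all$terms[["hps"]]) - 1e-9)
})

test_that("Trp-Trp HPS minimum is deeper than Ala-Ala", {
  p <- hps_params()
  uw <- hps_pair_energy(2^(1 / 6) * p["W", "sigma"], p["W", "sigma"],
                        p["W", "lambda"], 0.2)
  ua <- hps_pair_energy(2^(1 / 6) * p["A", "sigma"], p["A", "sigma"],
                        p["A", "lambda"], 0.2)
  expect_lt(uw, ua)
  expect_gt(p["W", "lambda"], p["A", "lambda"])
})
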