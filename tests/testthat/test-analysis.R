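test_that("density profile is flat for a uniform gas and conserves counts", {
  gas <- make_ideal_gas(400, box = c(300, 300, 1500), seed = 1,
                        beads_per_mol = 5, n_frames = 4)
  dp <- density_profile_z(gas, z_bin = 100)
  expect_equal(sum(dp$counts) * dp$n_frames, 400 * 5 * 4)
  # flat within Poisson error: every bin within 5 sigma of the mean
  mu <- mean(dp$counts)
  expect_true(all(abs(dp$counts - mu) < 5 * sqrt(mu)))
})

test_that("planted slab density plateau has the constructed width", {
  tp <- make_two_phase(30, 2, slab_width = 400, box = c(300, 300, 3000),
                       seed = 2)
  truth <- attr(tp, "truth")
  params <- analysis_params(z_bin = 20, density_threshold = truth$density / 2)
  ext <- condensate_extent(tp, params)
  expect_equal(ext$breadth[1], 400, tolerance = 20 / 400 * 2)
  dp <- density_profile_z(tp, z_bin = 20)
  expect_equal(sum(dp$counts), nrow(tp$system$beads))
})

test_that("condensate extent handles empty, uniform, and wrapped slabs", {
  params <- analysis_params(z_bin = 50, density_threshold = 1e-4)
  gas <- make_ideal_gas(20, box = c(300, 300, 3000), seed = 3)
  expect_equal(condensate_extent(gas, params)$breadth[1], 0)
  # slab straddling the periodic z boundary: shift a centred slab by Lz/2
  tp <- make_two_phase(30, 0, slab_width = 400, box = c(300, 300, 3000),
                       seed = 4)
  shifted <- tp
  shifted$frames[, 3, 1] <- shifted$frames[, 3, 1] + 1500
  p2 <- analysis_params(z_bin = 20,
                        density_threshold = attr(tp, "truth")$density / 2)
  b0 <- condensate_extent(tp, p2)$breadth[1]
  b1 <- condensate_extent(shifted, p2)$breadth[1]
  expect_equal(b1, b0)
})

test_that("contact map matches a brute-force oracle and is symmetric", {
  # hand-built 2-chain, 3-residue frame
  chain <- nanogmicelle:::fixture_chain(n_ntd = 1, n_dbd = 1, n_ctd = 1,
                                        n_wr = 0)
  sys <- build_system(list(list(topology = chain, count = 2)),
                      box = c(100, 100, 100))
  co <- rbind(c(10, 10, 10), c(14, 10, 10), c(18, 10, 10),
              c(10, 14, 10), c(30, 30, 30), c(18, 16, 10))
  traj <- as_cg_trajectory(co, sys)
  cm <- intermolecular_contact_map(traj, cutoff = 6.5)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    d <- sqrt(sum((co[i, ] - co[3 + j, ])^2))
    if (d <= 6.5) {
      oracle[i, j] <- oracle[i, j] + 1
      oracle[j, i] <- oracle[j, i] + 1
    }
  }
  oracle <- oracle / 2  # one frame, M(M-1) = 2 ordered pairs
  expect_equal(cm, oracle)
  expect_equal(cm, t(cm))
  # far-separated chains give the zero map
  far <- rbind(co[1:3, ], co[1:3, ] + 200)
  sysbig <- build_system(list(list(topology = chain, count = 2)),
                         box = c(1000, 1000, 1000))
  expect_true(all(intermolecular_contact_map(
    as_cg_trajectory(far, sysbig), 6.5) == 0))
})

test_that("molecule clustering equals a union-find oracle on random frames", {
  set.seed(11)
  for (rep in 1:5) {
    gas <- make_ideal_gas(20, box = c(200, 200, 200), seed = rep,
                          beads_per_mol = 4)
    co <- gas$frames[, , 1]
    sys <- gas$system
    cutoff <- 40
    cl <- molecule_clusters(co, sys, cutoff = cutoff)
    # brute-force union-find over the molecule min-distance matrix
    parent <- 1:20
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in 1:19) for (b in (a + 1):20) {
      ia <- which(sys$beads$mol == a); ib <- which(sys$beads$mol == b)
      dmin <- Inf
      for (i in ia) {
        d <- sweep(co[ib, , drop = FALSE], 2, co[i, ])
        d <- d - sweep(round(sweep(d, 2, sys$box, "/")), 2, sys$box, "*")
        dmin <- min(dmin, sqrt(min(rowSums(d^2))))
      }
      if (dmin <= cutoff) parent[find(a)] <- find(b)
    }
    oracle <- vapply(1:20, find, 1L)
    # same partition: co-membership matrices agree
    expect_equal(outer(cl$membership, cl$membership, "=="),
                 outer(oracle, oracle, "=="))
    expect_equal(sum(cl$sizes), 20)
  }
})

test_that("clustering boundary cases behave as defined", {
  chain <- nanogmicelle:::fixture_chain(n_ntd = 0, n_dbd = 0, n_ctd = 1,
                                        n_wr = 0)
  sys <- build_system(list(list(topology = chain, count = 2)),
                      box = c(1000, 1000, 1000))
  near <- rbind(c(100, 100, 100), c(149, 100, 100))
  expect_equal(molecule_clusters(near, sys, cutoff = 50)$sizes, 2L)
  far <- rbind(c(100, 100, 100), c(151, 100, 100))
  expect_equal(molecule_clusters(far, sys, cutoff = 50)$sizes, c(1L, 1L))
})

test_that("WR micelle graph sees only WR-bead contacts", {
  mic <- make_planted_micelle(10, 10, 40, 60, seed = 5)
  sys <- mic$system
  co <- mic$frames[, , 1]
  cl <- wr_micelle_clusters(co, sys)
  expect_equal(max(cl$sizes), 10)
  # brute-force WR-pair adjacency oracle against the engine's graph kernel
  b <- sys$beads
  adj <- matrix(FALSE, 10, 10); diag(adj) <- TRUE
  for (a in 1:9) for (bb in (a + 1):10) {
    ia <- which(b$mol == a & b$wr); ib <- which(b$mol == bb & b$wr)
    dmin <- min(as.matrix(stats::dist(rbind(co[ia, ], co[ib, ])))[
      seq_along(ia), length(ia) + seq_along(ib)])
    adj[a, bb] <- adj[bb, a] <- dmin <= 6.5
  }
  keep <- b$wr
  eng <- nanogmicelle:::.cpp_mol_graph(co[keep, , drop = FALSE],
                                       as.integer(b$mol[keep]),
                                       as.numeric(sys$box), 6.5)
  expect_equal(unname(eng), adj)
  # two molecules touching only via NTD beads are not WR-connected
  chain <- nanogmicelle:::fixture_chain(n_ntd = 3, n_dbd = 0, n_ctd = 4,
                                        n_wr = 2)
  sys2 <- build_system(list(list(topology = chain, count = 2)),
                       box = c(500, 500, 500))
  co2 <- matrix(0, 14, 3)
  co2[1:3, ] <- cbind(100 + c(0, 2, 4), 100, 100)       # NTD A
  co2[4:7, ] <- cbind(160 + c(0, 2, 4, 6), 100, 100)    # CTD A (incl WR)
  co2[8:10, ] <- cbind(103 + c(0, 2, 4), 100, 100)      # NTD B touches NTD A
  co2[11:14, ] <- cbind(200 + c(0, 2, 4, 6), 100, 100)  # CTD B far away
  expect_equal(max(wr_micelle_clusters(co2, sys2)$sizes), 1)
  expect_equal(max(molecule_clusters(co2, sys2, cutoff = 50)$sizes), 2)
  # singleton cluster for one molecule
  expect_equal(wr_micelle_clusters(
    make_planted_micelle(1, 10, 40, 60)$frames[, , 1],
    make_planted_micelle(1, 10, 40, 60)$system)$sizes, 1L)
})

test_that("dilute phase bookkeeping matches the planted fixture", {
  tp <- make_two_phase(30, 2, slab_width = 400, box = c(300, 300, 3000),
                       seed = 6)
  truth <- attr(tp, "truth")
  params <- analysis_params(z_bin = 20, density_threshold = truth$density / 2)
  st <- dilute_phase_stats(tp, params)
  expect_equal(st$n_dilute[1], 2)
  v_dilute <- prod(c(300, 300, 3000)) - st$extent[1] * 300 * 300
  expect_equal(st$concentration[1],
               2 / (6.02214076e23 * v_dilute * 1e-27))
  # conservation: dilute + condensed-cluster molecules = total
  cl <- molecule_clusters(tp$frames[, , 1], tp$system)
  big <- which(tabulate(cl$membership) >= 5)
  expect_equal(sum(cl$membership %in% big) + st$n_dilute[1], 32)
})

test_that("a cluster of exactly five molecules is condensed", {
  # 5 single-bead molecules in a tight line, 2 isolated
  chain <- nanogmicelle:::fixture_chain(n_ntd = 0, n_dbd = 0, n_ctd = 1,
                                        n_wr = 0)
  sys <- build_system(list(list(topology = chain, count = 7)),
                      box = c(2000, 2000, 2000))
  co <- rbind(cbind(100 + 40 * (0:4), 100, 100),
              c(1000, 1000, 1000), c(1500, 300, 900))
  traj <- as_cg_trajectory(co, sys)
  st <- dilute_phase_stats(traj, analysis_params(z_bin = 100,
                                                 density_threshold = 1e-7))
  expect_equal(st$n_dilute[1], 2)
  # all molecules in one cluster -> zero dilute
  co2 <- cbind(100 + 10 * (0:6), 100, 100)
  st2 <- dilute_phase_stats(as_cg_trajectory(co2, sys),
                            analysis_params(z_bin = 100,
                                            density_threshold = 1e-7))
  expect_equal(st2$n_dilute[1], 0)
})

test_that("domain radial profile recovers planted shell ordering", {
  mic <- make_planted_micelle(10, 10, 40, 60, seed = 7)
  cl <- wr_micelle_clusters(mic$frames[, , 1], mic$system)
  mem <- which(cl$membership == which.max(tabulate(cl$membership)))
  rp <- domain_radial_profile(mic$frames[, , 1], mic$system, mem)
  med <- tapply(rp$distance, rp$domain, median)
  expect_equal(unname(med["CTD"]), 10, tolerance = 0.15 * 10)
  expect_equal(unname(med["DBD"]), 40, tolerance = 0.15 * 40)
  expect_equal(unname(med["NTD"]), 60, tolerance = 0.15 * 60)
  expect_true(med["CTD"] < med["DBD"] && med["DBD"] < med["NTD"])
  # ordering invariant under rigid translation across the periodic boundary
  sh <- mic$frames[, , 1]
  sh <- sweep(sh, 2, c(140, 0, 250), "+")
  rp2 <- domain_radial_profile(sh, mic$system, mem)
  med2 <- tapply(rp2$distance, rp2$domain, median)
  expect_equal(unname(med2), unname(med), tolerance = 1e-6)
  # single-molecule cluster: finite distances around its own centroid
  rp1 <- domain_radial_profile(mic$frames[, , 1], mic$system, mem[1])
  expect_true(all(is.finite(rp1$distance)))
})

test_that("cluster size histograms are normalised and static-stable", {
  mic <- make_planted_micelle(10, 10, 40, 60, seed = 8)
  frames <- array(rep(mic$frames[, , 1], 10),
                  c(dim(mic$frames)[1], 3, 10))
  static <- as_cg_trajectory(frames, mic$system)
  cs <- cluster_size_distribution(static, "wr_graph", period_split = 5)
  expect_true(all(abs(rowSums(cs$histograms) - 1) < 1e-12))
  for (p in 2:5) expect_equal(cs$histograms[p, ], cs$histograms[1, ])
  expect_true(all(cs$convergence < 1e-12))
  expect_equal(which(cs$histograms[1, ] > 0), 10)
})

test_that("MSD recovers a planted diffusion coefficient", {
  bw <- make_brownian_walkers(100, D = 2.5, n_steps = 800, seed = 9)
  m <- msd_diffusion(bw, "all", max_lag = 160, lag_stride = 8,
                     origin_stride = 4)
  expect_equal(m$D, 2.5, tolerance = 0.05)
  expect_equal(m$msd[1], 0)
  expect_true(all(m$msd >= 0))
  # static trajectory: D = 0
  st <- make_brownian_walkers(20, D = 0, n_steps = 50, seed = 10)
  m0 <- msd_diffusion(st, "all", max_lag = 20)
  expect_equal(m0$D, 0)
  expect_true(all(m0$msd == 0))
  expect_error(msd_diffusion(make_brownian_walkers(5, 1, 1, seed = 1)),
               "insufficient")
})

test_that("tracked-set variance grows like 2 D t for free walkers", {
  # narrow z window (FRAP-like): small initial variance, growth 2 D t visible
  bw <- make_brownian_walkers(600, D = 3, n_steps = 300, seed = 11,
                              box = c(500, 500, 120))
  tv <- tracked_set_variance(bw, "z_window", reference_frame = 1,
                             z_window = c(0, 120))
  lags <- tv$lag_frames
  fit <- stats::lm(tv$variance ~ lags)
  expect_equal(unname(coef(fit)[2]), 2 * 3, tolerance = 0.15)
  # variance at lag 0 equals the selection's initial spread
  z0 <- bw$frames[tv$molecules, 3, 1]
  expect_equal(tv$variance[1], mean((z0 - mean(z0))^2))
})

test_that("micelle tracking is slower than FRAP-like tracking on the planted mix", {
  smg <- make_slow_micelle_fast_gas(n_micelle = 8, n_gas = 12,
                                    D_micelle = 0.05, D_gas = 5,
                                    n_frames = 40, seed = 12)
  mic <- tracked_set_variance(smg, "micelle", reference_frame = 1)
  expect_equal(length(mic$molecules), 8)
  frap <- tracked_set_variance(smg, "z_window", reference_frame = 1,
                               z_window = c(0, 400))
  late <- 10:40
  growth_mic <- mic$variance[late] - mic$variance[1]
  growth_frap <- frap$variance[late] - frap$variance[1]
  expect_lt(mean(growth_mic), mean(growth_frap))
  # all micelle members remain co-clustered in the rigid fixture
  expect_true(all(mic$n_remaining == 8))
  # static trajectory: constant variance and membership
  stat <- make_slow_micelle_fast_gas(6, 4, 0, 0, n_frames = 10, seed = 13)
  mv <- tracked_set_variance(stat, "micelle", reference_frame = 1)
  expect_true(all(mv$n_remaining == mv$n_remaining[1]))
})

test_that("DNA distance histogram matches pinned fixtures and brute force", {
  pin <- make_pinned_dna_pair(160, n_frames = 15, jitter = 0, seed = 14)
  dd <- dna_distance_distribution(pin, breaks = seq(0, 400, 10))
  expect_equal(sum(dd$histogram), 15)  # one pair x 15 frames
  expect_equal(max(abs(dd$distances - 160)), 0, tolerance = 1e-9)
  jit <- make_pinned_dna_pair(160, n_frames = 30, jitter = 2, seed = 15)
  dj <- dna_distance_distribution(jit, breaks = seq(0, 400, 10))
  expect_equal(dj$mids[which.max(dj$histogram)], 165, tolerance = 10)
  # brute-force centroid-distance oracle on one frame
  co <- jit$frames[, , 3]
  b <- jit$system$beads
  w <- b$mass
  c1 <- colSums(co[b$mol == 1, ] * w[b$mol == 1]) / sum(w[b$mol == 1])
  c2 <- colSums(co[b$mol == 2, ] * w[b$mol == 2]) / sum(w[b$mol == 2])
  d <- c1 - c2; d <- d - jit$box[3, ] * round(d / jit$box[3, ])
  dd3 <- dna_distance_distribution(jit, breaks = seq(0, 400, 10), frames = 3)
  expect_equal(dd3$distances, sqrt(sum(d^2)))
  expect_error(dna_distance_distribution(make_ideal_gas(3, seed = 1)), "DNA")
})

test_that("periodic-aware centroids respect wrapping", {
  box <- c(100, 100, 100)
  co <- rbind(c(98, 50, 50), c(2, 50, 50))
  cen <- pbc_centroid(co, box)
  expect_true(cen[1] < 2 || cen[1] > 98)
  expect_equal(cen[2:3], c(50, 50), tolerance = 1e-9)
})
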