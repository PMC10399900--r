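#' Analysis parameter set
#'
#' Cutoffs and bins shared by the condensate analyses: 6.5 A residue-residue
#' contacts, 50 A molecule-molecule interaction graph, dilute phase defined
#' as molecules outside clusters of five or more, z histogram bin, and the
#' bead-density threshold defining the condensed slab (when `NULL`, half the
#' maximum bin density of the profile being thresholded).
#'
#' @param contact_cutoff_residue Residue contact cutoff (A).
#' @param interaction_cutoff_molecule Molecule interaction cutoff (A).
#' @param dilute_min_cluster Minimum cluster size counted as condensed.
#' @param z_bin z histogram bin width (A).
#' @param density_threshold Beads/A^3 above which a bin is condensed, or
#'   `NULL` for the half-maximum rule.
#' @return A list of class `cg_analysis_params`.
#' @export
analysis_params <- function(contact_cutoff_residue = 6.5,
                            interaction_cutoff_molecule = 50,
                            dilute_min_cluster = 5,
                            z_bin = 10,
                            density_threshold = NULL) {
  if (contact_cutoff_residue <= 0 || interaction_cutoff_molecule <= 0 ||
      z_bin <= 0) stop("cutoffs and bins must be positive")
  if (dilute_min_cluster < 2) stop("dilute_min_cluster must be >= 2")
  structure(as.list(environment()), class = "cg_analysis_params")
}

#' Wrap precomputed frames into a trajectory object
#'
#' Used by the synthetic fixture generators and for analysis-only input, so
#' fixtures and engine output are interchangeable.
#'
#' @param frames n x 3 x F array (or a single n x 3 matrix) of unwrapped
#'   coordinates with molecules contiguous.
#' @param system The `cg_system` the coordinates belong to.
#' @param box Box side lengths; defaults to the system box.
#' @param steps Step index per frame.
#' @return A `cg_trajectory`.
#' @export
as_cg_trajectory <- function(frames, system, box = system$box, steps = NULL) {
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1))
  nf <- dim(frames)[3]
  if (is.null(steps)) steps <- seq_len(nf) - 1
  structure(list(frames = frames, steps = steps,
                 box = matrix(rep(as.numeric(box), each = nf), nf, 3),
                 kinetic_temperature = rep(NA_real_, nf),
                 config = NULL, system = system, seed = NA),
            class = "cg_trajectory")
}

#' Periodic-aware centroid by the circular-mean method
#'
#' @param coords n x 3 matrix.
#' @param box Box side lengths.
#' @param weights Optional weights (e.g. masses).
#' @return Length-3 centroid inside `[0, L)`.
#' @export
pbc_centroid <- function(coords, box, weights = NULL) {
  coords <- as.matrix(coords)
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  w <- weights / sum(weights)
  out <- numeric(3)
  for (d in 1:3) {
    th <- 2 * pi * coords[, d] / box[d]
    ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
    out[d] <- (ang / (2 * pi)) %% 1 * box[d]
  }
  out
}

mol_kinds <- function(system) vapply(system$molecules, function(m) m$kind, "")

# per-molecule centroids from unwrapped coordinates (molecules contiguous)
mol_centroids <- function(coords, system, mass_weighted = TRUE) {
  b <- system$beads
  w <- if (mass_weighted) b$mass else rep(1, nrow(b))
  cx <- rowsum(coords * w, b$mol) / rowsum(w, b$mol)[, 1]
  unname(as.matrix(cx))
}

min_image <- function(d, L) d - L * round(d / L)

#' z-axis density profile of bead counts
#'
#' Histogram of wrapped bead z coordinates averaged over frames, as behind
#' the amino-acid distribution plots.  With `center = TRUE` each frame is
#' shifted so the periodic-aware centroid of the selected beads sits at
#' Lz/2 before binning (removes slab drift before averaging).
#'
#' @param traj A `cg_trajectory`.
#' @param z_bin Bin width (A); must not exceed Lz.
#' @param select Optional bead indices (e.g. one species); default all.
#' @param frames Frame indices to average; default all.
#' @param center Centre the profile on the selection's centroid per frame.
#' @return List with `z` (bin centres), `counts` (mean beads per bin),
#'   `concentration` (mol/L of beads per bin), `total_counts`, `n_frames`,
#'   `z_bin`.
#' @export
density_profile_z <- function(traj, z_bin = 10, select = NULL, frames = NULL,
                              center = FALSE) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  lz <- traj$box[frames[1], 3]
  if (z_bin > lz) stop("z_bin exceeds the box z side")
  nb <- max(1, floor(lz / z_bin))
  edges <- seq(0, lz, length.out = nb + 1)
  counts <- numeric(nb)
  for (f in frames) {
    co <- traj$frames[, , f]
    if (!is.null(select)) co <- co[select, , drop = FALSE]
    z <- co[, 3]
    if (center) {
      cz <- pbc_centroid(co, traj$box[f, ], NULL)[3]
      z <- z + (lz / 2 - cz)
    }
    z <- z - lz * floor(z / lz)
    idx <- pmin(nb, floor(z / lz * nb) + 1)
    counts <- counts + tabulate(idx, nbins = nb)
  }
  bin_vol_l <- traj$box[frames[1], 1] * traj$box[frames[1], 2] *
    (lz / nb) * 1e-27
  list(z = (edges[-1] + edges[-(nb + 1)]) / 2,
       counts = counts / length(frames),
       concentration = counts / length(frames) / (cg_constants$avogadro * bin_vol_l),
       total_counts = sum(counts), n_frames = length(frames), z_bin = lz / nb)
}

#' Inter-molecular residue-residue contact map
#'
#' Symmetric L x L matrix whose (i, j) entry is the mean number of frames and
#' ordered molecule pairs in which residue i of one molecule lies within
#' `cutoff` of residue j of another (minimum-image distances).
#'
#' @param traj A `cg_trajectory`.
#' @param cutoff Contact cutoff (A), 6.5 by default.
#' @param frames Frame indices; default all.
#' @param normalize `"ordered_pairs"` (mean per frame per ordered molecule
#'   pair, the default) or `"frame"` (mean total count per frame).
#' @return L x L numeric matrix.
#' @export
intermolecular_contact_map <- function(traj, cutoff = 6.5, frames = NULL,
                                       normalize = c("ordered_pairs", "frame")) {
  normalize <- match.arg(normalize)
  system <- traj$system
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  keep <- system$beads$kind == "protein"
  if (sum(keep) == 0) stop("contact map needs protein chains")
  molid <- as.integer(factor(system$beads$mol[keep]))
  resid <- system$beads$resid[keep]
  m_count <- max(molid)
  if (m_count < 2) stop("contact map needs at least two protein chains")
  L <- max(resid)
  acc <- matrix(0, L, L)
  for (f in frames) {
    co <- traj$frames[, , f][keep, , drop = FALSE]
    acc <- acc + .cpp_contact_counts(co, molid, as.integer(resid),
                                     traj$box[f, ], cutoff, L)
  }
  denom <- if (normalize == "ordered_pairs") {
    length(frames) * m_count * (m_count - 1)
  } else {
    length(frames)
  }
  acc / denom
}

cluster_from_adjacency <- function(adj, ids) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  names(membership) <- ids
  membership
}

#' Molecule clusters from the 50 A interaction graph
#'
#' Single-linkage connected components of the molecule graph whose edges join
#' molecules whose minimum bead-bead distance is at most `cutoff`.  Crowders
#' are never part of the graph.
#'
#' @param frame n x 3 coordinate matrix (one trajectory frame).
#' @param system The `cg_system`.
#' @param box Box side lengths.
#' @param cutoff Interaction cutoff (A), 50 by default.
#' @return A `cg_clusters` object: `method`, `membership` (cluster id per
#'   molecule, NA for molecules outside the graph), `sizes` (multiset of
#'   cluster sizes).
#' @export
molecule_clusters <- function(frame, system, box = system$box, cutoff = 50) {
  kinds <- mol_kinds(system)
  in_graph <- which(kinds != "crowder")
  keep <- system$beads$mol %in% in_graph
  molid <- as.integer(factor(system$beads$mol[keep], levels = in_graph))
  adj <- .cpp_mol_graph(as.matrix(frame)[keep, , drop = FALSE], molid,
                        as.numeric(box), cutoff)
  membership <- rep(NA_integer_, length(kinds))
  membership[in_graph] <- cluster_from_adjacency(adj, in_graph)
  structure(list(method = "interaction_graph", cutoff = cutoff,
                 membership = membership,
                 sizes = as.integer(table(membership))),
            class = "cg_clusters")
}

#' Micelle clusters from tryptophan-repeat contacts
#'
#' Connected components of the molecule graph with an edge whenever any
#' WR-region bead pair of two molecules lies within `cutoff` (6.5 A).
#' Molecules without annotated WR spans (DNA, crowders) are excluded from the
#' graph and get membership NA.  The W8A mutant retains its WR spans (with
#' alanines), so it participates in the graph.
#'
#' @inheritParams molecule_clusters
#' @param cutoff WR contact cutoff (A), 6.5 by default.
#' @return A `cg_clusters` object with method `wr_graph`.
#' @export
wr_micelle_clusters <- function(frame, system, box = system$box, cutoff = 6.5) {
  has_wr <- vapply(seq_along(system$molecules), function(m) {
    any(system$beads$wr[system$beads$mol == m])
  }, TRUE)
  in_graph <- which(has_wr)
  if (length(in_graph) == 0) stop("no molecule carries WR annotation")
  keep <- system$beads$mol %in% in_graph & system$beads$wr
  molid <- as.integer(factor(system$beads$mol[keep], levels = in_graph))
  adj <- .cpp_mol_graph(as.matrix(frame)[keep, , drop = FALSE], molid,
                        as.numeric(box), cutoff)
  membership <- rep(NA_integer_, length(system$molecules))
  membership[in_graph] <- cluster_from_adjacency(adj, in_graph)
  structure(list(method = "wr_graph", cutoff = cutoff,
                 membership = membership,
                 sizes = as.integer(table(membership))),
            class = "cg_clusters")
}

#' Dilute-phase molecule counts and concentration
#'
#' A molecule is dilute when it does not belong to an interaction-graph
#' cluster of `dilute_min_cluster` (five) or more molecules.  The dilute
#' volume is the box volume minus the condensed-slab volume (condensate
#' extent times the box cross-section); the concentration averages dilute
#' counts over that volume.  Frames whose dilute volume degenerates to zero
#' or below are flagged `NA`.
#'
#' @param traj A `cg_trajectory`.
#' @param params An [analysis_params()] list.
#' @param frames Frame indices; default all.
#' @return List with per-frame `n_dilute`, `concentration` (mol/L), their
#'   means (`mean_n`, `mean_concentration`), standard error
#'   `se_concentration`, and the per-frame condensed `extent` (A).
#' @export
dilute_phase_stats <- function(traj, params = analysis_params(), frames = NULL) {
  system <- traj$system
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  kinds <- mol_kinds(system)
  prot <- which(kinds == "protein")
  ext <- condensate_extent(traj, params, frames = frames)
  n_dilute <- numeric(length(frames))
  conc <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[k]
    cl <- molecule_clusters(traj$frames[, , f], system, traj$box[f, ],
                            cutoff = params$interaction_cutoff_molecule)
    big <- which(tabulate(cl$membership) >= params$dilute_min_cluster)
    dil <- prot[!(cl$membership[prot] %in% big)]
    n_dilute[k] <- length(dil)
    v_dil <- prod(traj$box[f, ]) -
      ext$breadth[k] * traj$box[f, 1] * traj$box[f, 2]
    conc[k] <- if (v_dil > 0) n_dilute[k] / (cg_constants$avogadro * v_dil * 1e-27)
               else NA_real_
  }
  ok <- !is.na(conc)
  list(frames = frames, n_dilute = n_dilute, concentration = conc,
       extent = ext$breadth,
       mean_n = mean(n_dilute), mean_concentration = mean(conc[ok]),
       se_concentration = stats::sd(conc[ok]) / sqrt(max(1, sum(ok))))
}

#' Condensed-slab extent along z
#'
#' Per frame, the largest contiguous (periodic-aware) run of z bins whose
#' bead density exceeds the threshold; reports the z interval, its breadth,
#' and the number of molecules whose centroid falls inside it.
#'
#' @param traj A `cg_trajectory`.
#' @param params An [analysis_params()] list (bin width and threshold).
#' @param frames Frame indices; default all.
#' @return List of per-frame vectors `breadth` (A), `z_lo`, `z_hi`
#'   (interval, possibly wrapping), and `n_condensed` molecules.
#' @export
condensate_extent <- function(traj, params = analysis_params(), frames = NULL) {
  system <- traj$system
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  breadth <- numeric(length(frames))
  z_lo <- numeric(length(frames)); z_hi <- numeric(length(frames))
  n_cond <- integer(length(frames))
  kinds <- mol_kinds(system)
  for (k in seq_along(frames)) {
    f <- frames[k]
    box <- traj$box[f, ]
    lz <- box[3]
    nb <- max(1, floor(lz / params$z_bin))
    co <- traj$frames[, , f]
    z <- co[, 3]; z <- z - lz * floor(z / lz)
    cnt <- tabulate(pmin(nb, floor(z / lz * nb) + 1), nbins = nb)
    bin_vol <- box[1] * box[2] * (lz / nb)
    dens <- cnt / bin_vol
    thr <- if (is.null(params$density_threshold)) max(dens) / 2 else
      params$density_threshold
    above <- dens > thr
    if (!any(above) || is.null(params$density_threshold) && max(cnt) == 0) {
      breadth[k] <- 0; z_lo[k] <- NA; z_hi[k] <- NA; n_cond[k] <- 0
      next
    }
    run <- longest_circular_run(above)
    breadth[k] <- run$len * (lz / nb)
    z_lo[k] <- (run$start - 1) * (lz / nb)
    z_hi[k] <- (z_lo[k] + breadth[k]) %% lz
    cz <- mol_centroids(co, system)[, 3]
    cz <- cz - lz * floor(cz / lz)
    inside <- if (z_lo[k] <= z_hi[k] && run$len < nb) {
      cz >= z_lo[k] & cz < z_hi[k]
    } else if (run$len >= nb) rep(TRUE, length(cz)) else {
      cz >= z_lo[k] | cz < z_hi[k]
    }
    n_cond[k] <- sum(inside & kinds == "protein")
  }
  list(frames = frames, breadth = breadth, z_lo = z_lo, z_hi = z_hi,
       n_condensed = n_cond)
}

# longest run of TRUE in a circular logical vector
longest_circular_run <- function(x) {
  n <- length(x)
  if (all(x)) return(list(start = 1, len = n))
  if (!any(x)) return(list(start = NA, len = 0))
  xx <- c(x, x)
  r <- rle(xx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths == max(r$lengths[r$values]))
  best <- cand[1]
  list(start = (starts[best] - 1) %% n + 1, len = min(n, r$lengths[best]))
}

#' Domain distances from the cluster centre
#'
#' For each molecule of a cluster and each annotated domain, the
#' minimum-image distance between the domain centroid and the periodic-aware
#' (circular-mean) cluster centroid; mass-weighted by default.
#'
#' @param frame n x 3 coordinate matrix.
#' @param system The `cg_system`.
#' @param members Molecule indices forming the cluster.
#' @param box Box side lengths.
#' @param mass_weighted Mass-weight the centroids (geometric when `FALSE`).
#' @return Data frame with `mol`, `domain`, `distance` (A).
#' @export
domain_radial_profile <- function(frame, system, members, box = system$box,
                                  mass_weighted = TRUE) {
  stopifnot(length(members) >= 1)
  frame <- as.matrix(frame)
  b <- system$beads
  sel <- b$mol %in% members
  w <- if (mass_weighted) b$mass[sel] else NULL
  center <- pbc_centroid(frame[sel, , drop = FALSE], box, w)
  rows <- list()
  for (m in members) {
    for (dom in unique(b$domain[b$mol == m])) {
      idx <- which(b$mol == m & b$domain == dom)
      ww <- if (mass_weighted) b$mass[idx] else rep(1, length(idx))
      dc <- colSums(frame[idx, , drop = FALSE] * ww) / sum(ww)
      d <- sqrt(sum(min_image(dc - center, box)^2))
      rows[[length(rows) + 1]] <- data.frame(mol = m, domain = dom, distance = d)
    }
  }
  do.call(rbind, rows)
}

#' Cluster-size distributions over simulation periods
#'
#' Splits the frames into `period_split` consecutive periods and returns the
#' normalised histogram of cluster sizes per period, plus the L1 distance
#' between consecutive period histograms as a convergence diagnostic.
#'
#' @param traj A `cg_trajectory`.
#' @param method `"wr_graph"` or `"interaction_graph"`.
#' @param period_split Number of periods (10 in the reference analysis).
#' @param params An [analysis_params()] list.
#' @return List with `sizes` (histogram support), `histograms`
#'   (period x size matrix, rows sum to 1), `convergence` (L1 distances).
#' @export
cluster_size_distribution <- function(traj, method = c("wr_graph", "interaction_graph"),
                                      period_split = 10,
                                      params = analysis_params()) {
  method <- match.arg(method)
  nf <- n_frames(traj)
  if (nf < period_split) stop("need at least period_split frames")
  period <- cut(seq_len(nf), period_split, labels = FALSE)
  max_size <- length(traj$system$molecules)
  hist_m <- matrix(0, period_split, max_size)
  for (f in seq_len(nf)) {
    cl <- if (method == "wr_graph") {
      wr_micelle_clusters(traj$frames[, , f], traj$system, traj$box[f, ],
                          cutoff = params$contact_cutoff_residue)
    } else {
      molecule_clusters(traj$frames[, , f], traj$system, traj$box[f, ],
                        cutoff = params$interaction_cutoff_molecule)
    }
    for (s in cl$sizes) hist_m[period[f], s] <- hist_m[period[f], s] + 1
  }
  hist_m <- hist_m / pmax(1, rowSums(hist_m))
  conv <- if (period_split > 1) {
    rowSums(abs(hist_m[-1, , drop = FALSE] - hist_m[-period_split, , drop = FALSE]))
  } else numeric(0)
  list(sizes = seq_len(max_size), histograms = hist_m, convergence = conv)
}

#' Mean-square displacement and diffusion coefficient
#'
#' Time-origin-averaged MSD of molecule centroids (unwrapped coordinates),
#' optionally restricted to molecules classified dilute or condensed at each
#' origin (50 A interaction clustering; molecules keep their origin-phase
#' label for the whole window).  The diffusion coefficient comes from the
#' linear regression MSD = 6 D t over the stated lag window.
#'
#' @param traj A `cg_trajectory`.
#' @param phase `"all"`, `"dilute"` or `"condensed"`.
#' @param params An [analysis_params()] list.
#' @param max_lag Largest lag in frames (default: half the trajectory).
#' @param fit_range Lag window (fraction of `max_lag`) for the linear fit.
#' @param molecules Optional molecule indices to restrict to.
#' @param lag_stride,origin_stride Evaluate every `lag_stride`-th lag using
#'   every `origin_stride`-th time origin (subsampling for long
#'   trajectories).
#' @return List of class `cg_msd`: `lag_steps`, `msd` (A^2), `D`
#'   (A^2/step), `phase`, `fit` (the `lm` object), `n_origins`.
#' @export
msd_diffusion <- function(traj, phase = c("all", "dilute", "condensed"),
                          params = analysis_params(), max_lag = NULL,
                          fit_range = c(0.1, 0.5), molecules = NULL,
                          lag_stride = 1, origin_stride = 1) {
  phase <- match.arg(phase)
  system <- traj$system
  nf <- n_frames(traj)
  if (nf < 3) stop("insufficient data: need at least 3 frames")
  if (is.null(max_lag)) max_lag <- floor(nf / 2)
  kinds <- mol_kinds(system)
  prot <- which(kinds == "protein")
  if (!is.null(molecules)) prot <- intersect(prot, molecules)
  cents <- array(0, c(length(system$molecules), 3, nf))
  for (f in seq_len(nf)) cents[, , f] <- mol_centroids(traj$frames[, , f], system)
  phase_ok <- matrix(TRUE, length(system$molecules), nf)
  if (phase != "all") {
    for (f in seq_len(nf)) {
      cl <- molecule_clusters(traj$frames[, , f], system, traj$box[f, ],
                              cutoff = params$interaction_cutoff_molecule)
      big <- which(tabulate(cl$membership) >= params$dilute_min_cluster)
      cond <- cl$membership %in% big
      phase_ok[, f] <- if (phase == "condensed") cond else !cond
    }
  }
  lags <- unique(c(0, seq(lag_stride, max_lag, by = lag_stride)))
  msd <- numeric(length(lags))
  n_org <- 0L
  for (li in seq_along(lags)) {
    lag <- lags[li]
    acc <- 0; cnt <- 0
    for (t0 in seq(1, nf - lag, by = origin_stride)) {
      sel <- prot[phase_ok[prot, t0]]
      if (length(sel) == 0) next
      d <- cents[sel, , t0 + lag, drop = FALSE] - cents[sel, , t0, drop = FALSE]
      acc <- acc + sum(d^2)
      cnt <- cnt + length(sel)
      if (lag == 0) n_org <- n_org + length(sel)
    }
    msd[li] <- if (cnt > 0) acc / cnt else NA_real_
  }
  step_per_frame <- if (length(traj$steps) > 1) diff(traj$steps[1:2]) else 1
  lag_steps <- lags * step_per_frame
  win <- lags >= fit_range[1] * max_lag & lags <= fit_range[2] * max_lag & lags > 0
  fit <- stats::lm(msd[win] ~ lag_steps[win])
  d_coef <- unname(stats::coef(fit)[2]) / 6
  structure(list(lag_steps = lag_steps, msd = msd, D = d_coef, phase = phase,
                 fit = fit, n_origins = n_org),
            class = "cg_msd")
}

#' Spread of a tracked molecule set (FRAP-like and micelle tracking)
#'
#' Marks molecules at a reference frame either by a z window around a chosen
#' position (the FRAP-like selection) or by membership in one WR-contact
#' micelle, then follows the variance of their unwrapped z centroids as a
#' function of lag.  For micelle selections it also reports, per lag, how
#' many of the original members still share a WR cluster (the cluster holding
#' the largest number of original members).
#'
#' @param traj A `cg_trajectory`.
#' @param selection `"z_window"` or `"micelle"`.
#' @param reference_frame Frame index of the selection.
#' @param z_window For `"z_window"`: `c(zlo, zhi)` on wrapped centroid z.
#' @param micelle_id For `"micelle"`: cluster id at the reference frame
#'   (default: the largest WR cluster).
#' @param params An [analysis_params()] list.
#' @return List with `molecules` tracked, `lag_frames`, `variance` (A^2) and,
#'   for micelle selections, `n_remaining` per lag.
#' @export
tracked_set_variance <- function(traj, selection = c("z_window", "micelle"),
                                 reference_frame = 1, z_window = NULL,
                                 micelle_id = NULL,
                                 params = analysis_params()) {
  selection <- match.arg(selection)
  system <- traj$system
  nf <- n_frames(traj)
  stopifnot(reference_frame >= 1, reference_frame <= nf)
  kinds <- mol_kinds(system)
  ref <- traj$frames[, , reference_frame]
  box <- traj$box[reference_frame, ]
  cents_ref <- mol_centroids(ref, system)
  if (selection == "z_window") {
    if (is.null(z_window)) stop("z_window selection needs a z window")
    zw <- cents_ref[, 3] - box[3] * floor(cents_ref[, 3] / box[3])
    tracked <- which(zw >= z_window[1] & zw < z_window[2] & kinds == "protein")
  } else {
    cl <- wr_micelle_clusters(ref, system, box,
                              cutoff = params$contact_cutoff_residue)
    if (is.null(micelle_id)) {
      micelle_id <- which.max(tabulate(cl$membership))
    }
    tracked <- which(cl$membership == micelle_id)
  }
  if (length(tracked) == 0) stop("selection error: no molecule selected")
  lags <- 0:(nf - reference_frame)
  variance <- numeric(length(lags))
  n_remaining <- rep(NA_integer_, length(lags))
  for (li in seq_along(lags)) {
    f <- reference_frame + lags[li]
    cz <- mol_centroids(traj$frames[, , f], system)[tracked, 3]
    variance[li] <- stats::var(cz) * (length(cz) - 1) / length(cz)
    if (selection == "micelle") {
      cl_f <- wr_micelle_clusters(traj$frames[, , f], system, traj$box[f, ],
                                  cutoff = params$contact_cutoff_residue)
      mem <- cl_f$membership[tracked]
      n_remaining[li] <- if (all(is.na(mem))) 0L else
        max(table(mem[!is.na(mem)]))
    }
  }
  list(selection = selection, molecules = tracked, reference_frame = reference_frame,
       lag_frames = lags, variance = variance,
       n_remaining = if (selection == "micelle") n_remaining else NULL)
}

#' DNA-DNA centroid distance distribution
#'
#' Minimum-image distances between the centroids of all DNA duplex pairs over
#' the frames, histogrammed.
#'
#' @param traj A `cg_trajectory`.
#' @param breaks Histogram breaks (A) or a bin count.
#' @param frames Frame indices; default all.
#' @return List with `distances` (all pair/frame values), `histogram`
#'   (counts), `mids` (bin centres).
#' @export
dna_distance_distribution <- function(traj, breaks = 30, frames = NULL) {
  system <- traj$system
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  dna <- which(mol_kinds(system) == "dna_duplex")
  if (length(dna) < 2) stop("need at least two DNA duplexes")
  pairs <- utils::combn(dna, 2)
  dists <- numeric(0)
  for (f in frames) {
    cents <- mol_centroids(traj$frames[, , f], system)
    for (p in seq_len(ncol(pairs))) {
      d <- min_image(cents[pairs[1, p], ] - cents[pairs[2, p], ], traj$box[f, ])
      dists <- c(dists, sqrt(sum(d^2)))
    }
  }
  h <- graphics::hist(dists, breaks = breaks, plot = FALSE)
  list(distances = dists, histogram = h$counts, mids = h$mids, breaks = h$breaks)
}

#' @export
print.cg_clusters <- function(x, ...) {
  cat(sprintf("<cg_clusters %s: %d clusters, sizes [%s]>\n", x$method,
              length(x$sizes), paste(sort(x$sizes, decreasing = TRUE),
                                     collapse = ", ")))
  invisible(x)
}
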