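#' Ashbaugh-Hatch hydrophobicity-scale pair energy
#'
#' The HPS pair potential: inside the Lennard-Jones minimum
#' \eqn{r_{min} = 2^{1/6}\sigma} the energy is \eqn{LJ(r) + (1-\lambda)\epsilon},
#' outside it is \eqn{\lambda\,LJ(r)}; continuous at the branch point where
#' both give \eqn{-\lambda\epsilon}.  With a finite `cutoff` the attractive
#' branch is shifted by \eqn{-\lambda\,LJ(r_c)} so the potential vanishes
#' continuously at the cutoff (the engine default); `cutoff = Inf` gives the
#' unshifted textbook form.
#'
#' @param r Distance (Angstrom), vectorised.
#' @param sigma_ij Pair contact diameter (arithmetic mean of bead sigmas).
#' @param lam_ij Pair stickiness (arithmetic mean of bead lambdas).
#' @param epsilon Well depth (kcal/mol).
#' @param cutoff Truncation distance; `Inf` disables shifting.
#' @return Energy in kcal/mol.
#' @export
hps_pair_energy <- function(r, sigma_ij, lam_ij, epsilon = 0.2, cutoff = Inf) {
  if (any(r <= 0)) stop("singular distance: r must be > 0")
  lj <- function(rr) 4 * epsilon * ((sigma_ij / rr)^12 - (sigma_ij / rr)^6)
  shift <- if (is.finite(cutoff)) lam_ij * lj(cutoff) else 0
  rmin <- 2^(1 / 6) * sigma_ij
  u <- ifelse(r <= rmin,
              lj(r) + (1 - lam_ij) * epsilon - shift,
              lam_ij * lj(r) - shift)
  ifelse(r >= cutoff, 0, u)
}

#' Debye screening length of a monovalent salt solution
#'
#' \eqn{\lambda_D = \sqrt{\epsilon_0\epsilon_r k_B T / (2 N_A e^2 I)}} for a
#' 1:1 electrolyte of ionic strength `I`.
#'
#' @param ionic_strength mol/L (> 0).
#' @param temperature Kelvin.
#' @param dielectric Relative permittivity (78 at 300 K by default).
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength, temperature = 300, dielectric = 78) {
  if (any(ionic_strength <= 0)) {
    stop("ionic strength must be > 0 (disable electrostatics via the scope flag instead)")
  }
  eps0 <- 8.8541878128e-12; kb <- 1.380649e-23
  e <- 1.602176634e-19; na <- 6.02214076e23
  lam_m <- sqrt(eps0 * dielectric * kb * temperature /
                  (2 * na * e^2 * ionic_strength * 1000))
  lam_m * 1e10
}

#' Debye-Hueckel screened electrostatic pair energy
#'
#' \eqn{U = C q_i q_j e^{-r/\lambda_D} / (\epsilon_r r)} with
#' \eqn{C = 332.0637} kcal A/mol/e^2, truncated (and, for finite cutoffs,
#' shifted to zero) at `cutoff`.
#'
#' @param r Distance (Angstrom), vectorised.
#' @param qi,qj Charges in elementary charges.
#' @param ionic_strength mol/L.
#' @param temperature Kelvin.
#' @param dielectric Relative permittivity.
#' @param cutoff Truncation distance; `Inf` disables shifting.
#' @return Energy in kcal/mol.
#' @export
dh_pair_energy <- function(r, qi, qj, ionic_strength = 0.125, temperature = 300,
                           dielectric = 78, cutoff = Inf) {
  if (any(r <= 0)) stop("singular distance: r must be > 0")
  ld <- debye_length(ionic_strength, temperature, dielectric)
  u <- function(rr) cg_constants$coulomb * qi * qj * exp(-rr / ld) / (dielectric * rr)
  shift <- if (is.finite(cutoff)) u(cutoff) else 0
  ifelse(r >= cutoff, 0, u(r) - shift)
}

#' Excluded-volume (WCA) pair energy
#'
#' Purely repulsive r^-12-type potential: the Lennard-Jones potential shifted
#' up by `epsilon` and truncated at its minimum \eqn{2^{1/6}\sigma_{ij}}, so
#' it is zero at and beyond the cutoff, monotonically decreasing below it, and
#' equals `epsilon` at \eqn{r = \sigma_{ij}}.
#'
#' @param r Distance (Angstrom), vectorised.
#' @param sigma_ij Pair contact diameter.
#' @param epsilon Reference repulsion strength at `r = sigma_ij` (kcal/mol).
#' @return Energy in kcal/mol.
#' @export
excluded_volume_energy <- function(r, sigma_ij, epsilon = 0.2) {
  if (any(r <= 0)) stop("singular distance: r must be > 0")
  rc <- 2^(1 / 6) * sigma_ij
  u <- 4 * epsilon * ((sigma_ij / r)^12 - (sigma_ij / r)^6) + epsilon
  ifelse(r >= rc, 0, u)
}

#' Build an elastic network from reference coordinates
#'
#' All pairs within `cutoff` become harmonic restraints
#' \eqn{k (r - r_0)^2} at their reference distance; used to maintain the
#' folded DBD shape and DNA duplex geometry.
#'
#' @param reference_coords n x 3 matrix of reference positions (Angstrom).
#' @param cutoff Pair inclusion cutoff (Angstrom).
#' @param k Spring constant (kcal/mol/A^2).
#' @return Data frame `i`, `j`, `k`, `r0` with `i < j` (1-based local indices).
#' @export
elastic_network_build <- function(reference_coords, cutoff = 9, k = 2) {
  reference_coords <- as.matrix(reference_coords)
  n <- nrow(reference_coords)
  if (n < 2) stop("elastic network needs at least 2 reference coordinates")
  d <- as.matrix(stats::dist(reference_coords))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], k = k, r0 = d[idx])
}

#' Force-field parameter set
#'
#' Collects the nonbonded parameters handed to the engine.  `hps_scope`
#' controls which protein pairs feel the HPS attraction:
#' `"disordered_only"` (both beads disordered; the default, matching the
#' primary setup), `"all_residues"` (the control in which HPS applies to the
#' DBD too), or `"disordered_any"` (at least one bead disordered; the second
#' reading of the ambiguous mixed-pair treatment).  Pairs outside the scope
#' interact by excluded volume.  `electrostatics = FALSE` zeroes all
#' Debye-Hueckel terms (the no-electrostatics control), distinct from any
#' ionic-strength value.
#'
#' @param ionic_strength mol/L.
#' @param temperature Kelvin.
#' @param dielectric Relative permittivity.
#' @param epsilon_hps HPS well depth (kcal/mol).
#' @param epsilon_ev Excluded-volume reference repulsion (kcal/mol).
#' @param hps_cutoff HPS truncation (Angstrom; ~4 sigma).
#' @param dh_cutoff Debye-Hueckel truncation (Angstrom; 50 by default, the
#'   interaction cutoff used throughout the analyses).
#' @param electrostatics Logical flag.
#' @param hps_scope Scope flag, see above.
#' @param nonbonded Master switch; `FALSE` leaves only bonded terms (used by
#'   ideal-chain and free-diffusion checks).
#' @return A list of class `cg_forcefield`.
#' @export
forcefield <- function(ionic_strength = 0.125, temperature = 300, dielectric = 78,
                       epsilon_hps = 0.2, epsilon_ev = 0.2,
                       hps_cutoff = 25, dh_cutoff = 50,
                       electrostatics = TRUE,
                       hps_scope = c("disordered_only", "all_residues", "disordered_any"),
                       nonbonded = TRUE) {
  hps_scope <- match.arg(hps_scope)
  structure(list(
    ionic_strength = ionic_strength, temperature = temperature,
    dielectric = dielectric, epsilon_hps = epsilon_hps, epsilon_ev = epsilon_ev,
    hps_cutoff = hps_cutoff, dh_cutoff = dh_cutoff,
    electrostatics = electrostatics, hps_scope = hps_scope,
    nonbonded = nonbonded,
    debye_length = debye_length(ionic_strength, temperature, dielectric)
  ), class = "cg_forcefield")
}

# flatten system + forcefield into what the C++ kernels expect
pack_system <- function(system, ff, tether = NULL) {
  b <- system$beads
  cls <- ifelse(b$kind == "crowder", 3L,
         ifelse(b$kind == "dna_duplex", 2L,
         ifelse(b$disordered, 0L, 1L)))
  out <- list(
    sigma = b$sigma, lam = b$lam, charge = b$charge, mass = b$mass,
    cls = cls, box = as.numeric(system$box),
    bonds = as.matrix(system$bonds[, c("i", "j"), drop = FALSE]),
    bond_k = as.numeric(system$bonds$k), bond_b0 = as.numeric(system$bonds$b0),
    epairs = as.matrix(system$epairs[, c("i", "j"), drop = FALSE]),
    epair_k = as.numeric(system$epairs$k), epair_r0 = as.numeric(system$epairs$r0)
  )
  storage.mode(out$bonds) <- "integer"
  storage.mode(out$epairs) <- "integer"
  if (!is.null(tether)) {
    out$tether_k <- tether$k
    out$tether_ref <- tether$ref
  }
  out
}

pack_ff <- function(ff) {
  list(epsilon_hps = ff$epsilon_hps, hps_cutoff = ff$hps_cutoff,
       epsilon_ev = ff$epsilon_ev, dielectric = ff$dielectric,
       debye_length = ff$debye_length, dh_cutoff = ff$dh_cutoff,
       electrostatics = ff$electrostatics, nonbonded = ff$nonbonded,
       scope = switch(ff$hps_scope, disordered_only = 0L, all_residues = 1L,
                      disordered_any = 2L))
}

#' Total potential energy and forces of a configuration
#'
#' Evaluates every enabled term (bonds, elastic network, HPS, excluded
#' volume, Debye-Hueckel, tethers) under the minimum-image convention in all
#' three axes.  Forces are exact negative gradients of the returned energy.
#'
#' @param coords n x 3 coordinate matrix (Angstrom, unwrapped).
#' @param system A `cg_system`.
#' @param ff A `cg_forcefield`.
#' @param tether Optional list `k` (per-bead spring constants, 0 = free) and
#'   `ref` (n x 3 anchor coordinates).
#' @return List with `energy`, named `terms`, and `forces` (n x 3,
#'   kcal/mol/A).
#' @export
total_energy_forces <- function(coords, system, ff = forcefield(), tether = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(system$beads))
  .cpp_energy_forces(coords, pack_system(system, ff, tether), pack_ff(ff))
}
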