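#' Default Nanog domain boundaries
#'
#' The three-domain architecture of human Nanog: a charged disordered
#' N-terminal domain, a folded three-helix DNA-binding domain, and a
#' hydrophobic disordered C-terminal domain containing the tryptophan-repeat
#' (WR) region.  Boundaries are configurable; the defaults place the
#' homeodomain at 96-154 so that the hydrophobic repeat block (residues
#' 155-240) falls inside the CTD.
#'
#' @param ntd,dbd,ctd Integer vectors of length 2, 1-based inclusive spans.
#' @return A data frame with columns `name`, `start`, `end`.
#' @export
nanog_domains <- function(ntd = c(1, 95), dbd = c(96, 154), ctd = c(155, 305)) {
  d <- data.frame(name = c("NTD", "DBD", "CTD"),
                  start = c(ntd[1], dbd[1], ctd[1]),
                  end = c(ntd[2], dbd[2], ctd[2]),
                  stringsAsFactors = FALSE)
  if (any(d$start > d$end)) stop("domain spans must have start <= end")
  d
}

#' Find tryptophan-repeat spans in a CTD sequence
#'
#' Scans left to right for non-overlapping 5-residue windows beginning with
#' tryptophan, then keeps tandem clusters of repeats: runs in which successive
#' window starts are at most `max_gap` residues apart beyond the window width,
#' with at least `min_repeats` windows per run.  With the defaults this
#' recovers exactly the eight repeats of the human Nanog WR region while
#' discarding the isolated tryptophan between the homeodomain and the repeat
#' block.  Set `min_repeats = 1, max_gap = Inf` for the plain maximal scan.
#'
#' @param ctd_sequence Amino-acid string (one-letter codes).
#' @param width Window width (5: the repeats are five residues long).
#' @param max_gap Maximum number of residues between consecutive windows for
#'   them to count as the same tandem block.
#' @param min_repeats Minimum windows per tandem block.
#' @return Data frame with columns `start`, `end` (1-based, relative to the
#'   input sequence); zero rows when nothing is found.
#' @export
find_wr_repeats <- function(ctd_sequence, width = 5, max_gap = 5, min_repeats = 2) {
  stopifnot(nchar(ctd_sequence) > 0)
  aa <- strsplit(ctd_sequence, "")[[1]]
  n <- length(aa)
  starts <- integer(0)
  i <- 1
  while (i <= n - width + 1) {
    if (aa[i] == "W") {
      starts <- c(starts, i)
      i <- i + width
    } else {
      i <- i + 1
    }
  }
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # group into tandem blocks
  block <- cumsum(c(1, diff(starts) > width + max_gap))
  keep <- block %in% which(tabulate(block) >= min_repeats)
  starts <- starts[keep]
  data.frame(start = starts, end = starts + width - 1L)
}

aa_codes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
              "F", "P", "S", "T", "W", "Y", "V")

#' Build the coarse-grained topology of a Nanog chain
#'
#' One bead per residue at the C-alpha position.  Variants: `WT` (wild type),
#' `W8A` (the eight WR tryptophans mutated to alanine), `OnlyCTD` (CTD span
#' only), `DeltaDBD` (NTD + CTD with the DBD deleted), and `PhosphoNTD`
#' (serines 52/56/57/65 carry the phosphoserine charge, default -1).
#'
#' @param variant One of `"WT"`, `"W8A"`, `"OnlyCTD"`, `"DeltaDBD"`,
#'   `"PhosphoNTD"`.
#' @param sequence Amino-acid string; defaults to the packaged human Nanog.
#' @param domains Domain boundary data frame from [nanog_domains()].
#' @param params Bead parameter table from [hps_params()].
#' @param wr_spans Optional explicit WR span data frame (`start`, `end`,
#'   full-chain coordinates); overrides the scan.
#' @param phospho_sites Residue indices phosphorylated by `PhosphoNTD`.
#' @return An object of class `cg_chain`: a list with `kind`, `sequence`,
#'   `beads` (data frame: `resid`, `code`, `mass`, `charge`, `sigma`, `lam`,
#'   `domain`, `wr`, `disordered`), `bonds`, `epairs`, `domains`, `wr_spans`,
#'   `ref_coords` (DBD elastic-network reference, NULL when no DBD).
#' @export
build_nanog <- function(variant = c("WT", "W8A", "OnlyCTD", "DeltaDBD", "PhosphoNTD"),
                        sequence = nanog_sequence(),
                        domains = nanog_domains(),
                        params = hps_params(),
                        wr_spans = NULL,
                        phospho_sites = c(52, 56, 57, 65)) {
  variant <- match.arg(variant)
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (!all(aa %in% aa_codes)) {
    stop("unknown residue code(s): ", paste(unique(setdiff(aa, aa_codes)), collapse = ", "))
  }
  if (max(domains$end) != L || min(domains$start) != 1) {
    stop("domain boundaries do not cover the sequence (1..", L, ")")
  }
  ctd <- domains[domains$name == "CTD", ]
  if (is.null(wr_spans)) {
    sc <- find_wr_repeats(substr(sequence, ctd$start, ctd$end))
    wr_spans <- data.frame(start = sc$start + ctd$start - 1L,
                           end = sc$end + ctd$start - 1L)
  }
  if (variant == "W8A") {
    w_in_wr <- unlist(mapply(seq, wr_spans$start, wr_spans$end, SIMPLIFY = FALSE))
    w_pos <- intersect(which(aa == "W"), w_in_wr)
    if (length(w_pos) == 0) stop("W8A variant requested but no WR tryptophan found")
    aa[w_pos] <- "A"
  }
  code <- aa
  if (variant == "PhosphoNTD") {
    if (!all(aa[phospho_sites] == "S")) {
      stop("phospho sites must be serines in the supplied sequence")
    }
    code[phospho_sites] <- "X"
  }
  keep <- seq_len(L)
  if (variant == "OnlyCTD") keep <- seq(ctd$start, ctd$end)
  if (variant == "DeltaDBD") {
    dbd <- domains[domains$name == "DBD", ]
    keep <- setdiff(seq_len(L), seq(dbd$start, dbd$end))
  }

  dom_of <- character(L)
  for (k in seq_len(nrow(domains))) {
    dom_of[seq(domains$start[k], domains$end[k])] <- domains$name[k]
  }
  wr_of <- rep(FALSE, L)
  for (k in seq_len(nrow(wr_spans))) {
    wr_of[seq(wr_spans$start[k], wr_spans$end[k])] <- TRUE
  }

  code <- code[keep]
  p <- params[code, ]
  beads <- data.frame(resid = keep, code = code,
                      mass = p$mass, charge = p$charge,
                      sigma = p$sigma, lam = p$lambda,
                      domain = dom_of[keep], wr = wr_of[keep],
                      disordered = dom_of[keep] != "DBD",
                      stringsAsFactors = FALSE)
  n <- nrow(beads)
  bonds <- if (n > 1) {
    data.frame(i = seq_len(n - 1), j = seq(2, n), k = 5, b0 = 3.8)
  } else {
    data.frame(i = integer(0), j = integer(0), k = numeric(0), b0 = numeric(0))
  }
  # elastic network over the folded DBD, from an idealized (synthetic)
  # three-helix-bundle reference
  epairs <- data.frame(i = integer(0), j = integer(0), k = numeric(0), r0 = numeric(0))
  ref <- NULL
  dbd_local <- which(beads$domain == "DBD")
  if (length(dbd_local) >= 2) {
    ref <- dbd_reference_coords(length(dbd_local))
    en <- elastic_network_build(ref, cutoff = 9, k = 2)
    if (nrow(en) > 0) {
      epairs <- data.frame(i = dbd_local[en$i], j = dbd_local[en$j],
                           k = en$k, r0 = en$r0)
    }
  }
  structure(list(kind = "protein", variant = variant,
                 sequence = paste(code, collapse = ""),
                 beads = beads, bonds = bonds, epairs = epairs,
                 domains = domains, wr_spans = wr_spans,
                 ref_coords = ref),
            class = "cg_chain")
}

#' Net charge of a chain topology
#'
#' Sum of bead charges under the assignment Asp/Glu -1, Lys/Arg +1, His 0,
#' phosphoserine -1 (or the configured phosphate charge), DNA phosphates at
#' the configured phosphate charge.
#'
#' @param topology A `cg_chain`.
#' @return Signed total charge in elementary charges.
#' @export
net_charge <- function(topology) {
  sum(topology$beads$charge)
}

#' Idealized three-helix bundle reference for the DBD (synthetic)
#'
#' Generates C-alpha coordinates for a compact three-helix bundle: residues
#' split into three alpha-helical segments (rise 1.5 A, 3.6 residues/turn,
#' radius 2.3 A) laid antiparallel on a triangular prism 10 A apart.  Used
#' only to define elastic-network reference distances; it is a synthetic
#' stand-in for a folded homeodomain structure, adequate because condensate
#' behaviour is insensitive to DBD interaction details.
#'
#' @param n_res Number of DBD residues.
#' @return `n_res` x 3 coordinate matrix.
#' @export
dbd_reference_coords <- function(n_res) {
  stopifnot(n_res >= 2)
  per <- ceiling(n_res / 3)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8.66, 0))
  coords <- matrix(0, n_res, 3)
  for (i in seq_len(n_res)) {
    h <- (i - 1) %/% per          # helix index 0..2
    k <- (i - 1) %% per           # position along helix
    kk <- if (h %% 2 == 0) k else per - 1 - k  # antiparallel
    ang <- 2 * pi * k / 3.6
    coords[i, ] <- centers[h + 1, ] +
      c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * kk)
  }
  coords
}

dna_site_params <- function(phosphate_charge = -0.6) {
  data.frame(code = c("DP", "DS", "DB"),
             mass = c(94.97, 83.11, 150.0),
             charge = c(phosphate_charge, 0, 0),
             sigma = c(4.5, 6.2, 5.0),
             lam = 0,
             stringsAsFactors = FALSE)
}

#' Build a coarse-grained DNA duplex
#'
#' Three sites per nucleotide (phosphate, sugar, base); the 5'-terminal
#' nucleotide of each strand lacks its phosphate, so a duplex has
#' `6 n_bp - 2` beads.  B-form-like geometry (rise 3.4 A, 10.5 bp/turn) is
#' generated from an ideal helix and preserved by backbone bonds plus an
#' intra-duplex elastic network (the duplex is never meant to melt).
#' Phosphate sites carry `phosphate_charge`.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param sequence Base sequence of strand 1; defaults to poly-CG.
#' @param phosphate_charge Charge per phosphate site (default -0.6, the
#'   reduced charge conventional for screened three-site DNA models).
#' @return A `cg_chain` of kind `dna_duplex` with reference coordinates.
#' @export
build_dna_duplex <- function(n_bp, sequence = NULL, phosphate_charge = -0.6) {
  if (n_bp < 1) stop("n_bp must be >= 1")
  if (is.null(sequence)) {
    sequence <- paste(rep(c("C", "G"), length.out = n_bp), collapse = "")
  }
  p <- dna_site_params(phosphate_charge)
  rownames(p) <- p$code
  rise <- 3.4; twist <- 2 * pi / 10.5
  r_p <- 8.9; r_s <- 6.9; r_b <- 2.5
  build_strand <- function(antisense) {
    beads <- list(); coords <- list()
    for (nt in seq_len(n_bp)) {
      idx <- if (!antisense) nt else n_bp + 1 - nt
      ang <- idx * twist + if (antisense) 2.4 else 0
      z <- idx * rise
      sites <- c(if (nt > 1) "DP", "DS", "DB")
      rr <- c(DP = r_p, DS = r_s, DB = r_b)
      off <- c(DP = -0.35, DS = 0, DB = 0)
      for (s in sites) {
        a <- ang + off[[s]]
        beads[[length(beads) + 1]] <- data.frame(
          resid = nt, code = s, mass = p[s, "mass"], charge = p[s, "charge"],
          sigma = p[s, "sigma"], lam = 0, domain = "DNA", wr = FALSE,
          disordered = FALSE, stringsAsFactors = FALSE)
        coords[[length(coords) + 1]] <- c(rr[[s]] * cos(a), rr[[s]] * sin(a), z)
      }
    }
    list(beads = do.call(rbind, beads), coords = do.call(rbind, coords))
  }
  s1 <- build_strand(FALSE); s2 <- build_strand(TRUE)
  beads <- rbind(s1$beads, s2$beads)
  ref <- rbind(s1$coords, s2$coords)
  n <- nrow(beads)
  # backbone bonds within each strand at reference distances
  bond_rows <- list()
  offset <- 0
  for (strand in list(s1, s2)) {
    ns <- nrow(strand$beads)
    for (i in seq_len(ns - 1)) {
      a <- offset + i; b <- offset + i + 1
      bond_rows[[length(bond_rows) + 1]] <-
        data.frame(i = a, j = b, k = 20,
                   b0 = sqrt(sum((ref[a, ] - ref[b, ])^2)))
    }
    offset <- offset + ns
  }
  bonds <- do.call(rbind, bond_rows)
  en <- elastic_network_build(ref, cutoff = 12, k = 5)
  # drop pairs already bonded
  key_b <- paste(bonds$i, bonds$j)
  en <- en[!(paste(en$i, en$j) %in% key_b), ]
  structure(list(kind = "dna_duplex", variant = "polyCG",
                 sequence = sequence, beads = beads,
                 bonds = bonds,
                 epairs = data.frame(i = en$i, j = en$j, k = en$k, r0 = en$r0),
                 domains = NULL, wr_spans = NULL,
                 ref_coords = ref),
            class = "cg_chain")
}

#' Crowder count and radius for an ideal-sphere crowding agent
#'
#' Mass balance at solution density 1 g/cm^3:
#' `count = round(0.01 wt% * V_box * N_A / MW)`; the hard-sphere radius is
#' derived from the radius of gyration as `R = round(sqrt(5/3) Rg)` (the
#' uniform-sphere relation `Rg^2 = 3/5 R^2`).
#'
#' @param weight_percent Weight percent of crowder (>= 0).
#' @param molecular_weight g/mol (PEG8000: 8000).
#' @param box Box side lengths in Angstrom, length 3.
#' @param rg Radius of gyration in Angstrom.
#' @return List with `count` and `radius` (Angstrom).
#' @export
build_crowders <- function(weight_percent, molecular_weight = 8000,
                           box = c(300, 300, 3000), rg = 15) {
  if (weight_percent < 0 || molecular_weight <= 0 || any(box <= 0) || rg <= 0) {
    stop("crowder parameters must be non-negative (sizes positive)")
  }
  v_cm3 <- prod(box) * 1e-24
  count <- round(0.01 * weight_percent * v_cm3 / molecular_weight *
                   cg_constants$avogadro)
  list(count = as.integer(count), radius = round(sqrt(5 / 3) * rg))
}

crowder_chain <- function(radius) {
  structure(list(kind = "crowder", variant = "sphere", sequence = "",
                 beads = data.frame(resid = 1L, code = "CR", mass = 8000,
                                    charge = 0, sigma = 2 * radius, lam = 0,
                                    domain = "CR", wr = FALSE,
                                    disordered = FALSE,
                                    stringsAsFactors = FALSE),
                 bonds = data.frame(i = integer(0), j = integer(0),
                                    k = numeric(0), b0 = numeric(0)),
                 epairs = data.frame(i = integer(0), j = integer(0),
                                     k = numeric(0), r0 = numeric(0)),
                 domains = NULL, wr_spans = NULL, ref_coords = NULL),
            class = "cg_chain")
}

#' Assemble a periodic simulation system from chain topologies
#'
#' Replicates chain topologies with copy counts into one flat bead table with
#' global indices, optionally adding crowder spheres.
#'
#' @param chains List of entries `list(topology = <cg_chain>, count = <int>)`.
#' @param box Box side lengths (Lx, Ly, Lz) in Angstrom.
#' @param crowders Optional list with `count` and `radius` as returned by
#'   [build_crowders()].
#' @return An object of class `cg_system`: flat `beads` (with `mol` and
#'   `chain` columns), global `bonds` and `epairs`, the `box`, and the chain
#'   list.
#' @export
build_system <- function(chains, box = c(300, 300, 3000), crowders = NULL) {
  if (any(box <= 0)) stop("box sides must be positive")
  if (inherits(chains, "cg_chain")) chains <- list(list(topology = chains, count = 1))
  entries <- list()
  for (ch in chains) {
    for (k in seq_len(ch$count)) entries[[length(entries) + 1]] <- ch$topology
  }
  if (!is.null(crowders) && crowders$count > 0) {
    cr <- crowder_chain(crowders$radius)
    for (k in seq_len(crowders$count)) entries[[length(entries) + 1]] <- cr
  }
  beads <- list(); bonds <- list(); epairs <- list()
  offset <- 0
  for (m in seq_along(entries)) {
    tp <- entries[[m]]
    b <- tp$beads
    b$mol <- m
    b$chain <- tp$variant
    b$kind <- tp$kind
    beads[[m]] <- b
    if (nrow(tp$bonds) > 0) {
      bb <- tp$bonds; bb$i <- bb$i + offset; bb$j <- bb$j + offset
      bonds[[length(bonds) + 1]] <- bb
    }
    if (nrow(tp$epairs) > 0) {
      ee <- tp$epairs; ee$i <- ee$i + offset; ee$j <- ee$j + offset
      epairs[[length(epairs) + 1]] <- ee
    }
    offset <- offset + nrow(b)
  }
  structure(list(
    beads = do.call(rbind, beads),
    bonds = if (length(bonds)) do.call(rbind, bonds) else
      data.frame(i = integer(0), j = integer(0), k = numeric(0), b0 = numeric(0)),
    epairs = if (length(epairs)) do.call(rbind, epairs) else
      data.frame(i = integer(0), j = integer(0), k = numeric(0), r0 = numeric(0)),
    box = box,
    molecules = entries
  ), class = "cg_system")
}

#' Average molar concentration of protein chains in the box
#'
#' @param n_chains Number of molecules.
#' @param box Box side lengths in Angstrom.
#' @return Concentration in mol/L.
#' @export
average_concentration <- function(n_chains, box = c(300, 300, 3000)) {
  v_l <- prod(box) * 1e-27
  n_chains / (cg_constants$avogadro * v_l)
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("<cg_chain %s/%s: %d beads, net charge %+g>\n",
              x$kind, x$variant, nrow(x$beads), net_charge(x)))
  invisible(x)
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system: %d molecules, %d beads, box %g x %g x %g A>\n",
              length(x$molecules), nrow(x$beads), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}
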