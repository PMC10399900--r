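#' Physical constants used throughout the package
#'
#' Energies are in kcal/mol, lengths in Angstrom, masses in amu, charges in
#' elementary charges.  The derived time unit is
#' \eqn{\sqrt{\mathrm{amu}\,\mathring{A}^2/(\mathrm{kcal/mol})} \approx 48.89}
#' fs; all step counts and diffusion coefficients are reported in these model
#' units.
#' @format A named list: `kB` (kcal/mol/K), `coulomb` (kcal Angstrom/mol/e^2),
#'   `avogadro` (1/mol), `time_fs` (fs per model time unit).
#' @export
cg_constants <- list(
  kB = 0.0019872041,
  coulomb = 332.0637,
  avogadro = 6.02214076e23,
  time_fs = 48.8882
)

#' Per-residue bead parameters of the hydrophobicity-scale model
#'
#' Reads the packaged parameter table (mass, charge, contact diameter sigma
#' and stickiness lambda per one-letter residue code).  The lambda column is a
#' Tesei-et-al-derived calibration of the hydrophobicity scale; `X` denotes
#' phosphoserine, which keeps serine's sigma and lambda and carries charge
#' -1.0 by default.
#'
#' @param path Optional path to an alternative parameter TSV with columns
#'   `code`, `mass`, `charge`, `sigma`, `lambda` (the table is swappable).
#' @param phospho_charge Charge assigned to phosphoserine (`-1` default; `-2`
#'   represents the doubly ionised phosphate).
#' @return A data frame keyed by `code`.
#' @export
hps_params <- function(path = NULL, phospho_charge = -1) {
  if (is.null(path)) {
    path <- system.file("extdata", "hps_params.tsv", package = "nanogmicelle")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("code", "mass", "charge", "sigma", "lambda") %in% names(tab)))
  if (any(tab$sigma <= 0)) stop("sigma must be positive")
  aa <- setdiff(tab$code, "X")
  if (any(tab$lambda[tab$code %in% aa] < 0 | tab$lambda[tab$code %in% aa] > 1)) {
    stop("lambda must lie in [0, 1] for amino-acid types")
  }
  tab$charge[tab$code == "X"] <- phospho_charge
  rownames(tab) <- tab$code
  tab
}

#' The packaged human Nanog sequence
#'
#' Returns the 305-residue full-length human Nanog amino-acid sequence shipped
#' with the package.  On load it is validated against the three facts the
#' model depends on: length 305, net charge -1 (Asp/Glu -1, Lys/Arg +1, His
#' 0), and eight tryptophan repeats in the C-terminal domain.
#'
#' @param path Optional FASTA file with a user-supplied sequence.  A sequence
#'   whose WR scan does not find 8 repeats is accepted with a warning.
#' @return A single character string of one-letter codes.
#' @export
nanog_sequence <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nanog_human.fasta", package = "nanogmicelle")
  }
  fa <- read_fasta(path)
  seq <- fa[[1]]
  wr <- find_wr_repeats(substr(seq, 155, nchar(seq)))
  if (nrow(wr) != 8) {
    warning(sprintf("WR scan found %d repeats in the CTD (expected 8 for WT Nanog)",
                    nrow(wr)))
  }
  seq
}
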