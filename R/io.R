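#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (one string each).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  seqs <- lapply(split(lines[!hdr], id[!hdr]), function(x) {
    toupper(gsub("[[:space:]]", "", paste(x, collapse = "")))
  })
  seqs <- seqs[order(as.integer(names(seqs)))]
  names(seqs) <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  seqs
}

#' Read a simulation/analysis configuration from YAML
#'
#' Resolves a YAML file into a [sim_config()], an [analysis_params()] list
#' and a variant specification, filling defaults for absent keys and
#' rejecting unknown ones.
#'
#' @param path YAML file.  Recognised top-level keys: `simulation` (fields of
#'   [sim_config()]), `analysis` (fields of [analysis_params()]), `variant`
#'   (a [build_nanog()] variant name).
#' @return List with `config`, `analysis`, `variant`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known_top <- c("simulation", "analysis", "variant")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  sim_args <- raw$simulation
  if (!is.null(sim_args)) {
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) stop("config error: unknown simulation key(s): ",
                          paste(bad, collapse = ", "))
    if (!is.null(sim_args$box)) sim_args$box <- as.numeric(sim_args$box)
  }
  ana_args <- raw$analysis
  if (!is.null(ana_args)) {
    bad <- setdiff(names(ana_args), names(formals(analysis_params)))
    if (length(bad)) stop("config error: unknown analysis key(s): ",
                          paste(bad, collapse = ", "))
  }
  list(config = do.call(sim_config, if (is.null(sim_args)) list() else sim_args),
       analysis = do.call(analysis_params,
                          if (is.null(ana_args)) list() else ana_args),
       variant = if (is.null(raw$variant)) "WT" else raw$variant)
}

#' Write a configuration back to YAML
#'
#' Round-trips with [read_config()].
#'
#' @param cfg List as returned by [read_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  sim <- unclass(cfg$config)
  ana <- unclass(cfg$analysis)
  ana <- ana[!vapply(ana, is.null, TRUE)]
  yaml::write_yaml(list(simulation = sim, analysis = ana,
                        variant = cfg$variant), path)
  invisible(path)
}

pdb_chain_ids <- c(LETTERS, letters, as.character(0:9))

#' Write a bead topology as PDB plus a JSON sidecar
#'
#' One CA-like ATOM record per bead with chain identifiers cycling per
#' molecule, readable by standard structure tools; the sidecar records
#' per-bead charge, stickiness and domain/WR annotation, which PDB cannot
#' carry.
#'
#' @param system A `cg_system`.
#' @param coords n x 3 coordinates to write (wrapped into the box).
#' @param prefix Output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>.json`.
#' @return The PDB path, invisibly.
#' @export
write_topology_pdb <- function(system, coords, prefix) {
  b <- system$beads
  coords <- wrap_coords(as.matrix(coords), system$box)
  if (nrow(coords) != nrow(b)) stop("I/O error: bead count mismatch")
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL", X = "SEP", DP = "DP", DS = "DS", DB = "DB",
           CR = "CRW")
  res <- unname(aa3[b$code]); res[is.na(res)] <- "UNK"
  ch <- pdb_chain_ids[(b$mol - 1) %% length(pdb_chain_ids) + 1]
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(b)) %% 100000, res, ch, b$resid %% 10000,
    coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       system$box[1], system$box[2], system$box[3]),
               lines, "END"), paste0(prefix, ".pdb"))
  sidecar <- list(
    n_beads = nrow(b),
    box = as.numeric(system$box),
    beads = list(mol = b$mol, resid = b$resid, code = b$code,
                 charge = b$charge, lambda = b$lam, domain = b$domain,
                 wr = b$wr))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".pdb"))
}

#' Write a trajectory as plain-text TSV
#'
#' Long-format table (`frame`, `step`, `bead`, `x`, `y`, `z`) plus a JSON
#' header with box sides per frame; loss-free at the printed precision and
#' readable by any table tool.
#'
#' @param traj A `cg_trajectory`.
#' @param prefix Output path prefix; writes `<prefix>.traj.tsv` and
#'   `<prefix>.meta.json`.
#' @return The TSV path, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  nf <- n_frames(traj)
  n <- dim(traj$frames)[1]
  tab <- data.frame(
    frame = rep(seq_len(nf), each = n),
    step = rep(traj$steps, each = n),
    bead = rep(seq_len(n), nf),
    x = as.vector(traj$frames[, 1, ]),
    y = as.vector(traj$frames[, 2, ]),
    z = as.vector(traj$frames[, 3, ]))
  utils::write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
                     paste0(prefix, ".traj.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_beads = n, n_frames = nf,
                            steps = traj$steps,
                            box = lapply(seq_len(nf), function(f) traj$box[f, ]),
                            seed = traj$seed),
                       paste0(prefix, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".traj.tsv"))
}

#' Read a TSV trajectory written by [write_trajectory()]
#'
#' @param prefix Path prefix used at write time.
#' @param system The `cg_system` the coordinates belong to.
#' @return A `cg_trajectory`.
#' @export
read_trajectory <- function(prefix, system) {
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"), simplifyVector = TRUE)
  tab <- utils::read.delim(paste0(prefix, ".traj.tsv"))
  if (meta$n_beads != nrow(system$beads)) stop("I/O error: bead count mismatch")
  frames <- array(0, c(meta$n_beads, 3, meta$n_frames))
  ord <- order(tab$frame, tab$bead)
  tab <- tab[ord, ]
  frames[, 1, ] <- tab$x; frames[, 2, ] <- tab$y; frames[, 3, ] <- tab$z
  traj <- as_cg_trajectory(frames, system, steps = unique(tab$step))
  traj$box <- matrix(unlist(meta$box), meta$n_frames, 3, byrow = TRUE)
  traj$seed <- meta$seed
  traj
}

#' Write a run manifest
#'
#' Records everything needed to re-run a trajectory bit-identically: the
#' resolved configuration and its MD5 hash, the seed, package version, and
#' the output paths.  Written atomically (temp file + rename).
#'
#' @param traj A `cg_trajectory` from [langevin_run()] or
#'   [shrink_protocol()].
#' @param outputs Character vector of output paths covered by the manifest.
#' @param path Manifest destination (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(traj, outputs, path) {
  cfg <- unclass(traj$config)
  tmp_cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp_cfg, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp_cfg))
  unlink(tmp_cfg)
  manifest <- list(
    config = cfg, config_md5 = hash, seed = traj$seed,
    package_version = as.character(utils::packageVersion("nanogmicelle")),
    n_frames = n_frames(traj), final_step = max(traj$steps),
    outputs = outputs, written = format(Sys.time(), tz = "UTC"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}
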