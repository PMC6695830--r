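#' Read a PDB structure into an atom table
#'
#' Parses ATOM/HETATM records (via bio3d) and assigns masses and van der
#' Waals radii from the built-in element table. Records other than
#' ATOM/HETATM are ignored. Malformed coordinate fields raise a parse error
#' naming the offending line.
#'
#' @param path PDB file path.
#' @return An [atom_records()] table.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    xyz <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("parse error at line ", i, ": malformed coordinate field")
  }
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  el <- ifelse(!is.na(a$elesy) & nzchar(trimws(a$elesy)),
               trimws(a$elesy), guess_element(a$elety))
  atom_records(serial = a$eleno, name = trimws(a$elety), resname = a$resid,
               resid = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
               x = a$x, y = a$y, z = a$z,
               mass = element_mass(el), vdw = element_vdw(el))
}

#' Write an atom table as PDB
#'
#' @param atoms an [atom_records()] table.
#' @param path output file path.
#' @export
write_pdb <- function(atoms, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(atom_xyz(atoms))),
                   type = rep("ATOM", nrow(atoms)),
                   eleno = atoms$serial, elety = atoms$name,
                   resid = atoms$resname, resno = atoms$resid,
                   chain = atoms$chain)
  invisible(path)
}

#' Write a trajectory in XYZ format
#'
#' Each frame: an atom-count line, a comment line `t=<ps> window=<idx>`,
#' then one `name x y z` line per atom (3 decimals). A JSON sidecar
#' (`<path>.json`) maps each frame to its time, supervision window index
#' and accepted flag.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param sidecar write the JSON frame-provenance sidecar.
#' @export
write_xyz_traj <- function(traj, path, sidecar = TRUE) {
  con <- file(path, "w"); on.exit(close(con))
  nm <- traj$topology$name
  for (k in seq_len(n_frames(traj))) {
    w <- traj$window[k]
    cat(nrow(traj$topology), "\n",
        sprintf("t=%.6g window=%s", traj$times[k],
                if (is.na(w)) "NA" else w), "\n",
        sep = "", file = con)
    fr <- matrix(traj$coords[, , k], ncol = 3)
    writeLines(sprintf("%-4s %10.3f %10.3f %10.3f", nm, fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  if (sidecar) {
    jsonlite::write_json(
      data.frame(frame = seq_along(traj$times), time_ps = traj$times,
                 window_index = traj$window,
                 accepted = rep(TRUE, length(traj$times))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz_traj()] (or plain XYZ).
#' @param topology optional [atom_records()] table; when omitted a minimal
#'   topology is reconstructed from the atom names of the first frame.
#' @return A [trajectory()] (0-frame input yields an empty trajectory).
#' @export
read_xyz_traj <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  i <- 1; frame <- 0
  coords <- list(); times <- numeric(0); window <- integer(0); names1 <- NULL
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    frame <- frame + 1
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("format error at frame ", frame, ": bad atom count")
    if (i + 1 + nat > length(lines))
      stop("format error at frame ", frame, ": truncated frame")
    cm <- lines[i + 1]
    tm <- suppressWarnings(as.numeric(sub(".*t=([-0-9.eE+]+).*", "\\1", cm)))
    w <- sub(".*window=([^ ]+).*", "\\1", cm)
    body <- lines[i + 1 + seq_len(nat)]
    tok <- strsplit(trimws(body), "[[:space:]]+")
    nm <- vapply(tok, `[`, "", 1)
    xyz <- t(vapply(tok, function(s) as.numeric(s[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("format error at frame ", frame, ": bad coordinates")
    if (frame == 1) names1 <- nm
    else if (nat != nrow(coords[[1]]))
      stop("format error at frame ", frame, ": atom-count mismatch")
    coords[[frame]] <- xyz
    times <- c(times, if (is.na(tm)) frame else tm)
    window <- c(window, suppressWarnings(as.integer(w)))
    i <- i + 2 + nat
  }
  if (frame == 0) {
    topo <- topology %||% atom_records(integer(0), character(0), character(0),
                                       integer(0), character(0),
                                       numeric(0), numeric(0), numeric(0))
    return(trajectory(topo, array(0, c(nrow(topo), 3, 0)), numeric(0)))
  }
  topo <- topology %||% atom_records(seq_along(names1), names1, "UNK",
                                     seq_along(names1), "A",
                                     coords[[1]][, 1], coords[[1]][, 2],
                                     coords[[1]][, 3])
  arr <- array(NA_real_, c(nrow(coords[[1]]), 3, frame))
  for (k in seq_len(frame)) arr[, , k] <- coords[[k]]
  trajectory(topo, arr, times, window = window)
}

#' Write a potential specification as YAML
#'
#' @param spec a [potential_spec()].
#' @param path output path.
#' @export
write_potential_yaml <- function(spec, path) {
  yaml::write_yaml(list(
    wells = lapply(seq_len(nrow(spec$wells)), function(i) as.list(spec$wells[i, ])),
    bead_eps = spec$eps, bead_sigma = spec$sigma,
    dielectric = spec$dielectric,
    bead_charge = spec$bead_charge), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Sections `engine` and `supervision` are passed to [engine_config()] and
#' [supervision_config()]; a `system` section configures
#' [build_receptor_model()] (`source: generated`) or names a PDB file
#' (`source: pdb`, `path:`).
#'
#' @param path YAML file.
#' @return List with `system_args`, `engine`, `supervision`, `analysis`,
#'   `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  sys <- cfg$system %||% list(source = "generated")
  if (identical(sys$source, "pdb") && !file.exists(sys$path))
    stop("configured PDB path does not exist: ", sys$path)
  list(system_args = sys,
       engine = do.call(engine_config, cfg$engine %||% list()),
       supervision = do.call(supervision_config, cfg$supervision %||% list()),
       analysis = cfg$analysis %||% list(),
       output_dir = cfg$output_dir %||% ".")
}

# Machine-readable run manifest sufficient to re-execute bit-identically.
write_manifest <- function(path, command, args, seed) {
  jsonlite::write_json(list(command = command, arguments = args, seed = seed,
                            parameter_hash = digest_args(c(args, seed))),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

digest_args <- function(x) {
  s <- paste(deparse(x), collapse = "")
  # small rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
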