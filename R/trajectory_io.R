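#' Read a PDB file as a structure or trajectory
#'
#' Single-MODEL files (or files without MODEL records) yield a
#' [structure3d()]; multi-MODEL files with identical atom lists yield a
#' [trajectory3d()] with unit-spaced times (1 ps) unless `times` is given.
#' Parsing is delegated to \pkg{bio3d}; this wrapper enforces the toolkit's
#' contracts: insertion codes are rejected, alternate locations other than
#' blank/'A' are dropped with a warning (crystal structures routinely carry
#' altLocs), and MODELs with differing atom sets are a format error naming
#' the first mismatching atom.
#'
#' @param path PDB file path.
#' @param times optional per-frame times in ps for multi-model files.
#' @return a `structure3d` or `trajectory3d`.
#' @export
read_pdb <- function(path, times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_lines)) stop("no ATOM records in ", path)

  # Validate MODEL blocks before handing to the parser, so mismatched
  # models produce a diagnosable error instead of a scrambled matrix.
  model_starts <- grep("^MODEL", lines)
  n_models <- max(1L, length(model_starts))
  if (n_models > 1L) {
    ident <- function(block) substr(lines[block][grepl("^(ATOM  |HETATM)", lines[block])], 13, 27)
    ends <- c(model_starts[-1] - 1L, length(lines))
    ids <- lapply(seq_along(model_starts),
                  function(k) ident(model_starts[k]:ends[k]))
    for (k in seq_along(ids)[-1]) {
      if (length(ids[[k]]) != length(ids[[1]]) || any(ids[[k]] != ids[[1]])) {
        j <- which(ids[[k]] != ids[[1]][seq_along(ids[[k]])])[1]
        if (is.na(j)) j <- min(length(ids[[k]]), length(ids[[1]])) + 1L
        stop(sprintf("MODEL %d atom list differs from MODEL 1 at atom %d: '%s' vs '%s'",
                     k, j, trimws(ids[[k]][j])[1], trimws(ids[[1]][j])[1]))
      }
    }
  }

  pdb <- bio3d::read.pdb(path, multi = n_models > 1L, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported (residue ",
         at$resno[which(!is.na(at$insert) & nzchar(at$insert))[1]], ")")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    warning(sum(!keep), " alternate-location atoms (altLoc != 'A') dropped")
  }
  at$chain[is.na(at$chain)] <- ""
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy)))) {
    elesy <- substr(trimws(at$elety), 1, 1)  # fall back to atom-name prefix
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, elesy = trimws(elesy),
                      stringsAsFactors = FALSE)
  xyz_all <- pdb$xyz  # 1 or n_models rows of 3N
  if (n_models == 1L) {
    s <- structure3d(atoms[keep, , drop = FALSE],
                     matrix(xyz_all[1, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE],
                     title = basename(path))
    return(s)
  }
  coords <- array(NA_real_, c(n_models, sum(keep), 3L))
  for (f in seq_len(n_models)) {
    coords[f, , ] <- matrix(xyz_all[f, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
  }
  topo <- structure3d(atoms[keep, , drop = FALSE], coords[1, , ],
                      title = basename(path))
  if (is.null(times)) times <- seq_len(n_models) - 1
  trajectory3d(topo, coords, times = times)
}

# one formatted ATOM/HETATM line per atom; wwPDB v3.3 columns
format_pdb_lines <- function(atoms, xyz) {
  std_aa <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
  rec <- ifelse(atoms$resid %in% std_aa, "ATOM  ", "HETATM")
  name <- vapply(seq_len(nrow(atoms)), function(i) {
    nm <- atoms$elety[i]
    if (nchar(nm) >= 4L) sprintf("%-4s", substr(nm, 1, 4))
    else sprintf(" %-3s", nm)  # 1-char elements start in column 14
  }, character(1))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, seq_len(nrow(atoms)) %% 100000L, name, atoms$resid,
          substr(atoms$chain, 1, 1), atoms$resno,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          sprintf("%2s", substr(atoms$elesy, 1, 2)))
}

#' Write structures to a (possibly multi-model) PDB file
#'
#' @param x a `structure3d`, a `trajectory3d`, or a list of `structure3d`
#'   objects sharing one atom table (written as sequential MODELs).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structures <- function(x, path) {
  if (inherits(x, "structure3d")) {
    out <- c(sprintf("TITLE     %s", x$title),
             format_pdb_lines(x$atoms, x$xyz), "END")
    writeLines(out, path)
    return(invisible(path))
  }
  if (inherits(x, "trajectory3d")) {
    frames <- lapply(seq_len(n_frames(x)), function(i) frame_xyz(x, i))
    atoms <- x$topology$atoms
    title <- x$topology$title
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "structure3d"))) {
    atoms <- x[[1]]$atoms
    frames <- lapply(x, `[[`, "xyz")
    title <- x[[1]]$title
  } else stop("x must be a structure3d, trajectory3d, or list of structure3d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", title), con)
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(format_pdb_lines(atoms, frames[[f]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a DCD trajectory
#'
#' Coordinates are read with \pkg{bio3d}; frame times are computed from
#' `step_fs` and `save_interval_steps` (DCD headers are unreliable, so the
#' time axis is always user-controlled; the defaults are a 1.5 fs timestep
#' saved every 5000 steps, i.e. 7.5 ps frames).
#'
#' @param path DCD file path.
#' @param topology `structure3d` whose atom count must match the file.
#' @param step_fs,save_interval_steps time-axis metadata.
#' @param times optional explicit frame times (ps), overriding the metadata.
#' @return a `trajectory3d`.
#' @export
read_dcd <- function(path, topology, step_fs = 1.5, save_interval_steps = 5000L,
                     times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(topology, "structure3d"))
  if (is.na(file.size(path)) || file.size(path) < 276)
    stop("no frames in DCD file ", path)
  xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                  error = function(e) stop("failed to read DCD '", path, "': ",
                                           conditionMessage(e)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 1L) stop("no frames in DCD file ", path)
  na_file <- ncol(xyz) / 3L
  if (na_file != nrow(topology$atoms))
    stop("DCD atom count (", na_file, ") does not match topology (",
         nrow(topology$atoms), ")")
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, na_file, 3L))
  for (f in seq_len(nf)) coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory3d(topology, coords, times = times,
               step_fs = step_fs, save_interval_steps = save_interval_steps)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Single-precision binary DCD (the format's native precision, ~1e-4 A).
#'
#' @param traj a `trajectory3d`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory3d"))
  nf <- n_frames(traj); na <- n_atoms(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf                       # frames in file
  icntrl[2] <- 0L                       # first step
  icntrl[3] <- traj$save_interval_steps # save interval
  icntrl[4] <- nf * traj$save_interval_steps
  icntrl[20] <- 24L                     # CHARMM version flag
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(as.numeric(traj$step_fs), con, size = 4)  # delta (informational)
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4); writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "nbdtraj trajectory"), con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(as.integer(na), con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      writeBin(as.integer(4L * na), con, size = 4)
      writeBin(as.numeric(traj$coords[f, , k]), con, size = 4)
      writeBin(as.integer(4L * na), con, size = 4)
    }
  }
  invisible(path)
}

#' Simulation time axis from step counts
#'
#' @param n_steps number of integration steps.
#' @param step_fs integration timestep in fs.
#' @param save_interval_steps steps between saved frames.
#' @return list with `total_ns` (simulated time) and `frame_interval_ps`
#'   (time between saved frames).
#' @examples
#' time_axis(150e6, 1.5, 5000)  # 225 ns total, 7.5 ps between frames
#' @export
time_axis <- function(n_steps, step_fs, save_interval_steps) {
  if (any(c(n_steps, step_fs, save_interval_steps) <= 0))
    stop("all time-axis inputs must be positive")
  list(total_ns = n_steps * step_fs * 1e-6,
       frame_interval_ps = save_interval_steps * step_fs * 1e-3)
}

#' Subsample a trajectory at a coarser time interval
#'
#' Keeps the frames whose time lies within half a native frame spacing of a
#' multiple of `interval_ps`; frame 1 (t = times[1]) is always kept. Times
#' are preserved, so subsampling is idempotent at the same interval.
#'
#' @param traj a `trajectory3d`.
#' @param interval_ps target interval in ps, at least the native spacing.
#' @return a `trajectory3d` with a subset of frames.
#' @export
subsample <- function(traj, interval_ps) {
  nf <- n_frames(traj)
  if (nf == 1L) return(traj)
  dt <- stats::median(diff(traj$times))
  if (interval_ps < dt - 1e-9)
    stop("interval (", interval_ps, " ps) is smaller than the native frame spacing (",
         dt, " ps)")
  rel <- traj$times - traj$times[1]
  keep <- abs(rel - round(rel / interval_ps) * interval_ps) <= dt / 2 + 1e-9
  keep[1] <- TRUE
  trajectory3d(traj$topology,
               traj$coords[keep, , , drop = FALSE],
               times = traj$times[keep],
               step_fs = traj$step_fs,
               save_interval_steps = traj$save_interval_steps)
}

#' Write a time series table as headered CSV
#'
#' @param df data.frame whose first columns are `frame` and `time_ps`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
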