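#' Partition residues into quasi-rigid domains between two conformers
#'
#' Deterministic greedy seeded-growth partitioning of the selected CA
#' residues into blocks that move as rigid bodies between structures `x`
#' and `y`:
#'
#' 1. `y` is Kabsch-fitted onto `x` over the whole selection; `D` is the
#'    mean per-residue CA displacement after this global fit.
#' 2. Candidate seeds are all windows of `seed_window` consecutive
#'    residues (within a chain, gaps break windows), ranked by internal
#'    fit RMSD ascending; ties by lowest residue number.
#' 3. The best fully-unassigned seed is grown to a fixed point (at most
#'    `max_iter` sweeps): fit the current domain, admit any unassigned
#'    residue whose post-fit displacement is at most `tolerance * D`,
#'    drop members exceeding it.
#' 4. The converged domain is accepted if it has at least
#'    `min_domain_size` residues, else the seed is discarded; repeat until
#'    no seed qualifies. Leftover residues are reported unassigned
#'    (hinge/flexible).
#'
#' The tolerance is a fraction of the global mean displacement (0.4 by
#' default, i.e. 40%). Identical structures (`D = 0`) are a single
#' all-residue rigid domain. Domains may be sequence-discontinuous and
#' are returned in decreasing size order. The partition is invariant to
#' global rigid transforms of either structure and involves no randomness.
#'
#' @param x,y `structure3d` conformers sharing the selection's atoms.
#' @param sel CA `atom_selection` (one atom per residue).
#' @param tolerance displacement tolerance as a fraction of `D`, in (0, 1].
#' @param min_domain_size smallest accepted domain (residues).
#' @param seed_window seed window length (consecutive residues).
#' @param max_iter growth sweep cap per seed.
#' @return object of class `domain_partition`: `domains` (list of data
#'   frames with `chain`, `resno`, `index` into the selection),
#'   `unassigned`, `tolerance`, `mean_displacement`, `selection`.
#' @export
partition_rigid_domains <- function(x, y, sel, tolerance = 0.4,
                                    min_domain_size = 15L, seed_window = 12L,
                                    max_iter = 50L) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  check_selection(x, sel); check_selection(y, sel)
  keep <- c("chain", "resno", "elety")
  if (!identical(x$atoms[sel$indices, keep], y$atoms[sel$indices, keep]))
    stop("x and y do not share the selection's atoms")
  n <- length(sel$indices)
  if (n < min_domain_size) stop("selection smaller than min_domain_size")
  X <- x$xyz[sel$indices, , drop = FALSE]
  Y <- y$xyz[sel$indices, , drop = FALSE]
  ch <- x$atoms$chain[sel$indices]
  rn <- x$atoms$resno[sel$indices]

  YA <- apply_superposition(Y, kabsch_fit(Y, X))
  disp <- row_norms(YA - X)
  D <- mean(disp)
  res_df <- function(i) data.frame(chain = ch[i], resno = rn[i], index = i,
                                   stringsAsFactors = FALSE)
  mk <- function(domains, unassigned) {
    sizes <- vapply(domains, nrow, integer(1))
    first <- vapply(domains, function(d) min(d$resno), numeric(1))
    o <- order(-sizes, first)
    structure(list(domains = domains[o], unassigned = unassigned,
                   tolerance = tolerance, mean_displacement = D,
                   selection = sel),
              class = "domain_partition")
  }
  if (D < 1e-9) return(mk(list(res_df(seq_len(n))), res_df(integer(0))))

  # seed windows: consecutive residue numbers within a chain
  seeds <- list()
  for (chain in unique(ch)) {
    pos <- which(ch == chain)
    pos <- pos[order(rn[pos])]
    runs <- split(pos, cumsum(c(1, diff(rn[pos]) != 1)))
    for (r in runs) {
      if (length(r) < seed_window) next
      for (s in seq_len(length(r) - seed_window + 1L))
        seeds[[length(seeds) + 1L]] <- r[s:(s + seed_window - 1L)]
    }
  }
  if (!length(seeds)) stop("no seed windows: selection has no run of ",
                           seed_window, " consecutive residues")
  seed_rmsd <- vapply(seeds, function(w) kabsch_fit(X[w, ], YA[w, ])$rmsd,
                      numeric(1))
  seed_first <- vapply(seeds, function(w) min(rn[w]), numeric(1))
  seeds <- seeds[order(seed_rmsd, seed_first)]

  assigned <- logical(n)
  domains <- list()
  for (w in seeds) {
    if (any(assigned[w])) next
    members <- w
    for (it in seq_len(max_iter)) {
      sp <- kabsch_fit(X[members, , drop = FALSE], YA[members, , drop = FALSE])
      dall <- row_norms(apply_superposition(X, sp) - YA)
      cand <- which(!assigned & dall <= tolerance * D)
      if (length(cand) < 3L) { members <- integer(0); break }
      if (length(cand) == length(members) && all(cand == members)) break
      members <- cand
    }
    if (length(members) >= min_domain_size) {
      assigned[members] <- TRUE
      domains[[length(domains) + 1L]] <- res_df(members)
    }
  }
  mk(domains, res_df(which(!assigned)))
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition> ", length(x$domains), " rigid domains, ",
      nrow(x$unassigned), " unassigned residues (tolerance ",
      x$tolerance, " x D, D = ", signif(x$mean_displacement, 3), " A)\n", sep = "")
  for (i in seq_along(x$domains)) {
    d <- x$domains[[i]]
    cat(sprintf("  domain %d: %d residues [%s]\n", i, nrow(d),
                compact_ranges(d$chain, d$resno)))
  }
  invisible(x)
}

# "A:1-60, B:10-20" style summaries; internal
compact_ranges <- function(chain, resno) {
  parts <- c()
  for (chn in unique(chain)) {
    r <- sort(resno[chain == chn])
    brk <- cumsum(c(1, diff(r) != 1))
    for (g in split(r, brk)) {
      parts <- c(parts, if (length(g) > 1)
        sprintf("%s:%d-%d", chn, min(g), max(g)) else sprintf("%s:%d", chn, g))
    }
  }
  paste(parts, collapse = ", ")
}

#' Screw-transform report for a rigid-domain partition
#'
#' Characterises the motion of each rigid domain between conformers `x`
#' and `y` as a screw transform. The largest domain (tie: lowest residue
#' number) serves as the reference frame: `y` is aligned onto `x` over
#' that domain, and each domain's restricted Kabsch fit between `x` and
#' the aligned `y` is decomposed into angle, hinge axis, pivot point,
#' pitch and the distance moved by the domain's geometric centre. The
#' reference domain itself therefore reports an angle near zero, and
#' reported rotations are relative to it, as domain-motion analyses
#' conventionally present them. Domains are ordered by decreasing angle.
#'
#' @param x,y the conformer pair used for the partition.
#' @param partition a `domain_partition`.
#' @param angle_min passed to [screw_decomposition()].
#' @return object of class `hinge_report`: per-domain list of `residues`
#'   and `screw`, plus `reference_domain` (index into the partition's
#'   ordering), `global_rmsd` (over the whole selection after
#'   reference-domain alignment).
#' @export
hinge_report <- function(x, y, partition, angle_min = 1.0) {
  stopifnot(inherits(partition, "domain_partition"))
  if (!length(partition$domains)) stop("partition has no domains")
  sel <- partition$selection
  X <- x$xyz[sel$indices, , drop = FALSE]
  Y <- y$xyz[sel$indices, , drop = FALSE]
  ref_dom <- 1L  # partition is ordered by decreasing size, tie lowest resno
  ri <- partition$domains[[ref_dom]]$index
  YA <- apply_superposition(Y, kabsch_fit(Y[ri, , drop = FALSE],
                                          X[ri, , drop = FALSE]))
  doms <- lapply(partition$domains, function(d) {
    if (!nrow(d)) stop("empty domain in partition")
    sp <- kabsch_fit(X[d$index, , drop = FALSE], YA[d$index, , drop = FALSE])
    list(residues = d,
         screw = screw_decomposition(sp$rotation, sp$translation,
                                     X[d$index, , drop = FALSE],
                                     angle_min = angle_min),
         fit_rmsd = sp$rmsd)
  })
  angles <- vapply(doms, function(d) d$screw$angle_deg, numeric(1))
  o <- order(-angles)
  structure(list(domains = doms[o],
                 reference_domain = which(o == ref_dom),
                 global_rmsd = rmsd_between(X, YA),
                 partition = partition),
            class = "hinge_report")
}

#' @export
print.hinge_report <- function(x, ...) {
  cat("<hinge_report> ", length(x$domains), " domains, global rmsd ",
      sprintf("%.3f", x$global_rmsd), " A (reference domain ",
      x$reference_domain, ")\n", sep = "")
  for (i in seq_along(x$domains)) {
    d <- x$domains[[i]]
    cat(sprintf("  domain %d [%s]: ", i,
                compact_ranges(d$residues$chain, d$residues$resno)))
    print(d$screw)
  }
  invisible(x)
}

#' Hinge analysis of the extreme structures of a PCA mode
#'
#' Composes [extreme_frames()], [partition_rigid_domains()] and
#' [hinge_report()]: the trajectory frames at the minimum and maximum
#' projection of the chosen mode are partitioned into quasi-rigid domains
#' and each domain's motion (from the minimum- to the maximum-projection
#' structure) is reported as a screw transform. The minimum-projection
#' structure is the frame of reference for reporting.
#'
#' @param traj a `trajectory3d`.
#' @param model an `ed_pca` fitted on (or applicable to) the trajectory.
#' @param mode mode index.
#' @param tolerance,min_domain_size,seed_window passed to
#'   [partition_rigid_domains()].
#' @return a `hinge_report` with extra fields `frames` and `times` of the
#'   extreme structures.
#' @export
analyse_mode_extremes <- function(traj, model, mode = 1L, tolerance = 0.4,
                                  min_domain_size = 15L, seed_window = 12L) {
  proj <- project_trajectory(traj, model, mode)
  ext <- extreme_frames(proj, traj, model)
  part <- partition_rigid_domains(ext$min_structure, ext$max_structure,
                                  model$selection, tolerance = tolerance,
                                  min_domain_size = min_domain_size,
                                  seed_window = seed_window)
  rep <- hinge_report(ext$min_structure, ext$max_structure, part)
  rep$frames <- ext$frames
  rep$times <- ext$times
  rep
}

#' Write hinge axes as PDB pseudo-atoms
#'
#' Two pseudo-atom records per defined axis (endpoints of a segment of
#' `length` Angstrom centred on the pivot), for visualising hinge axes
#' alongside the structures.
#'
#' @param report a `hinge_report`.
#' @param path output PDB file.
#' @param length axis segment length in Angstrom.
#' @return `path`, invisibly.
#' @export
write_hinge_axes <- function(report, path, length = 40) {
  rows <- list(); xyz <- NULL
  k <- 0L
  for (i in seq_along(report$domains)) {
    s <- report$domains[[i]]$screw
    if (!s$axis_defined) next
    k <- k + 1L
    e1 <- s$pivot - (length / 2) * s$axis
    e2 <- s$pivot + (length / 2) * s$axis
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "X", resno = c(k, k), resid = "AXS",
      elety = c("AX1", "AX2"), elesy = "X", stringsAsFactors = FALSE)
    xyz <- rbind(xyz, rbind(e1, e2))
  }
  if (!k) stop("no defined axes to write")
  write_structures(structure3d(do.call(rbind, rows), xyz, title = "hinge axes"),
                   path)
}

#' Serialise a hinge report to JSON
#' @param report a `hinge_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hinge_json <- function(report, path) {
  doms <- lapply(report$domains, function(d) {
    s <- d$screw
    list(residues = compact_ranges(d$residues$chain, d$residues$resno),
         n_residues = nrow(d$residues),
         angle_deg = s$angle_deg,
         axis = if (s$axis_defined) as.numeric(s$axis) else NULL,
         pivot = if (s$axis_defined) as.numeric(s$pivot) else NULL,
         pitch = if (s$axis_defined) s$pitch else NULL,
         centre_displacement = s$centre_displacement,
         fit_rmsd = d$fit_rmsd)
  })
  jsonlite::write_json(list(domains = doms,
                            reference_domain = report$reference_domain,
                            global_rmsd = report$global_rmsd,
                            unassigned = compact_ranges(
                              report$partition$unassigned$chain,
                              report$partition$unassigned$resno)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
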