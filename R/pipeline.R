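#' Assemble and validate an analysis configuration
#'
#' Bundles everything [run_analysis()] needs: the topology, one or more
#' labelled runs, the residue scheme, and the analysis parameters. The
#' parameter defaults are the standard protocol: PCA on frames subsampled
#' to 75 ps intervals and aligned to the starting coordinates, RMSD
#' moving average with a period of 20, hinge tolerance 0.4 (40%).
#'
#' Runs may be given as in-memory `trajectory3d` objects or as file paths
#' (`.pdb` multi-model or `.dcd`; DCD requires `topology`).
#'
#' @param topology a `structure3d` or PDB path.
#' @param trajectories named list of `trajectory3d` objects or file paths;
#'   names are the run labels (e.g. `ADPPi-1`).
#' @param scheme a [residue_scheme()].
#' @param reference_run label of the run whose PC1 the others are
#'   projected onto (default: the first).
#' @param pca_interval_ps subsampling interval for PCA and projections.
#' @param moving_average_period RMSD smoothing window (frames).
#' @param hinge_tolerance tolerance for [partition_rigid_domains()].
#' @param output_dir directory for the report bundle.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param subsample_for_pca subsample before PCA/projections (default
#'   TRUE; disable to use every frame).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(topology, trajectories, scheme = residue_scheme(),
                            reference_run = NULL, pca_interval_ps = 75,
                            moving_average_period = 20L, hinge_tolerance = 0.4,
                            output_dir = "nbdtraj_out", seed = 1L,
                            subsample_for_pca = TRUE) {
  if (is.character(topology)) topology <- read_pdb(topology)
  if (!inherits(topology, "structure3d")) stop("config error: invalid topology")
  if (!length(trajectories)) stop("config error: empty trajectory list")
  if (is.null(names(trajectories)) || any(!nzchar(names(trajectories))))
    stop("config error: every trajectory needs a run label")
  trajectories <- lapply(trajectories, function(tr) {
    if (is.character(tr)) {
      tr <- if (grepl("\\.dcd$", tr, ignore.case = TRUE))
        read_dcd(tr, topology) else read_pdb(tr)
    }
    if (!inherits(tr, "trajectory3d")) stop("config error: invalid trajectory entry")
    tr
  })
  if (is.null(reference_run)) reference_run <- names(trajectories)[1]
  if (!reference_run %in% names(trajectories))
    stop("config error: reference_run '", reference_run, "' is not a run label")
  if (pca_interval_ps <= 0 || moving_average_period < 1 ||
      hinge_tolerance <= 0 || hinge_tolerance > 1)
    stop("config error: invalid analysis parameter")
  structure(list(topology = topology, trajectories = trajectories,
                 scheme = scheme, reference_run = reference_run,
                 pca_interval_ps = pca_interval_ps,
                 moving_average_period = as.integer(moving_average_period),
                 hinge_tolerance = hinge_tolerance,
                 output_dir = output_dir, seed = as.integer(seed),
                 subsample_for_pca = isTRUE(subsample_for_pca)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised keys: `topology`, `trajectories` (map of label to path),
#' `reference_run`, `pca_interval_ps`, `moving_average_period`,
#' `hinge_tolerance`, `output_dir`, `seed`, `subsample_for_pca`, and an
#' optional `scheme` map of residue-range lists (each a list of
#' `[lo, hi]` pairs) plus `nucleotide_monomer` / `apo_monomer` /
#' `d_loop_residue` overrides.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  scheme <- residue_scheme()
  if (!is.null(y$scheme)) {
    args <- y$scheme
    rng_keys <- intersect(names(args), c("core", "helical_rmsd", "helical_domain",
                                         "q_loop", "pro_loop", "a34_loop",
                                         "c_term_tail", "walker_a", "c_motif"))
    for (k in rng_keys) args[[k]] <- lapply(args[[k]], as.numeric)
    scheme <- do.call(residue_scheme, args)
  }
  args <- list(topology = y$topology, trajectories = as.list(y$trajectories),
               scheme = scheme)
  for (k in c("reference_run", "pca_interval_ps", "moving_average_period",
              "hinge_tolerance", "output_dir", "seed", "subsample_for_pca"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(analysis_config, args)
}

# run one pipeline stage with a named error context; internal
run_stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis battery
#'
#' Reproduces the complete trajectory-analysis protocol on every
#' configured run and writes a machine-readable report bundle to the
#' output directory:
#'
#' * `rmsd_<run>.csv` — dimer (all-CA fit), per-monomer (self-fit) and
#'   per-subdomain (core / helical, self-fit) RMSD series against the
#'   starting structure, plus `rmsd_ma_<run>.csv` with the trailing
#'   moving average of the subdomain series.
#' * `opening_<run>.csv` — the two composite-site opening distances.
#' * `pca_fractions_<run>.csv` and `projection_<run>.csv` — eigenvalue
#'   fractions and the mode-1 self-projection of each run's PCA (fitted
#'   on the subsampled trajectory, aligned to the starting structure).
#' * `cross_projection_<run>.csv`, `overlap.csv`, `correlation.csv` —
#'   every run projected onto the reference run's PC1; the subspace
#'   overlap of that mode against each run's PCs 1-2; and the Pearson
#'   correlation between each run's cross-projection and its apo-site
#'   opening distance.
#' * `hinge_report.json` and `hinge_axes.pdb` — rigid-domain/screw
#'   analysis between the extreme projection structures of the reference
#'   run's PC1.
#' * `mode1_interpolation.pdb` — the two extremes plus 8 interpolated
#'   structures along PC1.
#' * `manifest.json` (all outputs with MD5 hashes, plus parameters) and
#'   `run.log`.
#'
#' Per-monomer and per-subdomain RMSD use self-fit (fit and compute on the
#' same selection), so monomer-internal stability is separated from the
#' intermonomer rearrangement that dominates the dimer-wide RMSD.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with the key computed quantities
#'   (`fractions`, `overlaps`, `correlations`, `hinge`, `files`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(msg) writeLines(sprintf("[%s] %s",
                                          format(Sys.time(), "%H:%M:%S"), msg),
                                  log_con)
  log(sprintf("runs: %s; reference: %s; seed %d",
              paste(names(config$trajectories), collapse = ", "),
              config$reference_run, config$seed))
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$output_dir, name)
    write_series_csv(df, p)
    files <<- c(files, p)
    p
  }
  scheme <- config$scheme
  topo <- config$topology
  chains <- c(scheme$nucleotide_monomer, scheme$apo_monomer)

  sub <- run_stage("subsample", log, lapply(config$trajectories, function(tr) {
    if (config$subsample_for_pca) subsample(tr, config$pca_interval_ps) else tr
  }))

  run_stage("rmsd", log, for (run in names(config$trajectories)) {
    tr <- config$trajectories[[run]]
    sel_all <- scheme_selection(topo, scheme, "all")
    out <- rmsd_series(tr, sel_all)[, c("frame", "time_ps")]
    out$dimer <- rmsd_series(tr, sel_all)$rmsd
    ma <- data.frame(frame = integer(0))
    for (ch in chains) {
      out[[paste0("monomer_", ch)]] <-
        rmsd_series(tr, scheme_selection(topo, scheme, "monomer", chain = ch))$rmsd
      for (sd in c("core", "helical_rmsd")) {
        nm <- paste0(sub("_rmsd", "", sd), "_", ch)
        out[[nm]] <- rmsd_series(tr, scheme_selection(topo, scheme, sd, chain = ch))$rmsd
      }
    }
    emit(out, sprintf("rmsd_%s.csv", run))
    p <- config$moving_average_period
    if (nrow(out) >= p) {
      sm <- out[p:nrow(out), c("frame", "time_ps")]
      for (nm in setdiff(names(out), c("frame", "time_ps")))
        sm[[nm]] <- moving_average(out[[nm]], p)
      emit(sm, sprintf("rmsd_ma_%s.csv", run))
    }
  })

  opening <- run_stage("opening", log, {
    lst <- lapply(names(config$trajectories), function(run) {
      d <- opening_distance_series(config$trajectories[[run]], scheme)
      emit(d, sprintf("opening_%s.csv", run))
      d
    })
    names(lst) <- names(config$trajectories)
    lst
  })

  models <- run_stage("pca", log, {
    lst <- lapply(names(sub), function(run) {
      m <- fit_pca(sub[[run]], scheme_selection(topo, scheme, "all"),
                   reference = topo)
      emit(utils::head(summary(m, n = 20), 20), sprintf("pca_fractions_%s.csv", run))
      emit(project_trajectory(sub[[run]], m, 1), sprintf("projection_%s.csv", run))
      m
    })
    names(lst) <- names(sub)
    lst
  })

  ref_model <- models[[config$reference_run]]
  cross <- run_stage("cross_projection", log, {
    lst <- lapply(names(sub), function(run) {
      pr <- project_trajectory(sub[[run]], ref_model, 1)
      emit(pr, sprintf("cross_projection_%s.csv", run))
      pr
    })
    names(lst) <- names(sub)
    lst
  })

  overlaps <- run_stage("overlap", log, {
    ov <- vapply(names(models), function(run)
      subspace_overlap(ref_model$modes[, 1], models[[run]], k = 2), numeric(1))
    emit(data.frame(run = names(ov), overlap_vs_reference_pc1 = as.numeric(ov)),
         "overlap.csv")
    ov
  })

  correlations <- run_stage("correlation", log, {
    cc <- vapply(names(sub), function(run) {
      projection_distance_correlation(cross[[run]],
                                      opening_distance_series(sub[[run]], scheme)$site_apo)
    }, numeric(1))
    emit(data.frame(run = names(cc), r_projection_vs_apo_opening = as.numeric(cc)),
         "correlation.csv")
    cc
  })

  hinge <- run_stage("hinge", log, {
    rep <- analyse_mode_extremes(sub[[config$reference_run]], ref_model, 1,
                                 tolerance = config$hinge_tolerance)
    p <- file.path(config$output_dir, "hinge_report.json")
    write_hinge_json(rep, p); files <- c(files, p)
    if (any(vapply(rep$domains, function(d) d$screw$axis_defined, logical(1)))) {
      pa <- file.path(config$output_dir, "hinge_axes.pdb")
      write_hinge_axes(rep, pa); files <- c(files, pa)
    }
    rep
  })

  run_stage("interpolation", log, {
    pr <- project_trajectory(sub[[config$reference_run]], ref_model, 1)
    tr <- interpolate_mode(ref_model, 1, min(pr$value), max(pr$value), n_inner = 8)
    p <- file.path(config$output_dir, "mode1_interpolation.pdb")
    write_structures(tr, p); files <- c(files, p)
  })

  manifest <- list(
    runs = names(config$trajectories),
    reference_run = config$reference_run,
    parameters = list(pca_interval_ps = config$pca_interval_ps,
                      moving_average_period = config$moving_average_period,
                      hinge_tolerance = config$hinge_tolerance,
                      subsample_for_pca = config$subsample_for_pca,
                      seed = config$seed),
    files = {
      fl <- sort(unique(c(files, file.path(config$output_dir, c(
        "hinge_report.json", "mode1_interpolation.pdb")))))
      fl <- fl[file.exists(fl)]
      stats::setNames(as.list(unname(tools::md5sum(fl))), basename(fl))
    })
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log("done")
  invisible(list(fractions = lapply(models, function(m) m$fractions[1:3]),
                 overlaps = overlaps, correlations = correlations,
                 hinge = hinge, models = models,
                 opening = opening,
                 files = list.files(config$output_dir, full.names = TRUE)))
}
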