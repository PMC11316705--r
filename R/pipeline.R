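#' Run the simulate -> observables pipeline from a config file
#'
#' Expands the config's `rho_sigma3` x `beta` grid (optionally over
#' `n_seeds` consecutive seeds per cell), runs each confined-chain
#' simulation, and writes per-run outputs under `outdir`: an XYZ trajectory,
#' contact- and distance-profile CSVs, and a JSON scaling-fit summary. A
#' run whose outputs already exist is skipped unless `force = TRUE`.
#'
#' @param config_path Path to a YAML/JSON config (see [read_config]).
#' @param outdir Output directory (created if needed).
#' @param force Recompute runs whose outputs already exist.
#' @param quiet Suppress per-run progress messages.
#' @return Data frame indexing the runs (one row per run: density, beta,
#'   seed, alpha, file paths), invisibly written as `runs.csv` too.
#' @export
cli_simulate <- function(config_path, outdir, force = FALSE, quiet = FALSE) {
  cfg <- read_config(config_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ff_keys <- c("k_fene", "R0", "eps_wca", "sigma", "wall_eps", "wall_spacing")
  ff <- do.call(force_field, cfg[intersect(names(cfg), ff_keys)])
  base <- cfg[setdiff(names(cfg), c(ff_keys, "n_seeds", "beta", "rho_sigma3"))]
  n_seeds <- if (is.null(cfg$n_seeds)) 1L else as.integer(cfg$n_seeds)
  seed0 <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  base$seed <- NULL
  grid <- expand.grid(rho_sigma3 = if (is.null(cfg$rho_sigma3)) 0.25
                                   else cfg$rho_sigma3,
                      beta = if (is.null(cfg$beta)) 1 else cfg$beta,
                      seed = seed0 + seq_len(n_seeds) - 1L)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tag <- sprintf("rho%.3g_beta%.3g_seed%d", g$rho_sigma3, g$beta, g$seed)
    paths <- file.path(outdir, paste0(tag, c(".xyz", "_pc.csv", "_r2.csv",
                                             "_fit.json")))
    if (!force && all(file.exists(paths))) {
      if (!quiet) message("cached: ", tag)
      fit <- jsonlite::read_json(paths[4])
      rows[[i]] <- data.frame(g, alpha = as.numeric(fit$alpha),
                              xyz = paths[1], pc_csv = paths[2],
                              r2_csv = paths[3], fit_json = paths[4])
      next
    }
    sc <- do.call(sim_config,
                  c(base, list(rho_sigma3 = g$rho_sigma3, beta = g$beta,
                               seed = g$seed, ff = ff)))
    if (!quiet) message("running: ", tag)
    traj <- run_simulation(sc)
    pc <- contact_probability(traj)
    r2 <- mean_squared_internal_distance(traj)
    fit <- fit_scaling_exponent(pc)
    write_xyz(traj, paths[1],
              comment = sprintf("rho=%g beta=%g seed=%d", g$rho_sigma3,
                                g$beta, g$seed))
    meta <- c(seed = g$seed, rho_sigma3 = g$rho_sigma3, beta = g$beta)
    write_profile_csv(pc, paths[2], meta)
    write_profile_csv(r2, paths[3], meta)
    jsonlite::write_json(list(alpha = fit$alpha, stderr = fit$stderr,
                              r_squared = fit$r_squared, l_min = fit$l_min,
                              l_max = fit$l_max, n_points = fit$n_points,
                              seed = g$seed, rho_sigma3 = g$rho_sigma3,
                              beta = g$beta),
                         paths[4], auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(g, alpha = fit$alpha, xyz = paths[1],
                            pc_csv = paths[2], r2_csv = paths[3],
                            fit_json = paths[4])
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(outdir, "runs.csv"), row.names = FALSE)
  invisible(out)
}

#' Run the shape-analysis pipeline on a directory of structures
#'
#' Reads per-chromosome replica structures (XYZ or CMM files named
#' `<chrom>_<replica>.xyz` / `.cmm`, or one multi-frame XYZ per chromosome),
#' fits spheroids, writes the shape report CSV and the normalized rescaled
#' contact-probability curves CSV.
#'
#' @param input Directory of structure files, or a `"ct_ensemble"`.
#' @param outdir Output directory.
#' @param grid Shared rescaled grid for the contact curves.
#' @param r_cutoff Contact cutoff used on the structures (input units).
#' @param tol Shape-class tolerance.
#' @return List with `report` (data frame) and `curves`
#'   (normalize_across_chromosomes output), invisibly.
#' @export
cli_shapes <- function(input, outdir = NULL,
                       grid = seq(0.05, 1, by = 0.05), r_cutoff = 2,
                       tol = 0.15) {
  if (inherits(input, "ct_ensemble")) {
    ensembles <- input$structures
  } else {
    files <- list.files(input, pattern = "\\.(xyz|cmm)$", full.names = TRUE)
    if (!length(files)) stop("no .xyz or .cmm structures found in ", input,
                             call. = FALSE)
    ensembles <- list()
    for (f in files) {
      nm <- sub("_[0-9]+$", "", sub("\\.(xyz|cmm)$", "", basename(f)))
      reps <- tryCatch({
        if (grepl("\\.cmm$", f)) list(read_cmm(f))
        else {
          arr <- read_xyz(f)$frames
          lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
        }
      }, error = function(e) {
        warning(sprintf("skipping unreadable structure %s: %s", basename(f),
                        conditionMessage(e)))
        NULL
      })
      if (is.null(reps)) next
      ensembles[[nm]] <- c(ensembles[[nm]], reps)
    }
    if (!length(ensembles))
      stop("all structure files were unreadable", call. = FALSE)
  }
  report <- shape_report(ensembles, tol = tol)
  curves <- lapply(ensembles, function(reps) {
    frames <- array(unlist(reps), c(nrow(reps[[1]]), 3, length(reps)))
    pc <- contact_probability(list(frames = frames) |>
                                structure(class = "trajectory"),
                              r_cutoff = r_cutoff, last_fraction = 1)
    rescale_profile(pc, grid)
  })
  norm <- normalize_across_chromosomes(curves)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_profile_csv(report, file.path(outdir, "shape_report.csv"))
    curves_df <- data.frame(l = norm$grid, norm$normalized,
                            check.names = FALSE)
    write_profile_csv(curves_df, file.path(outdir, "normalized_curves.csv"))
  }
  invisible(list(report = report, curves = norm))
}
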