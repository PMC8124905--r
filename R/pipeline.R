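#' Run the full analysis pipeline
#'
#' Executes the analysis battery on a configured trajectory: input reading,
#' superposition, global and per-domain/per-ss RMSD with lowess curves,
#' RMSD-band fractions, RGYR and RMSD-RGYR correlation, RMSF with
#' flexible-region flagging, inter-domain distance density, quasiharmonic
#' PCA with octant trace, DCC with candidate mining, and (if kinetic data
#' are configured) the Michaelis-Menten fit. Every stage writes a flat
#' TSV/CSV table into `out_dir` and is logged to `run.log`.
#'
#' @param config A `run_config` (see [read_run_config()]) or a path to one.
#' @param out_dir Output directory (created if needed).
#' @return An `analysis_report`: named list of output paths plus run
#'   metadata. On stage failure the error names the failing stage; partial
#'   outputs are retained and the report file gains a FAILED marker.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  outputs <- list()
  stage_name <- "setup"
  logmsg <- function(...) {
    writeLines(paste0("[", stage_name, "] ", sprintf(...)), log_con)
  }
  stage <- function(name, code) {
    stage_name <<- name
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      writeLines(paste0("[", name, "] FAILED: ", conditionMessage(e)), log_con)
      writeLines(sprintf("FAILED at stage %s", name),
                 file.path(out_dir, "FAILED"))
      gtb_stop(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)),
               class = "gtb_pipeline_error")
    })
    logmsg("done in %.2f s", proc.time()[["elapsed"]] - t0)
    out
  }
  emit <- function(key, filename, writer) {
    path <- file.path(out_dir, filename)
    writer(path)
    outputs[[key]] <<- path
    path
  }

  inputs <- stage("trajio", {
    if (is.null(config$trajectory) || !file.exists(config$trajectory)) {
      gtb_config_error(paste0("config field 'trajectory' does not point to ",
                              "a readable file: ",
                              config$trajectory %||% "<missing>"))
    }
    structure_model <- if (!is.null(config$structure))
      read_structure(config$structure) else NULL
    traj <- read_trajectory(config$trajectory, structure_model,
                            format = config$trajectory_format,
                            frame_interval_ps = config$frame_interval_ps)
    if (config$stride > 1) {
      traj <- subset_frames(traj, seq(1, n_frames(traj), by = config$stride))
      traj$frame_interval_ps <- config$frame_interval_ps * config$stride
    }
    if (!is.null(config$ss)) validate_ss_coverage(config$ss, traj)
    if (!is.null(config$active_site) &&
        !all(config$active_site %in% traj$residues$resnum)) {
      gtb_config_error("active_site residues absent from trajectory")
    }
    logmsg("%d frames x %d residues (stride %d)", n_frames(traj),
           n_residues(traj), config$stride)
    list(traj = traj, structure = structure_model)
  })
  traj <- inputs$traj
  ref <- if (!is.null(inputs$structure)) inputs$structure else 1

  desc <- stage("descriptors", {
    glob <- rmsd_series(traj, ref)
    emit("rmsd_global", "rmsd_global.tsv",
         function(p) write_series_tsv(glob, p))
    emit("rmsd_global_lowess", "rmsd_global_lowess.tsv", function(p)
      write_series_tsv(lowess_smooth(glob, config$lowess_fraction), p))
    bands <- rmsd_band_fractions(glob, config$rmsd_band_edges)
    emit("rmsd_bands", "rmsd_band_fractions.tsv", function(p)
      utils::write.table(data.frame(band = names(bands),
                                    percent = as.numeric(bands)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    for (lab in names(config$domains$residues)) {
      dsel <- domain_residues(config$domains, lab)
      dser <- rmsd_series(traj, ref, fit_selection = dsel,
                          measure_selection = dsel)
      emit(paste0("rmsd_domain_", lab),
           sprintf("rmsd_domain_%s.tsv", lab),
           function(p) write_series_tsv(dser, p))
      if (!is.null(config$ss)) {
        # per-ss-class RMSD within the domain, skipping loop/3_10 regions
        for (cls in c("helix", "sheet")) {
          ssres <- intersect(dsel,
                             config$ss$resnum[config$ss$class == cls])
          if (length(ssres) < 3) next
          sser <- rmsd_series(traj, ref, fit_selection = dsel,
                              measure_selection = ssres)
          emit(paste0("rmsd_ss_", lab, "_", cls),
               sprintf("rmsd_ss_%s_%s.tsv", lab, cls),
               function(p) write_series_tsv(sser, p))
        }
      }
    }
    rg <- rgyr_series(traj)
    emit("rgyr", "rgyr.tsv", function(p) write_series_tsv(rg, p))
    logmsg("RMSD-RGYR Pearson r = %.3f", series_correlation(glob, rg))
    dist <- interdomain_distance_series(traj, config$domains)
    emit("interdomain_distance", "interdomain_distance.tsv",
         function(p) write_series_tsv(dist, p))
    dens <- distance_density(dist, config$density_bandwidth)
    emit("distance_density", "distance_density.tsv", function(p)
      utils::write.table(data.frame(distance_A = dens$grid,
                                    density = dens$density),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("distance_modes", "distance_modes.tsv", function(p)
      utils::write.table(dens$modes, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    aligned <- align_to_mean(traj)
    prof <- rmsf_profile(aligned)
    emit("rmsf", "rmsf.tsv", function(p) write_profile_tsv(prof, p))
    emit("flexible_regions", "flexible_regions.tsv", function(p)
      utils::write.table(flag_flexible_regions(prof, domains = config$domains,
                                               ss = config$ss),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    list(aligned = aligned)
  })
  aligned <- desc$aligned

  stage("pca", {
    model <- pca_fit(aligned, K = max(3, config$pca$n_components))
    emit("pca_variance", "pca_variance.tsv", function(p)
      utils::write.table(summary(model, n = 10), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
    trace <- octant_trace(model)
    emit("pca_projections", "pca_projections.tsv",
         function(p) write_projections_tsv(model, p, trace))
    emit("octant_occupancy", "octant_occupancy.tsv", function(p)
      utils::write.table(data.frame(octant = names(trace$occupancy),
                                    percent = as.numeric(trace$occupancy)),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("octant_transitions", "octant_transitions.tsv", function(p)
      utils::write.table(trace$transitions, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    for (k in 1:3) {
      interp <- pc_interpolation(model, k, steps = 10)
      emit(paste0("pc", k, "_interpolation"),
           sprintf("pc%d_interpolation.xyz", k),
           function(p) write_xyztable(interp, p))
    }
    logmsg("top-3 variance = %.1f%%, PC zero crossings %s",
           sum(model$variance_fractions[1:3]),
           paste(trace$zero_crossings, collapse = "/"))
  })

  stage("dcc", {
    dcc <- dcc_matrix(aligned)
    emit("dcc_matrix", "dcc_matrix.tsv", function(p) write_dcc_tsv(dcc, p))
    if (!is.null(config$active_site) && !is.null(inputs$structure)) {
      cand <- mine_candidates(
        dcc, inputs$structure, config$domains, config$active_site,
        corr_cutoff = config$mining$corr_cutoff,
        min_dist = config$mining$min_dist,
        donor_site = config$mining$donor_site,
        max_donor_dist = config$mining$max_donor_dist,
        allowed_classes = config$mining$allowed_classes)
      emit("candidates", "candidates.tsv", function(p)
        utils::write.table(as.data.frame(cand), p, sep = "\t",
                           quote = FALSE, row.names = FALSE))
      logmsg("%d candidate residue(s)", nrow(cand))
    }
  })

  if (!is.null(config$kinetics_data)) {
    stage("kinetics", {
      dat <- read_kinetics_csv(config$kinetics_data)
      fits <- list(enzyme = mm_fit(dat$conc_M, dat$rate_per_s))
      if (!is.null(config$kinetics_reference)) {
        rdat <- read_kinetics_csv(config$kinetics_reference)
        fits <- c(list(reference = mm_fit(rdat$conc_M, rdat$rate_per_s)),
                  fits)
      }
      emit("kinetics", "kinetics.tsv",
           function(p) write_kinetics_tsv(fits, p))
    })
  }

  stage_name <- "report"
  empty <- names(outputs)[!vapply(outputs, function(p)
    file.exists(p) && file.size(p) > 0, logical(1))]
  if (length(empty) > 0) {
    gtb_stop(paste0("declared outputs missing or empty: ",
                    paste(empty, collapse = ", ")), "gtb_pipeline_error")
  }
  report <- structure(list(
    outputs = outputs,
    out_dir = out_dir,
    log = log_path,
    meta = list(seed = config$seed, stride = config$stride,
                n_frames = n_frames(traj), n_residues = n_residues(traj),
                package_version = as.character(utils::packageVersion("gtbdyn")))),
    class = "analysis_report")
  logmsg("pipeline complete: %d tables", length(outputs))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", length(x$outputs), " outputs in ", x$out_dir,
      "\n", sep = "")
  cat(" ", paste(basename(unlist(x$outputs)), collapse = ", "), "\n")
  invisible(x)
}
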