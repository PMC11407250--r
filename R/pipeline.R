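# Config-driven orchestration: phantom -> optics -> forward (two cardiac
# phases, all wavelengths) -> Jacobian/ranking -> flat field -> pulse/noise
# metrics, with CSV/JSON/VTK outputs and a checksummed manifest.

#' Build a run configuration
#'
#' Defaults encode the reference experiment: an OA-like phantom, a 6 x 6
#' optode grid over 100 x 70 mm, channels 20-120 mm in 20 mm groups, seven
#' wavelengths 730-850 nm, 5% pulsatile arterial volume, the exponential
#' noise model (0.0024, 0.0236/mm) with 480-beat averaging and a 10 mm
#' square detector.
#'
#' @param phantom a [phantom_spec()].
#' @param wavelengths simulation wavelengths in nm.
#' @param grid_shape,grid_extent optode grid (rows x cols, mm x mm).
#' @param dmin,dmax channel distance window (mm).
#' @param edges distance-group bin edges (mm).
#' @param detector_side,detector_dx large-detector patch geometry (mm).
#' @param noise a [noise_model()], or `NULL` to disable noise.
#' @param analyses character subset of
#'   `c("jacobian", "flatfield", "pulse", "ranking")`.
#' @param top_k channels kept per group in rankings/summaries.
#' @param outdir output directory.
#' @param seed RNG seed for all stochastic stages.
#' @param write_vtk write sensitivity maps as `.vtu` files.
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       wavelengths = seq(730, 850, by = 20),
                       grid_shape = c(6L, 6L), grid_extent = c(100, 70),
                       dmin = 20, dmax = 120, edges = seq(20, 120, by = 20),
                       detector_side = 10, detector_dx = 0.4,
                       noise = noise_model(),
                       analyses = c("jacobian", "flatfield", "pulse", "ranking"),
                       top_k = 10L, outdir = tempfile("fetalnirs_run_"),
                       seed = 1L, write_vtk = FALSE) {
  analyses <- match.arg(analyses,
                        c("jacobian", "flatfield", "pulse", "ranking"),
                        several.ok = TRUE)
  if (!length(analyses)) stop("at least one analysis must be enabled")
  tab <- load_chromophores()
  rng <- range(tab$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop("wavelengths outside the chromophore table range")
  structure(list(phantom = phantom, wavelengths = wavelengths,
                 grid_shape = grid_shape, grid_extent = grid_extent,
                 dmin = dmin, dmax = dmax, edges = edges,
                 detector_side = detector_side, detector_dx = detector_dx,
                 noise = noise, analyses = analyses, top_k = as.integer(top_k),
                 outdir = outdir, seed = as.integer(seed),
                 write_vtk = isTRUE(write_vtk)),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return For `read_run_config`, a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- do.call(phantom_spec, as.list(cfg$phantom))
  nm <- if (is.null(cfg$noise)) NULL else do.call(noise_model, as.list(cfg$noise))
  args <- cfg[setdiff(names(cfg), c("phantom", "noise"))]
  do.call(run_config, c(list(phantom = ph, noise = nm), args))
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  ph <- unclass(config$phantom)
  ph$brain_depth <- NULL   # derived; re-derived on read
  out <- list(phantom = ph,
              noise = if (is.null(config$noise)) NULL else unclass(config$noise))
  for (f in c("wavelengths", "grid_shape", "grid_extent", "dmin", "dmax",
              "edges", "detector_side", "detector_dx", "analyses", "top_k",
              "outdir", "seed", "write_vtk"))
    out[[f]] <- config[[f]]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the full sensitivity-analysis pipeline
#'
#' Executes every enabled analysis for every wavelength on one phantom and
#' writes: `channels.csv`, `metrics.csv` (per-channel fluences and pulse
#' metrics), `rankings.csv`, `summary.csv` (per wavelength x group statistics
#' over the top channels), `feasibility.json`, `config.json` and
#' `manifest.json` (file inventory with md5 checksums). Fully deterministic
#' for a fixed seed.
#'
#' @param config a [run_config()].
#' @return list of class `run_manifest` (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  t_all <- proc.time()[["elapsed"]]
  timing <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  mesh <- stage("phantom", build_phantom(config$phantom, seed = config$seed))
  layout <- stage("probe", build_probe_layout(mesh, config$grid_shape,
                                              config$grid_extent))
  channels <- stage("channels", {
    ch <- select_channels(layout, config$dmin, config$dmax)
    group_channels(ch, config$edges)
  })
  groups <- attr(channels, "groups")

  src_opt <- layout$optodes[layout$optodes$role == "source", ]
  det_opt <- layout$optodes[layout$optodes$role == "detector", ]
  used_s <- unique(channels$source_id)
  used_d <- unique(channels$detector_id)
  patches <- stage("patches", {
    p <- lapply(used_d, function(id) {
      o <- det_opt[det_opt$id == id, ]
      detector_patch(mesh, c(o$u, o$v), side = config$detector_side,
                     dx = config$detector_dx, dy = config$detector_dx)
    })
    stats::setNames(p, as.character(used_d))
  })

  metrics <- list(); rankings <- list(); feas <- list(); ffmaps <- list()
  brain <- label_nodes(mesh, "fetal_brain")
  for (lam in config$wavelengths) {
    props_d <- assign_properties(mesh, lam, "diastole")
    props_s <- assign_properties(mesh, lam, "systole")
    sources <- stats::setNames(lapply(used_s, function(id) {
      o <- src_opt[src_opt$id == id, ]
      make_source(mesh, c(o$u, o$v), props_d)
    }), as.character(used_s))

    fem_d <- assemble_fem(mesh, props_d)
    jac <- stage(sprintf("jacobian_%d", lam),
                 compute_jacobian(fem_d, channels, sources, patches))
    phi_d <- jac$Phi

    phi_s <- phi_d
    if ("pulse" %in% config$analyses) {
      fem_s <- assemble_fem(mesh, props_s)
      sols <- lapply(sources, function(s) solve_fluence(fem_s, s))
      phi_s <- vapply(seq_len(nrow(channels)), function(i) {
        detector_fluence(sols[[as.character(channels$source_id[i])]],
                         patches[[as.character(channels$detector_id[i])]])
      }, numeric(1))
    }

    met <- data.frame(wavelength = lam,
                      source_id = channels$source_id,
                      detector_id = channels$detector_id,
                      distance_mm = channels$distance,
                      group = channels$group,
                      phi_diastole = phi_d, phi_systole = phi_s)
    if ("pulse" %in% config$analyses) {
      met$delta_od <- delta_od(phi_d, phi_s)
      met$dynamic_range <- dynamic_range(phi_d, phi_s, allow_nonfinite = TRUE)
      if (!is.null(config$noise)) {
        noisy <- lapply(seq_len(nrow(met)), function(i)
          averaged_noisy_metrics(phi_d[i], phi_s[i], met$distance_mm[i],
                                 config$noise))
        met$delta_od_noisy <- vapply(noisy, `[[`, numeric(1), "delta_od")
        met$dynamic_range_noisy <- vapply(noisy, `[[`, numeric(1), "dynamic_range")
      }
    }
    metrics[[as.character(lam)]] <- met

    scores <- brain_sensitivity_scores(jac, brain)
    if ("ranking" %in% config$analyses) {
      rk <- do.call(rbind, lapply(groups$label[groups$NM > 0], function(g)
        cbind(wavelength = lam,
              rank_top_channels(scores, channels, g, config$top_k))))
      rankings[[as.character(lam)]] <- rk
    }

    if ("flatfield" %in% config$analyses) {
      props_p <- perturb_field(props_d, 0.01)
      fem_p <- assemble_fem(mesh, props_p)
      sols_p <- lapply(sources, function(s) solve_fluence(fem_p, s))
      phi_p <- vapply(seq_len(nrow(channels)), function(i) {
        detector_fluence(sols_p[[as.character(channels$source_id[i])]],
                         patches[[as.character(channels$detector_id[i])]])
      }, numeric(1))
      dphi <- difference_data(phi_d, phi_p, channels$distance, config$noise)
      for (g in groups$label[groups$NM > 0]) {
        jm <- total_normalized_jacobian(jac, g)
        fm <- grouped_flatfield_map(jac, dphi, g)
        feas[[sprintf("%d_%s", lam, g)]] <-
          c(list(wavelength = lam, group = g),
            classify_feasibility(jm, fm, brain))
        ffmaps[[sprintf("%d_%s", lam, g)]] <- list(jac = jm, ff = fm)
      }
    }
    message(sprintf("[fetalnirs] wavelength %d nm done", lam))
  }

  # ---- outputs -------------------------------------------------------------
  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(config$outdir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }
  put("channels.csv", function(p)
    utils::write.csv(channel_table(channels, layout), p, row.names = FALSE))
  metrics_df <- do.call(rbind, metrics)
  put("metrics.csv", function(p) utils::write.csv(metrics_df, p, row.names = FALSE))
  rankings_df <- if (length(rankings)) do.call(rbind, rankings) else NULL
  if (!is.null(rankings_df))
    put("rankings.csv", function(p) utils::write.csv(rankings_df, p, row.names = FALSE))
  if (!is.null(rankings_df) && "pulse" %in% config$analyses) {
    summary_df <- summarize_groups(rankings_df, metrics_df)
    put("summary.csv", function(p) utils::write.csv(summary_df, p, row.names = FALSE))
  }
  if (length(feas))
    put("feasibility.json", function(p)
      jsonlite::write_json(unname(feas), p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
  if (config$write_vtk && length(ffmaps)) {
    for (key in names(ffmaps)) {
      put(sprintf("maps_%s.vtu", key), function(p)
        write_vtu(mesh, p, point_data = list(
          jacobian_total = ffmaps[[key]]$jac$map,
          flatfield = ffmaps[[key]]$ff$map)))
    }
  }
  put("config.json", function(p) write_run_config(config, p))

  manifest <- list(
    package = "fetalnirs",
    version = as.character(utils::packageVersion("fetalnirs")),
    seed = config$seed,
    timing_s = as.list(timing),
    total_s = round(proc.time()[["elapsed"]] - t_all, 3),
    n_channels = nrow(channels),
    groups = groups,
    files = data.frame(path = basename(paths),
                       md5 = unname(tools::md5sum(paths))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$outdir <- config$outdir
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Per-group summary statistics over the top-ranked channels
#'
#' For each wavelength and distance group: mean and standard deviation, over
#' the ranked channels, of the brain sensitivity score, the pulse dOD, the
#' maximum detected fluence (diastole), the minimum fluence (pulsatile
#' difference) and the required dynamic range. Noisy metrics are used when
#' present.
#'
#' @param rankings ranking table (`rankings.csv` layout).
#' @param metrics per-channel metrics table (`metrics.csv` layout).
#' @return data frame, one row per wavelength x group.
#' @export
summarize_groups <- function(rankings, metrics) {
  key <- function(df) paste(df$wavelength, df$source_id, df$detector_id)
  metrics$minimum_fluence <- metrics$phi_diastole - metrics$phi_systole
  od_col <- if ("delta_od_noisy" %in% names(metrics)) "delta_od_noisy" else "delta_od"
  dr_col <- if ("dynamic_range_noisy" %in% names(metrics)) "dynamic_range_noisy"
  else "dynamic_range"
  mk <- key(metrics)
  rows <- list()
  for (lam in unique(rankings$wavelength)) {
    for (g in unique(rankings$group[rankings$wavelength == lam])) {
      rk <- rankings[rankings$wavelength == lam & rankings$group == g, ]
      mi <- match(paste(lam, rk$source_id, rk$detector_id), mk)
      sub <- metrics[mi, ]
      fin <- function(x) x[is.finite(x)]
      stat <- function(x) c(mean(fin(x)), stats::sd(fin(x)))
      s_sc <- stat(rk$score); s_od <- stat(sub[[od_col]])
      s_mx <- stat(sub$phi_diastole); s_mn <- stat(sub$minimum_fluence)
      s_dr <- stat(sub[[dr_col]])
      rows[[length(rows) + 1L]] <- data.frame(
        wavelength = lam, group = g, n_channels = nrow(rk),
        sensitivity_mean = s_sc[1], sensitivity_sd = s_sc[2],
        delta_od_mean = s_od[1], delta_od_sd = s_od[2],
        max_fluence_mean = s_mx[1], max_fluence_sd = s_mx[2],
        min_fluence_mean = s_mn[1], min_fluence_sd = s_mn[2],
        dynamic_range_mean = s_dr[1], dynamic_range_sd = s_dr[2])
    }
  }
  out <- do.call(rbind, rows)
  # a single-channel group has sd 0, not NA
  for (cl in grep("_sd$", names(out))) out[[cl]][is.na(out[[cl]])] <- 0
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("fetalnirs run: seed %d, %d channels, %.1f s\n",
              x$seed, x$n_channels, x$total_s))
  cat("outputs:", paste(x$files$path, collapse = ", "), "\n")
  invisible(x)
}
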