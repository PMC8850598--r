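#' Simulate a complete recording session
#'
#' Builds a synthetic session with known ground truth: one foraging
#' trajectory, a mixed cell population (grid cells, head-direction
#' cells, theta-modulated interneurons, untuned Poisson cells), and a
#' speed-modulated theta LFP. Useful as pipeline input and for
#' end-to-end recovery checks.
#'
#' @param duration session length, s
#' @param arena arena geometry
#' @param n_grid,n_hd,n_int,n_untuned population composition
#' @param drift_rate grid phase drift, cm/min
#' @param seed RNG seed
#' @param ... passed to [simulate_trajectory()]
#' @return list: `traj`, `cells` (named list of `spike_train`s), `lfp`,
#'   `ground_truth` (per-cell generator parameters)
#' @export
simulate_session <- function(duration = 1200, arena = arena_rect(75, 75),
                             n_grid = 2, n_hd = 2, n_int = 1,
                             n_untuned = 1, drift_rate = 0, seed = 1, ...) {
  traj <- simulate_trajectory(duration, arena, seed = seed, ...)
  cells <- list()
  gt <- list()
  k <- 0
  with_seed(seed + 1000L, {
    for (i in seq_len(n_grid)) {
      k <- k + 1
      spacing <- stats::runif(1, 35, 50)
      gc <- grid_cell(spacing = spacing,
                      orientation = stats::runif(1, 0, 60),
                      phase = stats::runif(2, 0, spacing),
                      peak_rate = 15, drift_rate = drift_rate,
                      duration = duration, seed = seed + 10L + i)
      id <- sprintf("grid%02d", i)
      cells[[id]] <- poisson_spikes(gc, traj, seed = seed + 100L + k,
                                    cell_id = id)
      gt[[id]] <- list(type = "grid", spacing = spacing,
                       drift_rate = drift_rate)
    }
    for (i in seq_len(n_hd)) {
      k <- k + 1
      pd <- stats::runif(1, 0, 360)
      hc <- hd_cell(preferred_direction = pd, kappa = 4, peak_rate = 25)
      id <- sprintf("hd%02d", i)
      cells[[id]] <- poisson_spikes(hc, traj, seed = seed + 100L + k,
                                    cell_id = id)
      gt[[id]] <- list(type = "head_direction", preferred_direction = pd,
                       kappa = 4)
    }
    for (i in seq_len(n_int)) {
      k <- k + 1
      tc <- theta_cell(base_rate = 20, theta_freq = 8, depth = 0.5)
      id <- sprintf("int%02d", i)
      cells[[id]] <- poisson_spikes(tc, traj, seed = seed + 100L + k,
                                    cell_id = id, waveform_width = 0.2)
      gt[[id]] <- list(type = "interneuron", theta_freq = 8)
    }
    for (i in seq_len(n_untuned)) {
      k <- k + 1
      id <- sprintf("untuned%02d", i)
      cells[[id]] <- poisson_spikes(function(x, y, t, hd)
        rep(3, length(t)), traj, seed = seed + 100L + k, cell_id = id)
      gt[[id]] <- list(type = "untuned", rate = 3)
    }
  })
  lfp <- simulate_lfp(traj, seed = seed + 2000L)
  list(traj = traj, cells = cells, lfp = lfp, ground_truth = gt)
}

#' Run the full analysis pipeline on one session
#'
#' Computes, for every cell, the metric set and functional label; for
#' spatially stable analysis candidates, the epoch-wise 2-D displacement
#' summary; cross-correlogram synchrony for grid-interneuron and
#' grid-head-direction pairs; and, when an LFP is present, the
#' theta-by-speed spectrogram and per-cell intrinsic frequencies. All
#' outputs are plain data frames; when `out_dir` is given they are also
#' written as CSV files together with a machine-readable run manifest.
#'
#' @param session list with `traj`, `cells`, optional `lfp` (as returned
#'   by [simulate_session()] or [read_session_bundle()]), or a path to a
#'   session bundle directory
#' @param out_dir optional output directory
#' @param stability_epochs,stability_epoch_len epoch partition for the
#'   displacement analysis; cells in sessions shorter than their product
#'   are skipped
#' @param ... passed to [make_ratemap()]
#' @return list of tables: `cells`, `stability`, `synchrony`, `rhythm`
#'   (list: `spectrogram`, `intrinsic`), `manifest`
#' @export
run_pipeline <- function(session, out_dir = NULL, stability_epochs = 10,
                         stability_epoch_len = 180, ...) {
  if (is.character(session)) session <- read_session_bundle(session)
  traj <- session$traj
  cells <- session$cells
  if (is.null(traj) || !length(cells)) {
    stop_invalid("session must contain a trajectory and at least one cell")
  }
  metrics <- do.call(rbind, lapply(cells, function(cl)
    cell_metrics(traj, cl, ...)))
  labels <- character(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    labels[i] <- classify_mec_cell(as.list(metrics[i, ]))$label
  }
  metrics$label <- labels
  T_ <- traj_duration(traj)
  stab <- NULL
  if (T_ >= stability_epochs * stability_epoch_len) {
    cand <- which(labels %in% c("grid", "head_direction", "nongrid_spatial"))
    stab <- do.call(rbind, lapply(cand, function(i) {
      maps <- epoch_maps(traj, cells[[i]], n_epochs = stability_epochs,
                         epoch_len = stability_epoch_len, ...)
      ds <- displacement_summary(maps)
      cbind(data.frame(cell_id = metrics$cell_id[i],
                       label = labels[i],
                       mean_displacement = ds$mean_displacement),
            stats::setNames(as.data.frame(t(ds$by_lag$mean_displacement)),
                            paste0("lag", ds$by_lag$lag)))
    }))
  }
  sync <- synchrony_table(cells, labels)
  rhythm <- NULL
  if (!is.null(session$lfp)) {
    spec <- theta_speed_spectrogram(session$lfp, traj)
    intr <- do.call(rbind, lapply(seq_along(cells), function(i) {
      pf <- tryCatch(intrinsic_frequency(cells[[i]])$peak_freq,
                     error = function(e) NA_real_)
      data.frame(cell_id = metrics$cell_id[i], intrinsic_freq = pf)
    }))
    rhythm <- list(spectrogram = spec, intrinsic = intr)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gridcells")),
    n_cells = length(cells), duration_s = T_,
    params = list(stability_epochs = stability_epochs,
                  stability_epoch_len = stability_epoch_len))
  manifest$config_hash <- fnv1a(paste(deparse(manifest), collapse = ""))
  out <- list(cells = metrics, stability = stab, synchrony = sync,
              rhythm = rhythm, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    if (!is.null(stab)) {
      utils::write.csv(stab, file.path(out_dir, "stability.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(sync, file.path(out_dir, "synchrony.csv"),
                     row.names = FALSE)
    if (!is.null(rhythm)) {
      utils::write.csv(rhythm$intrinsic,
                       file.path(out_dir, "intrinsic_frequency.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(speed = spec$speed_centers,
                   theta_power = spec$theta_power_by_speed,
                   theta_freq = spec$theta_freq_by_speed),
        file.path(out_dir, "theta_by_speed.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}
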