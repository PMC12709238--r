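# End-to-end orchestration: one call from traces (synthetic or on-disk) to
# signalling parameters, waves, networks/communities, subpopulations and
# spatial statistics, with a provenance manifest.

#' Build a pipeline run configuration
#'
#' Collects every stage parameter with mode-dependent defaults. Mouse-like
#' mode: 10 Hz sampling, zero-lag band-pass 0.035-1.5 Hz, wave link window
#' 0.5 s. Human-like mode: 0.33 Hz sampling on a 15 um ISR grid, zero-lag
#' high-pass 0.0075 Hz, wave link window 6 s, neighbourhood radius 22 um.
#' Every value is echoed into the run manifest so no default stays silent.
#'
#' @param mode `"mouse"` or `"human"`.
#' @param islet an [islet_config()] for synthetic input (default: one built
#'   from `mode` and `seed`), or `NULL` when `input_dir` is given.
#' @param input_dir directory with `traces.csv`, `coords.csv`, `meta.json`
#'   to analyse instead of synthetic data.
#' @param seed integer seed controlling generation, community detection and
#'   shuffle baselines.
#' @param k_avg_target target mean degree of the functional network.
#' @param k_avg_tol tolerance on the achieved mean degree.
#' @param theta_amp binarization threshold fraction.
#' @param first_fraction fraction of a wave counted as "first" for initiator
#'   scoring.
#' @param sustained_window optional `c(t0, t1)` override (s); default is
#'   first-quartile response time + 60 s up to the end of the recording.
#' @param n_regions number of equal-area concentric regions.
#' @param correlate_on `"filtered"` (default) to correlate the filtered
#'   continuous traces, or `"binary"` to correlate the binarized states.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("mouse", "human"), islet = NULL,
                       input_dir = NULL, seed = 1, k_avg_target = 8,
                       k_avg_tol = 0.2, theta_amp = 0.3,
                       first_fraction = 0.1, sustained_window = NULL,
                       n_regions = 8,
                       correlate_on = c("filtered", "binary")) {
  correlate_on <- match.arg(correlate_on)
  mode <- match.arg(mode)
  if (is.null(islet) && is.null(input_dir)) {
    islet <- if (mode == "mouse") islet_config(seed = seed) else
      islet_config(n_cells = 150, mode = "grid", sampling_hz = 0.33,
                   duration_s = 2400, stim_onset_s = 300, wave_rate_hz = 0.05,
                   conduction_speed_um_s = 20,
                   response_delay_spread_s = 10,
                   osc_duration_s = c(mean = 30, sd = 6), seed = seed)
  }
  filt <- if (mode == "mouse") list(f_lo = 0.035, f_hi = 1.5) else
    list(f_c = 0.0075)
  cfg <- list(mode = mode, islet = islet, input_dir = input_dir, seed = seed,
              filter = filt, smooth_window = if (mode == "mouse") 5L else 1L,
              theta_amp = theta_amp,
              min_dur_s = if (mode == "mouse") 1 else 9,
              resp_hold_s = if (mode == "mouse") 2 else 15,
              R_t = if (mode == "mouse") 0.5 else 6,
              min_wave_size = 5, first_fraction = first_fraction,
              k_avg_target = k_avg_target, k_avg_tol = k_avg_tol,
              sustained_window = sustained_window, n_regions = n_regions,
              correlate_on = correlate_on)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trace conditioning (zero-lag filtering + adjacent
#' averaging), response-time detection and first responders, binarization
#' and signalling parameters over the sustained phase, intercellular wave
#' detection and initiator scoring, functional-network construction at the
#' target mean degree with Louvain communities and hub labels, and the
#' spatial statistics suite (distance profiles, same/different-community
#' contrasts, hierarchical-clustering overlaps, concentric regions).
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all result tables are
#'   serialized there (CSV/JSON/GraphML) along with `manifest.json`.
#' @return object of class `islet_result` with components `params`, `binary`,
#'   `waves`, `initiators`, `network`, `communities`, `hubs`, `profiles`,
#'   `contrasts`, `overlaps`, `regions`, `region_distributions`, `truth`
#'   (synthetic runs only) and `manifest`.
#' @export
run_islet_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (!is.null(config$input_dir)) {
    ts <- stage("input", read_traceset(config$input_dir))
  } else {
    gen <- stage("synthio", generate_islet(config$islet))
    ts <- gen$traces
    truth <- gen$truth
  }
  n <- ncol(ts$values)

  filtered <- stage("filter", {
    f <- if (config$mode == "mouse")
      bandpass_zero_lag(ts, config$filter$f_lo, config$filter$f_hi)
    else highpass_zero_lag(ts, config$filter$f_c)
    smooth_adjacent(f, config$smooth_window)
  })
  resp <- stage("response",
                detect_response_time(ts, hold_s = config$resp_hold_s))
  ba <- stage("binarize", binarize(filtered, theta_amp = config$theta_amp,
                                   min_dur_s = config$min_dur_s))

  win <- config$sustained_window
  if (is.null(win)) {
    q25 <- stats::quantile(resp, 0.25, na.rm = TRUE, names = FALSE)
    win <- c(ts$stim_onset_s + q25 + 60, ts$time_s[length(ts$time_s)])
    if (diff(win) < 60)
      stop("pipeline stage 'window' failed: sustained phase shorter than 60 s")
  }

  params <- stage("params", signaling_params(ba, win, resp))
  params$first_responder <- stage("first_responders", first_responders(params))

  # one local-neighbourhood definition throughout: the same radius used for
  # the community contrast also links wave events (it always exceeds the
  # 6-NN coupling-edge lengths, which 1.5 x median NN distance need not)
  R_s <- neighborhood_radius(ts$positions, ts$mode)
  wc <- stage("waves", detect_waves(ba, ts$positions, R_s = R_s,
                                    R_t = config$R_t,
                                    min_wave_size = config$min_wave_size,
                                    window = win))
  init <- stage("initiators",
                initiator_scores(wc, n_cells = n,
                                 first_fraction = config$first_fraction))

  corr_input <- if (config$correlate_on == "binary")
    new_trace_set(ba$states, ts$time_s, ts$positions, ts$sampling_hz,
                  ts$stim_onset_s, ts$mode) else filtered
  R <- stage("correlation", correlation_matrix(corr_input, win))
  net <- stage("network", threshold_to_degree(R, config$k_avg_target,
                                              config$k_avg_tol))
  comm <- stage("communities", detect_communities(net, seed = config$seed))
  hubs <- stage("hubs", identify_hubs(net))

  nbr_r <- neighborhood_radius(ts$positions, ts$mode)
  prof_vals <- cbind(active_time = params$active_time,
                     freq_hz = params$freq_hz, dur_s = params$dur_s,
                     response_time_s = params$response_time_s)
  profiles <- stage("profiles",
                    distance_binned_differences(prof_vals, ts$positions,
                                                mode = ts$mode))
  contrasts <- stage("contrasts", list(
    active_time = community_neighborhood_contrast(params$active_time,
                                                  ts$positions, comm, nbr_r),
    response_time = community_neighborhood_contrast(params$response_time_s,
                                                    ts$positions, comm, nbr_r)))
  overlaps <- stage("overlaps", {
    out <- list()
    for (metric in c("euclidean", "active_time", "response_time")) {
      cl <- hierarchical_clusters(ts$positions, params$active_time,
                                  params$response_time_s, metric = metric,
                                  n_clusters = comm$n_communities)
      out[[metric]] <- overlap_proportion(comm, cl, seed = config$seed)
    }
    out
  })
  rp <- stage("regions", concentric_partition(ts$positions, config$n_regions))
  region_dist <- stage("region_distributions", list(
    hubs = subpopulation_by_region(rp, hubs),
    initiators = subpopulation_by_region(rp, init$initiator_flag),
    first_responders = subpopulation_by_region(rp, params$first_responder)))

  manifest <- list(package_version = as.character(utils::packageVersion("isletnet")),
                   mode = config$mode, seed = config$seed,
                   n_cells = n, sampling_hz = ts$sampling_hz,
                   stim_onset_s = ts$stim_onset_s,
                   filter = config$filter,
                   smooth_window = config$smooth_window,
                   theta_amp = config$theta_amp,
                   min_dur_s = config$min_dur_s,
                   sustained_window = win,
                   wave_R_s_um = R_s, wave_R_t_s = config$R_t,
                   min_wave_size = config$min_wave_size,
                   first_fraction = config$first_fraction,
                   k_avg_target = config$k_avg_target,
                   k_avg_achieved = net$k_avg,
                   correlation_threshold = net$threshold,
                   n_communities = comm$n_communities, modularity_Q = comm$Q,
                   neighborhood_radius_um = nbr_r,
                   grid_spacing_um = if (ts$mode == "grid")
                     config$islet$grid_spacing_um else NULL,
                   n_regions = config$n_regions,
                   n_waves = length(wc$waves))

  res <- structure(list(traces = ts, filtered = filtered, params = params,
                        binary = ba, waves = wc, initiators = init,
                        network = net, communities = comm, hubs = hubs,
                        profiles = profiles, contrasts = contrasts,
                        overlaps = overlaps, regions = rp,
                        region_distributions = region_dist, truth = truth,
                        manifest = manifest),
                   class = "islet_result")
  if (!is.null(out_dir)) write_result_bundle(res, out_dir)
  res
}

#' @export
print.islet_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<islet_result> %d cells (%s mode)\n",
                     "  k_avg = %.2f (target %g), %d communities, Q = %.3f\n",
                     "  %d waves, sustained window [%.0f, %.0f] s\n"),
              m$n_cells, m$mode, m$k_avg_achieved, m$k_avg_target,
              m$n_communities, m$modularity_Q, m$n_waves,
              m$sustained_window[1], m$sustained_window[2]))
  invisible(x)
}

# Serialize an islet_result into a directory of plain-text files.
write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(res$params, p("params.csv"), row.names = FALSE)
  utils::write.csv(res$binary$states, p("binary.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(res$waves$waves, function(w)
    w[c("id", "cells", "times", "ranks")]), p("waves.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(cell = res$params$cell,
                              score = res$initiators$score,
                              initiator = res$initiators$initiator_flag),
                   p("initiators.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell = res$params$cell,
                              community = res$communities$labels),
                   p("communities.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell = res$params$cell,
                              degree = res$network$degrees,
                              hub = res$hubs), p("hubs.csv"),
                   row.names = FALSE)
  utils::write.csv(res$profiles, p("profile.csv"), row.names = FALSE)
  ct <- do.call(rbind, lapply(names(res$contrasts), function(nm) {
    cc <- res$contrasts[[nm]]
    data.frame(parameter = nm, median_same = cc$median_same,
               median_diff = cc$median_diff, U = cc$test$U, p = cc$test$p)
  }))
  utils::write.csv(ct, p("contrast.csv"), row.names = FALSE)
  jsonlite::write_json(res$overlaps, p("overlap.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(data.frame(cell = res$params$cell,
                              region = res$regions$region_label),
                   p("regions.csv"), row.names = FALSE)
  write_network_graphml(res$network, res$traces$positions, res$communities,
                        res$hubs, p("net.graphml"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Summary report for a pipeline run
#'
#' Writes a multi-panel PDF (community-coloured network map, per-community
#' active-time boxplots, distance profiles with standard-error bands, and
#' subpopulation-by-region bars) plus a numeric summary table recomputed
#' from the result object. Panels whose inputs are missing are skipped and
#' listed in the return value.
#'
#' @param res an `islet_result`.
#' @param out_dir output directory.
#' @return invisibly, a list with `pdf`, `summary_csv` and `omitted`.
#' @export
make_report <- function(res, out_dir) {
  stopifnot(inherits(res, "islet_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pdf_path <- file.path(out_dir, "report.pdf")
  omitted <- character()
  grDevices::pdf(pdf_path, width = 8, height = 7)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  pos <- res$traces$positions
  ## network map
  if (!is.null(res$network)) {
    cols <- grDevices::hcl.colors(max(res$communities$labels), "Dark 3")
    graphics::plot(pos, asp = 1, pch = 21,
                   bg = cols[res$communities$labels],
                   xlab = "x (um)", ylab = "y (um)",
                   main = sprintf("Functional network (k_avg = %.1f)",
                                  res$network$k_avg))
    ee <- which(res$network$adjacency & upper.tri(res$network$adjacency),
                arr.ind = TRUE)
    graphics::segments(pos[ee[, 1], 1], pos[ee[, 1], 2],
                       pos[ee[, 2], 1], pos[ee[, 2], 2],
                       col = grDevices::adjustcolor("grey40", 0.3))
    graphics::points(pos[res$hubs, , drop = FALSE], pch = 21, bg = "black")
  } else omitted <- c(omitted, "network map")
  ## active time by community
  graphics::boxplot(res$params$active_time ~ res$communities$labels,
                    xlab = "community", ylab = "relative active time",
                    main = "Active time by community")
  ## distance profiles
  pr <- res$profiles[res$profiles$param == "active_time", ]
  ok <- !is.na(pr$mean_abs_diff)
  graphics::plot((pr$d_lo + pr$d_hi)[ok] / 2, pr$mean_abs_diff[ok],
                 type = "b", xlab = "intercellular distance (um)",
                 ylab = expression(Delta * bar(P)(d)),
                 main = "Active-time difference vs distance")
  se_ok <- ok & !is.na(pr$se)
  graphics::arrows((pr$d_lo + pr$d_hi)[se_ok] / 2,
                   pr$mean_abs_diff[se_ok] - pr$se[se_ok],
                   (pr$d_lo + pr$d_hi)[se_ok] / 2,
                   pr$mean_abs_diff[se_ok] + pr$se[se_ok],
                   angle = 90, code = 3, length = 0.02)
  ## subpopulations by region
  if (length(res$waves$waves) > 0) {
    rd <- res$region_distributions
    mat <- rbind(hubs = rd$hubs$fraction,
                 initiators = rd$initiators$fraction,
                 first_responders = rd$first_responders$fraction)
    graphics::barplot(mat, beside = TRUE, names.arg = rd$hubs$region,
                      legend.text = rownames(mat),
                      xlab = "concentric region (1 = centre)",
                      ylab = "fraction of subpopulation",
                      main = "Subpopulations by region")
  } else omitted <- c(omitted, "initiator panels (no waves detected)")

  summ <- data.frame(
    quantity = c("n_cells", "k_avg_achieved", "n_communities",
                 "modularity_Q", "n_waves", "median_active_time",
                 "overlap_euclidean", "contrast_active_time_p"),
    value = c(res$manifest$n_cells, res$network$k_avg,
              res$communities$n_communities, res$communities$Q,
              length(res$waves$waves),
              stats::median(res$params$active_time),
              res$overlaps$euclidean$proportion_matched,
              res$contrasts$active_time$test$p))
  csv_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summ, csv_path, row.names = FALSE)
  invisible(list(pdf = pdf_path, summary_csv = csv_path, omitted = omitted))
}
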