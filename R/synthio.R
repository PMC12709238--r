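# Synthetic islet generator: geometry, ground-truth modules, dynamics, and
# readers/writers for the on-disk trace format.

#' Configuration for a synthetic islet
#'
#' Builds a validated configuration for [generate_islet()]. Defaults emulate a
#' mouse-like recording: ~150 beta cells scattered in an elliptical field,
#' imaged at 10 Hz for 6 minutes with a glucose step at 60 s. The human-like
#' alternative (`mode = "grid"`, `sampling_hz = 0.33`) places islet subregions
#' (ISRs) on a 15 um square mesh, the resolution used when single cells cannot
#' be segmented.
#'
#' @param n_cells number of cells (or ISRs); at least 12 so top-1/6
#'   subpopulation sets are non-empty.
#' @param field_shape semi-axes (um) of the elliptical islet cross-section.
#' @param mode `"scatter"` (cells at random positions with minimum spacing) or
#'   `"grid"` (15 um square mesh of ISRs).
#' @param n_modules number of spatially contiguous ground-truth modules.
#' @param sampling_hz acquisition rate (Hz); 10 for mouse-like, 0.33 for
#'   human-like recordings.
#' @param duration_s total recording length (s).
#' @param stim_onset_s time of the glucose step (s).
#' @param wave_rate_hz rate of the Poisson process generating intercellular
#'   waves during the sustained phase.
#' @param p_global_wave probability that a wave recruits the whole islet
#'   rather than staying confined to its seed module.
#' @param conduction_speed_um_s wave conduction speed over the cell-cell
#'   coupling graph (um/s).
#' @param response_delay_spread_s within-module SD of glucose response delays
#'   (s); module mean delays are drawn separately, so activation is clustered.
#' @param osc_duration_s mean/SD pair (s) for the duration of the activation
#'   transient each cell fires when it first responds to glucose.
#' @param noise_sd SD of additive Gaussian noise (fluorescence a.u.; pulse
#'   amplitude is 1).
#' @param drift_amp amplitude of the slow sinusoid-plus-linear baseline drift.
#' @param grid_spacing_um mesh edge length in grid mode (um).
#' @param min_spacing_um minimum inter-cell distance in scatter mode (um).
#' @param seed integer seed; every random draw in [generate_islet()] comes
#'   from one stream seeded here.
#' @return an object of class `islet_config`.
#' @export
islet_config <- function(n_cells = 150,
                         field_shape = c(110, 85),
                         mode = c("scatter", "grid"),
                         n_modules = 12,
                         sampling_hz = 10,
                         duration_s = 360,
                         stim_onset_s = 60,
                         wave_rate_hz = 0.3,
                         p_global_wave = 0.1,
                         conduction_speed_um_s = 90,
                         response_delay_spread_s = 2,
                         osc_duration_s = c(mean = 6, sd = 1),
                         noise_sd = 0.15,
                         drift_amp = 0.3,
                         grid_spacing_um = 15,
                         min_spacing_um = 10,
                         seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(n_cells = as.integer(n_cells), field_shape = field_shape,
              mode = mode, n_modules = as.integer(n_modules),
              sampling_hz = sampling_hz, duration_s = duration_s,
              stim_onset_s = stim_onset_s, wave_rate_hz = wave_rate_hz,
              p_global_wave = p_global_wave,
              conduction_speed_um_s = conduction_speed_um_s,
              response_delay_spread_s = response_delay_spread_s,
              osc_duration_s = osc_duration_s, noise_sd = noise_sd,
              drift_amp = drift_amp, grid_spacing_um = grid_spacing_um,
              min_spacing_um = min_spacing_um, seed = as.integer(seed))
  class(cfg) <- "islet_config"
  validate_islet_config(cfg)
  cfg
}

validate_islet_config <- function(cfg) {
  if (cfg$n_cells < 12) stop("invalid config: n_cells must be >= 12")
  if (cfg$sampling_hz <= 0) stop("invalid config: sampling_hz must be > 0")
  if (cfg$n_modules < 1) stop("invalid config: n_modules must be >= 1")
  if (cfg$p_global_wave < 0 || cfg$p_global_wave > 1)
    stop("invalid config: p_global_wave must lie in [0, 1]")
  if (length(cfg$field_shape) != 2 || any(cfg$field_shape <= 0))
    stop("invalid config: field_shape must be two positive semi-axes")
  if (cfg$stim_onset_s < 30)
    stop("invalid config: need >= 30 s of pre-stimulus baseline")
  if (cfg$mode == "grid") grid_dims(cfg$n_cells)  # errors if unfactorable
  invisible(cfg)
}

# Factor n_cells into an nx x ny grid no more elongated than 4:1.
grid_dims <- function(n_cells) {
  divs <- which(n_cells %% seq_len(n_cells) == 0L)
  nx <- divs[which.min(abs(divs - sqrt(n_cells)))]
  ny <- n_cells %/% nx
  if (max(nx, ny) > 4 * min(nx, ny))
    stop("invalid config: n_cells = ", n_cells,
         " inconsistent with grid dimensions (best factorization ",
         nx, " x ", ny, " is more elongated than 4:1)")
  c(nx, ny)
}

# Dart-throwing (Poisson-disk) placement of n points inside an ellipse with
# semi-axes ab, enforcing a minimum spacing. Deterministic given the RNG state.
poisson_disk_ellipse <- function(n, ab, min_spacing, max_tries = 400L) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- c(stats::runif(1, -ab[1], ab[1]), stats::runif(1, -ab[2], ab[2]))
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop("could not place ", n, " cells with spacing ", min_spacing,
           " um inside the field; enlarge field_shape")
    if ((cand[1] / ab[1])^2 + (cand[2] / ab[2])^2 > 1) next
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  colnames(pts) <- c("x_um", "y_um")
  pts
}

# Solve sum(pmin(d, gaps)) = target for the common pulse duration d.
# gaps are the times available to each pulse before the next one (or the end
# of the window). Returns Inf when even filling every gap cannot reach target.
solve_common_duration <- function(gaps, target) {
  if (length(gaps) == 0L) return(0)
  if (sum(gaps) <= target) return(Inf)
  g <- sort(gaps)
  n <- length(g)
  filled <- 0
  for (j in seq_len(n)) {
    remaining <- n - j + 1L
    # all gaps >= g[j] still open; can we reach target before exhausting g[j]?
    d <- (target - filled) / remaining
    if (d <= g[j]) return(d)
    filled <- filled + g[j]
  }
  stop("unreachable")  # guarded by sum(gaps) > target
}

#' Generate a synthetic islet recording with ground truth
#'
#' Simulates an islet whose cells carry module-structured intrinsic
#' parameters, respond to a glucose step with clustered delays, and during the
#' sustained phase participate in intercellular Ca2+ waves seeded at
#' high-excitability initiator cells and conducted over a 6-nearest-neighbour
#' coupling graph. Fluorescence is the binary activity passed through a
#' calcium-indicator-like pulse kernel plus baseline drift and Gaussian noise.
#'
#' The generative steps, in the order they consume the RNG stream:
#' 1. positions (dart-throwing in scatter mode, mesh in grid mode);
#' 2. module labels = Voronoi regions of `n_modules` cells drawn as seeds;
#' 3. per-module mean active time and response delay, plus i.i.d. per-cell
#'    jitter; initiator flags = the most peripheral top-1/6 among cells with
#'    above-median intrinsic active time;
#' 4. activation transients at each cell's response time;
#' 5. Poisson wave times; each wave is seeded at an initiator of its module
#'    (or any initiator if global) and propagated at `conduction_speed_um_s`
#'    along shortest paths of the coupling graph;
#' 6. per-cell pulse durations chosen so the union of wave pulses occupies
#'    exactly the cell's intrinsic active-time fraction of the sustained
#'    window; 7. drift phases and additive noise.
#'
#' @param config an [islet_config()].
#' @return list with components `traces` (a `trace_set`) and `truth` (an
#'   `islet_truth`: `module_label`, `intrinsic_active_time`,
#'   `intrinsic_response_time` (s after stimulus), `initiator_flag`,
#'   `wave_log`, ground-truth `binary` matrix, and the `sustained_window`).
#' @export
generate_islet <- function(config) {
  validate_islet_config(config)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_cells
  fs <- config$sampling_hz
  dt <- 1 / fs
  n_t <- floor(config$duration_s * fs)
  time_s <- (seq_len(n_t) - 1L) * dt

  ## 1. geometry -------------------------------------------------------------
  if (config$mode == "scatter") {
    pos <- poisson_disk_ellipse(n, config$field_shape, config$min_spacing_um)
  } else {
    dims <- grid_dims(n)
    a <- config$grid_spacing_um
    # mesh anchored at the origin so every coordinate is a multiple of the
    # ISR edge length
    gx <- (seq_len(dims[1]) - 1L) * a
    gy <- (seq_len(dims[2]) - 1L) * a
    pos <- as.matrix(expand.grid(x_um = gx, y_um = gy))
  }

  ## 2. spatially contiguous modules (Voronoi of seed cells) ------------------
  seed_cells <- sample.int(n, config$n_modules)
  d_seed <- outer(seq_len(n), seed_cells, function(i, j) {
    sqrt((pos[i, 1] - pos[j, 1])^2 + (pos[i, 2] - pos[j, 2])^2)
  })
  module_label <- max.col(-d_seed, ties.method = "first")

  ## 3. intrinsic parameters and initiator flags ------------------------------
  mod_at <- stats::runif(config$n_modules, 0.12, 0.35)
  at <- pmin(0.6, pmax(0.02, mod_at[module_label] + stats::rnorm(n, 0, 0.03)))
  mod_delay <- stats::runif(config$n_modules, 4, 24)
  delay <- pmax(0.5, mod_delay[module_label] +
                  stats::rnorm(n, 0, config$response_delay_spread_s))
  centroid <- colMeans(pos)
  periph <- sqrt((pos[, 1] - centroid[1])^2 + (pos[, 2] - centroid[2])^2)
  # initiators: top-1/6 overall, allocated to modules in proportion to size
  # (at least one per module) and placed as a contiguous rim patch grown by
  # proximity from each module's most peripheral cell, so waves of a module
  # start repeatedly from the same elevated-excitability region
  n_init <- ceiling(n / 6)
  mod_sizes <- tabulate(module_label, config$n_modules)
  quota <- pmax(1L, floor(n_init * mod_sizes / n))
  while (sum(quota) > n_init) {
    j <- which.max(quota)
    quota[j] <- quota[j] - 1L
  }
  rem <- n_init - sum(quota)
  if (rem > 0) {
    frac <- n_init * mod_sizes / n - quota
    add <- order(-frac)[seq_len(rem)]
    quota[add] <- quota[add] + 1L
  }
  initiator_flag <- logical(n)
  for (m in seq_len(config$n_modules)) {
    cand <- which(module_label == m)
    if (length(cand) == 0L || quota[m] == 0L) next
    start <- cand[order(-periph[cand], cand)][1]
    d_start <- sqrt((pos[cand, 1] - pos[start, 1])^2 +
                    (pos[cand, 2] - pos[start, 2])^2)
    take <- utils::head(cand[order(d_start, cand)], quota[m])
    initiator_flag[take] <- TRUE
  }
  # initiator cells are themselves more active: raise their intrinsic active
  # time to at least the 60th percentile of the raw distribution, which
  # provably stays at or above the post-boost population median (at most
  # n/6 values are raised, so the median cannot move past the raw 0.583
  # quantile)
  at[initiator_flag] <- pmax(at[initiator_flag],
                             stats::quantile(at, 0.6, names = FALSE))

  ## coupling graph: symmetrized 6-nearest-neighbour --------------------------
  k_nn <- min(6L, n - 1L)
  nn <- knn_indices(pos, k_nn)
  edges <- unique(t(apply(cbind(rep(seq_len(n), k_nn), as.vector(nn)), 1L,
                          sort)))
  elen <- sqrt((pos[edges[, 1], 1] - pos[edges[, 2], 1])^2 +
               (pos[edges[, 1], 2] - pos[edges[, 2], 2])^2)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = elen)

  ## 4. activation transients --------------------------------------------------
  om <- config$osc_duration_s
  trans_dur <- pmax(1, stats::rnorm(n, om[[1]], om[[2]]))
  resp_abs <- config$stim_onset_s + delay

  ## 5. waves ------------------------------------------------------------------
  t_sus0 <- config$stim_onset_s + max(delay) + 5
  t_sus1 <- config$duration_s
  if (t_sus1 - t_sus0 < 30)
    stop("sustained window shorter than 30 s; increase duration_s")
  span <- c(t_sus0 + 2, t_sus1 - 2)
  n_waves <- stats::rpois(1, config$wave_rate_hz * diff(span))
  wave_times <- sort(stats::runif(n_waves, span[1], span[2]))
  wave_log <- vector("list", n_waves)
  hit_times <- vector("list", n)  # onset times per cell from waves
  for (w in seq_len(n_waves)) {
    is_global <- stats::runif(1) < config$p_global_wave
    if (is_global) {
      members <- seq_len(n)
      seed_pool <- which(initiator_flag)
    } else {
      m <- sample.int(config$n_modules, 1)
      members <- which(module_label == m)
      seed_pool <- which(initiator_flag & module_label == m)
      if (length(seed_pool) == 0L)
        seed_pool <- members[which.max(at[members])]
    }
    seed_cell <- if (length(seed_pool) == 1L) seed_pool else
      sample(seed_pool, 1)
    sub <- igraph::induced_subgraph(g, members)
    dists <- igraph::distances(sub,
                               v = match(seed_cell, members))[1, ]
    reach <- is.finite(dists)
    cells <- members[reach]
    times <- wave_times[w] + dists[reach] / config$conduction_speed_um_s
    ord <- order(times, cells)
    cells <- cells[ord]; times <- times[ord]
    wave_log[[w]] <- list(id = w, cells = cells, times = times,
                          global = is_global, seed = seed_cell)
    for (i in seq_along(cells))
      hit_times[[cells[i]]] <- c(hit_times[[cells[i]]], times[i])
  }

  ## 6. binary activity --------------------------------------------------------
  binary <- matrix(0L, n_t, n)
  frame_of <- function(t) pmin(n_t, pmax(1L, floor(t * fs) + 1L))
  w_sus <- t_sus1 - t_sus0
  for (i in seq_len(n)) {
    # activation transient
    a0 <- resp_abs[i]; a1 <- min(a0 + trans_dur[i], config$duration_s)
    binary[frame_of(a0):frame_of(a1 - dt / 2), i] <- 1L
    ht <- hit_times[[i]]
    if (length(ht) > 0L) {
      ht <- sort(ht)
      gaps <- diff(c(ht, t_sus1))
      d_i <- solve_common_duration(gaps, at[i] * w_sus)
      for (t0 in ht) {
        t1 <- min(t0 + d_i, t_sus1)
        f0 <- frame_of(t0)
        binary[f0:max(f0, frame_of(t1 - dt / 2)), i] <- 1L
      }
    }
  }

  ## 7. fluorescence ------------------------------------------------------------
  if (fs >= 2) {
    # exponential indicator kernel: fast rise, fast decay (see vignette for
    # why the decay is kept shorter than the frame-accurate binarization
    # tolerance demands)
    up <- 1 - exp(-dt / 0.2)
    down <- exp(-dt / 0.08)
    pulse <- matrix(0, n_t, n)
    state <- numeric(n)
    for (k in seq_len(n_t)) {
      on <- binary[k, ] == 1L
      state[on] <- state[on] + (1 - state[on]) * up
      state[!on] <- state[!on] * down
      pulse[k, ] <- state
    }
  } else {
    pulse <- binary * 1.0  # boxcar: slow sampling cannot resolve kinetics
  }
  phase <- stats::runif(n, 0, 2 * pi)
  p_drift <- max(120, config$duration_s / 3)
  drift <- outer(time_s, phase, function(t, ph)
    0.6 * sin(2 * pi * t / p_drift + ph)) +
    matrix(rep(2 * (time_s / config$duration_s - 0.5), n), n_t, n) * 0.4
  values <- pulse + config$drift_amp * drift +
    matrix(stats::rnorm(n_t * n, 0, config$noise_sd), n_t, n)
  colnames(values) <- sprintf("cell_%03d", seq_len(n) - 1L)

  ts <- new_trace_set(values, time_s, pos, fs, config$stim_onset_s,
                      config$mode)
  truth <- structure(list(module_label = module_label,
                          intrinsic_active_time = at,
                          intrinsic_response_time = delay,
                          initiator_flag = initiator_flag,
                          wave_log = wave_log,
                          binary = binary,
                          sustained_window = c(t_sus0, t_sus1),
                          config = config),
                     class = "islet_truth")
  list(traces = ts, truth = truth)
}

#' Construct a trace set
#'
#' The universal input container of the pipeline: a time x cell fluorescence
#' matrix with per-frame timestamps, per-cell positions and acquisition
#' metadata.
#'
#' @param values numeric time x cell matrix (a.u.).
#' @param time_s per-frame timestamps (s), strictly increasing and uniform.
#' @param positions N x 2 matrix of cell positions (um).
#' @param sampling_hz acquisition rate (Hz).
#' @param stim_onset_s stimulation onset (s).
#' @param mode `"scatter"` or `"grid"`.
#' @return object of class `trace_set`.
#' @export
new_trace_set <- function(values, time_s, positions, sampling_hz,
                          stim_onset_s, mode = "scatter") {
  values <- as.matrix(values)
  positions <- as.matrix(positions)
  colnames(positions) <- c("x_um", "y_um")
  ts <- structure(list(values = values, time_s = as.numeric(time_s),
                       positions = positions, sampling_hz = sampling_hz,
                       stim_onset_s = stim_onset_s, mode = mode),
                  class = "trace_set")
  assert_trace_set(ts)
  ts
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cells x %d frames @ %.3g Hz (%s mode), stim at %.1f s\n",
              ncol(x$values), nrow(x$values), x$sampling_hz, x$mode,
              x$stim_onset_s))
  invisible(x)
}

#' Write / read a trace set on disk
#'
#' The on-disk layout is three plain-text files in `dir`: `traces.csv`
#' (header `t,cell_000,...`, column `t` in seconds), `coords.csv`
#' (header `cell,x_um,y_um`) and `meta.json` (sampling rate, stimulation
#' onset, mode). Values round-trip at full double precision.
#'
#' @param ts a `trace_set`.
#' @param dir directory to write into (created if missing).
#' @return `write_traceset` returns `dir` invisibly; `read_traceset` returns
#'   the reconstructed `trace_set`.
#' @export
write_traceset <- function(ts, dir) {
  assert_trace_set(ts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 17 significant digits guarantee a bit-identical double round trip
  g17 <- function(x) sub("^\\s+", "", formatC(x, digits = 17, format = "g"))
  tr <- data.frame(t = g17(ts$time_s),
                   apply(ts$values, 2L, g17), check.names = FALSE)
  data.table::fwrite(tr, file.path(dir, "traces.csv"), quote = FALSE)
  co <- data.frame(cell = colnames(ts$values) %||%
                     sprintf("cell_%03d", seq_len(ncol(ts$values)) - 1L),
                   x_um = g17(ts$positions[, 1]), y_um = g17(ts$positions[, 2]))
  data.table::fwrite(co, file.path(dir, "coords.csv"), quote = FALSE)
  jsonlite::write_json(list(sampling_hz = ts$sampling_hz,
                            stim_onset_s = ts$stim_onset_s, mode = ts$mode),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(dir) {
  tr_path <- file.path(dir, "traces.csv")
  tr <- as.data.frame(data.table::fread(tr_path, check.names = FALSE))
  if (!identical(colnames(tr)[1], "t"))
    stop("parse error in ", tr_path, ": first column must be 't'")
  for (j in seq_along(tr)) {
    col <- suppressWarnings(as.numeric(tr[[j]]))
    if (anyNA(col))
      stop("parse error in ", tr_path, ": non-numeric or missing value at ",
           "row ", which(is.na(col))[1], ", column '", colnames(tr)[j], "'")
    tr[[j]] <- col
  }
  co <- as.data.frame(data.table::fread(file.path(dir, "coords.csv")))
  if (!all(c("cell", "x_um", "y_um") %in% colnames(co)))
    stop("parse error in coords.csv: expected header cell,x_um,y_um")
  if (anyNA(co$x_um) || anyNA(co$y_um))
    stop("parse error in coords.csv: missing coordinate")
  if (nrow(co) != ncol(tr) - 1L)
    stop("coords.csv lists ", nrow(co), " cells but traces.csv has ",
         ncol(tr) - 1L)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  values <- as.matrix(tr[, -1, drop = FALSE])
  new_trace_set(values, tr$t, cbind(as.numeric(co$x_um), as.numeric(co$y_um)),
                as.numeric(meta$sampling_hz), as.numeric(meta$stim_onset_s),
                meta$mode)
}

#' Write / read ground-truth labels
#'
#' Serializes an `islet_truth` (without the binary matrix, which is
#' reconstructable from the wave log and config) to `truth.json`.
#'
#' @param truth an `islet_truth` from [generate_islet()].
#' @param dir directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- truth[c("module_label", "intrinsic_active_time",
                 "intrinsic_response_time", "initiator_flag",
                 "sustained_window")]
  out$wave_log <- lapply(truth$wave_log, function(w)
    w[c("id", "cells", "times", "global", "seed")])
  jsonlite::write_json(out, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
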