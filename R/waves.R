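# Intercellular Ca2+ wave detection by space-time clustering of onset
# events, and wave-initiator scoring.

#' Default spatial link radius for wave detection
#'
#' Scatter mode: 1.5 times the median nearest-neighbour distance; grid mode:
#' 22 um (the local-neighbourhood radius used with a 15 um ISR mesh).
#'
#' @param positions N x 2 position matrix (um).
#' @param mode `"scatter"` or `"grid"`.
#' @return radius in um.
#' @export
default_wave_radius <- function(positions, mode = "scatter") {
  if (mode == "grid") return(22)
  d <- position_dist(positions)
  diag(d) <- Inf
  1.5 * stats::median(apply(d, 1L, min))
}

#' Detect intercellular waves by space-time clustering
#'
#' Every 0-to-1 transition is an onset event `(cell, time)`. Two events are
#' linked when the cells lie within `R_s` um of each other and the onsets are
#' within `R_t` s. Waves are the connected components of this link graph with
#' at least `min_wave_size` events. Within a component each cell contributes
#' its earliest event; members are ranked by activation time (ties by cell
#' index).
#'
#' @param ba a `binary_activity`.
#' @param positions N x 2 position matrix (um).
#' @param R_s spatial link radius (um).
#' @param R_t temporal link window (s).
#' @param min_wave_size minimal number of events for a component to count as
#'   a wave.
#' @param window optional `c(t0, t1)`; only onsets inside it are clustered.
#' @return object of class `wave_catalog`: list of waves (each with `id`,
#'   `cells`, `times`, `ranks`) plus the parameters used.
#' @export
detect_waves <- function(ba, positions,
                         R_s = default_wave_radius(positions),
                         R_t = 0.5, min_wave_size = 5, window = NULL) {
  stopifnot(inherits(ba, "binary_activity"))
  if (R_s <= 0 || R_t <= 0) stop("R_s and R_t must be positive")
  ev_cell <- rep(seq_along(ba$onsets), lengths(ba$onsets))
  ev_time <- unlist(ba$onsets, use.names = FALSE)
  if (!is.null(window)) {
    keep <- ev_time >= window[1] & ev_time < window[2]
    ev_cell <- ev_cell[keep]; ev_time <- ev_time[keep]
  }
  n_ev <- length(ev_time)
  empty <- structure(list(waves = list(),
                          params = list(R_s = R_s, R_t = R_t,
                                        min_wave_size = min_wave_size),
                          n_cells = ncol(ba$states), n_events = n_ev),
                     class = "wave_catalog")
  if (n_ev == 0L) return(empty)
  ord <- order(ev_time, ev_cell)
  ev_cell <- ev_cell[ord]; ev_time <- ev_time[ord]
  dmat <- position_dist(positions)
  # union-find over events; only time-sorted pairs within R_t are examined
  parent <- seq_len(n_ev)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  j0 <- 1L
  for (j in seq_len(n_ev)) {
    while (ev_time[j] - ev_time[j0] > R_t) j0 <- j0 + 1L
    if (j0 < j) for (k in j0:(j - 1L)) {
      if (dmat[ev_cell[k], ev_cell[j]] <= R_s) {
        rk <- find(k); rj <- find(j)
        if (rk != rj) parent[rk] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n_ev), find, integer(1))
  waves <- list()
  for (cc in unique(comp)) {
    sel <- which(comp == cc)
    if (length(sel) < min_wave_size) next
    cells <- ev_cell[sel]; times <- ev_time[sel]
    # one event per cell per wave: keep the earliest
    first <- !duplicated(cells)
    cells <- cells[first]; times <- times[first]
    o <- order(times, cells)
    waves[[length(waves) + 1L]] <-
      list(cells = cells[o], times = times[o], ranks = seq_along(o),
           n_events = length(sel))
  }
  if (length(waves) > 0L) {
    starts <- vapply(waves, function(w) w$times[1], numeric(1))
    waves <- waves[order(starts)]
    for (w in seq_along(waves)) waves[[w]]$id <- w
  }
  empty$waves <- waves
  empty$n_clustered_events <- sum(vapply(waves, `[[`, numeric(1), "n_events"))
  empty
}

#' @export
print.wave_catalog <- function(x, ...) {
  cat(sprintf("<wave_catalog> %d waves from %d onset events (R_s = %.1f um, R_t = %.2f s)\n",
              length(x$waves), x$n_events, x$params$R_s, x$params$R_t))
  invisible(x)
}

#' Score and flag wave-initiator cells
#'
#' For each wave the "first" set is the earliest
#' `max(1, ceiling(first_fraction * size))` activations. A cell's initiator
#' score is the share of waves it participated in where it was in the first
#' set. Initiators are the top 1/6 of cells by score (ties by cell index).
#'
#' @param wc a `wave_catalog`.
#' @param n_cells total number of cells.
#' @param first_fraction fraction of a wave counted as "first", in (0, 0.5].
#' @return list with `score` (per-cell fraction in `[0,1]`), `n_waves_in`
#'   (participation counts) and `initiator_flag`.
#' @export
initiator_scores <- function(wc, n_cells = wc$n_cells, first_fraction = 0.1) {
  stopifnot(inherits(wc, "wave_catalog"))
  if (first_fraction <= 0 || first_fraction > 0.5)
    stop("first_fraction must lie in (0, 0.5]")
  n_in <- n_first <- integer(n_cells)
  for (w in wc$waves) {
    size <- length(w$cells)
    k <- max(1L, ceiling(first_fraction * size))
    n_in[w$cells] <- n_in[w$cells] + 1L
    n_first[w$cells[seq_len(k)]] <- n_first[w$cells[seq_len(k)]] + 1L
  }
  score <- ifelse(n_in > 0L, n_first / pmax(n_in, 1L), 0)
  if (length(wc$waves) == 0L) {
    warning("empty wave catalog: all initiator scores are 0, no flags set")
    return(list(score = score, n_waves_in = n_in,
                initiator_flag = rep(FALSE, n_cells)))
  }
  list(score = score, n_waves_in = n_in,
       initiator_flag = top_fraction_flags(score))
}
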