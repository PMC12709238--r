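# Shared fixtures and oracles for the test suite. Everything is generated in
# code; heavier objects are built once per session and memoised here.

# A small, fast islet for unit tests (~40 cells, 4 min recording).
small_cfg <- function(seed = 1, ...) {
  islet_config(n_cells = 42, field_shape = c(65, 55), n_modules = 4,
               duration_s = 240, stim_onset_s = 40, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# Memoised generation keyed by deparsed config, so repeated tests reuse it.
get_islet <- function(cfg) {
  key <- paste(deparse(cfg[setdiff(names(cfg), "")]), collapse = "")
  key <- digest_key(key)
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- generate_islet(cfg)
  .fixture_env[[key]]
}

digest_key <- function(s) paste0("k", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))))

# Adjusted Rand index, written from the contingency-table definition --
# independent of any package implementation.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force connected components of an onset-event link graph: O(E^2)
# double loop, the oracle for detect_waves' union-find clustering.
brute_components <- function(cells, times, positions, R_s, R_t) {
  n <- length(cells)
  d <- as.matrix(stats::dist(positions))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          d[cells[i], cells[j]] <= R_s && abs(times[i] - times[j]) <= R_t) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Build a binary_activity object directly from a 0/1 state matrix, without
# going through binarize (which would refuse all-constant columns).
ba_from_states <- function(states, sampling_hz = 10) {
  states <- as.matrix(states)
  time_s <- (seq_len(nrow(states)) - 1) / sampling_hz
  onsets <- offsets <- vector("list", ncol(states))
  for (i in seq_len(ncol(states))) {
    r <- runs_of_ones_oracle(states[, i])
    onsets[[i]] <- time_s[r$start]
    offsets[[i]] <- time_s[r$end] + 1 / sampling_hz
  }
  structure(list(states = states, onsets = onsets, offsets = offsets,
                 time_s = time_s, sampling_hz = sampling_hz),
            class = "binary_activity")
}

# Naive loop version of run extraction, used as an oracle for binarization.
runs_of_ones_oracle <- function(s) {
  starts <- integer(); ends <- integer()
  inside <- FALSE
  for (i in seq_along(s)) {
    if (s[i] == 1 && !inside) { starts <- c(starts, i); inside <- TRUE }
    if (s[i] == 0 && inside) { ends <- c(ends, i - 1L); inside <- FALSE }
  }
  if (inside) ends <- c(ends, length(s))
  data.frame(start = starts, end = ends)
}

# Amplitude of the component of x at frequency f (Hz), by projection.
tone_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * f * t))) / length(x)
}
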