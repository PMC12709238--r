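# Spatial organization statistics: distance-binned parameter differences,
# same- vs different-community neighbourhood contrasts, hierarchical
# clustering overlap with network communities, equal-area concentric
# partitioning, and the Mann-Whitney U test.

#' Distance-binned mean absolute parameter differences
#'
#' For every unordered cell pair the absolute difference `|P_i - P_j|` of a
#' signalling parameter is accumulated into the distance bin
#' `d <= d_ij < d + delta_d`; the profile reports the per-bin mean, pair
#' count and standard error. Bins without pairs carry `NA`, not 0.
#'
#' @param values per-cell parameter vector, or a matrix/data.frame with one
#'   column per parameter.
#' @param positions N x 2 position matrix (um).
#' @param delta_d bin width (um); default 10 (scatter) / 15 (grid).
#' @param d_max upper distance limit (um); default the 90th percentile of
#'   pairwise distances.
#' @param mode `"scatter"` or `"grid"` (sets the default bin width).
#' @return data.frame of class `distance_profile` with columns `param`,
#'   `d_lo`, `d_hi`, `mean_abs_diff`, `n_pairs`, `se`.
#' @export
distance_binned_differences <- function(values, positions, delta_d = NULL,
                                        d_max = NULL, mode = "scatter") {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- if (ncol(values) == 1) "P" else
      paste0("P", seq_len(ncol(values)))
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 cells")
  if (is.null(delta_d)) delta_d <- if (mode == "grid") 15 else 10
  if (delta_d <= 0) stop("delta_d must be positive")
  dvec <- stats::dist(positions)
  if (max(dvec) <= .Machine$double.eps^0.5) {
    warning("all cells are co-located; returning a single degenerate bin")
    d_max <- delta_d
  }
  if (is.null(d_max)) d_max <- stats::quantile(dvec, 0.9, names = FALSE)
  edges <- seq(0, d_max + delta_d * 1e-9, by = delta_d)
  if (edges[length(edges)] < d_max) edges <- c(edges, edges[length(edges)] + delta_d)
  keep <- dvec < edges[length(edges)]
  bin <- findInterval(as.numeric(dvec)[keep], edges, rightmost.closed = FALSE)
  out <- list()
  for (p in colnames(values)) {
    adiff <- abs(stats::dist(values[, p]))[keep]
    n_pairs <- tabulate(bin, nbins = length(edges) - 1L)
    s1 <- vapply(seq_along(n_pairs), function(b) sum(adiff[bin == b]), 0)
    mean_ad <- ifelse(n_pairs > 0, s1 / n_pairs, NA_real_)
    se <- vapply(seq_along(n_pairs), function(b) {
      if (n_pairs[b] < 2) return(NA_real_)
      stats::sd(adiff[bin == b]) / sqrt(n_pairs[b])
    }, 0)
    out[[p]] <- data.frame(param = p, d_lo = edges[-length(edges)],
                           d_hi = edges[-1], mean_abs_diff = mean_ad,
                           n_pairs = n_pairs, se = se)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("distance_profile", "data.frame")
  res
}

#' Local neighbourhood radius
#'
#' Scatter mode: 1.5 times the islet-wide mean of each cell's mean distance
#' to its six closest neighbours. Grid mode (15 um ISR mesh): a fixed 22 um.
#' `reading = "global"` switches to the alternative interpretation, 1.5
#' times the mean of the six smallest intercellular distances in the islet.
#'
#' @param positions N x 2 position matrix (um).
#' @param mode `"scatter"` or `"grid"`.
#' @param reading `"per_cell"` (default) or `"global"`.
#' @return radius in um.
#' @export
neighborhood_radius <- function(positions, mode = "scatter",
                                reading = c("per_cell", "global")) {
  reading <- match.arg(reading)
  if (mode == "grid") return(22)
  n <- nrow(positions)
  if (n < 7) stop("need at least 7 cells to define a 6-neighbour radius")
  d <- position_dist(positions)
  diag(d) <- Inf
  if (reading == "global") {
    return(1.5 * mean(sort(d[upper.tri(d)])[1:6]))
  }
  nn_mean <- apply(d, 1L, function(row) mean(sort(row)[1:6]))
  1.5 * mean(nn_mean)
}

#' Same- vs different-community neighbourhood contrast
#'
#' For each cell, neighbours are the cells within radius `r`. The mean
#' absolute parameter difference to same-community neighbours and to
#' different-community neighbours is computed per cell (`NA` when a group is
#' empty), and the two per-cell distributions are compared with a two-sided
#' Mann-Whitney U test.
#'
#' @param values per-cell parameter vector.
#' @param positions N x 2 position matrix (um).
#' @param labels per-cell community labels (or a `community_partition`).
#' @param r neighbourhood radius (um), e.g. from [neighborhood_radius()].
#' @return list with `per_cell` (data.frame `same_mean`, `diff_mean`),
#'   `median_same`, `median_diff`, and `test` (`U`, `p`, or `NA` when no
#'   cell has both neighbour types).
#' @export
community_neighborhood_contrast <- function(values, positions, labels, r) {
  if (inherits(labels, "community_partition")) labels <- labels$labels
  if (r <= 0) stop("radius must be positive")
  n <- length(values)
  d <- position_dist(positions)
  same_mean <- diff_mean <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= r & seq_len(n) != i)
    if (length(nb) == 0L) next
    same <- nb[labels[nb] == labels[i]]
    diff <- nb[labels[nb] != labels[i]]
    if (length(same) > 0L) same_mean[i] <- mean(abs(values[same] - values[i]))
    if (length(diff) > 0L) diff_mean[i] <- mean(abs(values[diff] - values[i]))
  }
  a <- same_mean[!is.na(same_mean)]
  b <- diff_mean[!is.na(diff_mean)]
  test <- if (length(a) == 0L || length(b) == 0L) {
    warning("no cell has both same- and different-community neighbours; test skipped")
    list(U = NA_real_, p = NA_real_)
  } else mann_whitney_u(a, b)
  list(per_cell = data.frame(same_mean = same_mean, diff_mean = diff_mean),
       median_same = stats::median(a), median_diff = stats::median(b),
       test = test)
}

#' Hierarchical clustering of cells by position or signalling parameters
#'
#' Agglomerative clustering with average linkage on one of three pairwise
#' distance metrics -- Euclidean position distance, absolute active-time
#' difference, or absolute response-time difference -- cut to exactly
#' `n_clusters` groups (normally the number of detected network
#' communities).
#'
#' @param positions N x 2 position matrix (um).
#' @param values_active_time per-cell relative active time.
#' @param values_response_time per-cell response time (s).
#' @param metric `"euclidean"`, `"active_time"` or `"response_time"`.
#' @param n_clusters number of clusters to cut to.
#' @return integer vector of cluster labels.
#' @export
hierarchical_clusters <- function(positions, values_active_time = NULL,
                                  values_response_time = NULL,
                                  metric = c("euclidean", "active_time",
                                             "response_time"),
                                  n_clusters) {
  metric <- match.arg(metric)
  n <- nrow(positions)
  if (n_clusters < 1 || n_clusters > n)
    stop("n_clusters must lie in [1, N = ", n, "]")
  dd <- switch(metric,
               euclidean = stats::dist(positions),
               active_time = stats::dist(values_active_time),
               response_time = stats::dist(values_response_time))
  hc <- stats::hclust(dd, method = "average")
  as.integer(stats::cutree(hc, k = n_clusters))
}

# Maximum-agreement assignment between two label sets: given a contingency
# table, the best one-to-one matching of row labels to column labels and the
# number of cells on the matched diagonal. Exact for <= 7 labels by
# enumeration; larger problems use weighted bipartite matching (Hungarian
# method via igraph).
max_agreement <- function(tab) {
  r <- nrow(tab); c <- ncol(tab)
  k <- max(r, c)
  sq <- matrix(0, k, k)
  sq[seq_len(r), seq_len(c)] <- tab
  if (k <= 7) {
    perms <- permutations_of(k)
    best <- 0
    for (p in perms) {
      s <- sum(sq[cbind(seq_len(k), p)])
      if (s > best) best <- s
    }
    return(best)
  }
  g <- igraph::make_bipartite_graph(rep(c(FALSE, TRUE), each = k),
                                    edges = as.vector(rbind(
                                      rep(seq_len(k), each = k),
                                      rep(seq_len(k) + k, times = k))))
  w <- as.vector(t(sq))  # edge (i, j+k) in row-major order
  m <- igraph::max_bipartite_match(g, weights = w + 1e-9)
  s <- 0
  for (i in seq_len(k)) {
    j <- m$matching[i] - k
    if (!is.na(j) && j >= 1) s <- s + sq[i, j]
  }
  s
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) for (pos in seq_len(k)) {
    out[[idx]] <- append(p, k, after = pos - 1L)
    idx <- idx + 1L
  }
  out
}

#' Overlap between network communities and hierarchical clusters
#'
#' Cluster labels are aligned to community labels by maximum-agreement
#' one-to-one matching on the contingency table; the overlap proportion is
#' the fraction of cells whose aligned labels agree. A shuffle baseline
#' (cluster labels permuted, preserving group sizes) gives the expected
#' proportion under no association.
#'
#' @param communities per-cell community labels (or `community_partition`).
#' @param clusters per-cell cluster labels.
#' @param n_shuffle number of label shufflings for the baseline.
#' @param seed seed for the shuffle baseline.
#' @return list with `proportion_matched`, `baseline_random`, `baseline_sd`.
#' @export
overlap_proportion <- function(communities, clusters, n_shuffle = 200,
                               seed = 1) {
  if (inherits(communities, "community_partition"))
    communities <- communities$labels
  if (length(communities) != length(clusters))
    stop("communities and clusters must label the same cells")
  n <- length(communities)
  prop <- function(cl) max_agreement(table(communities, cl)) / n
  p_obs <- prop(clusters)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  p_null <- vapply(seq_len(n_shuffle), function(i) prop(sample(clusters)), 0)
  list(proportion_matched = p_obs, baseline_random = mean(p_null),
       baseline_sd = stats::sd(p_null))
}

#' Partition an islet into equal-area concentric regions
#'
#' The convex hull of the cell positions is scaled about its centroid by
#' factors `sqrt(i / n_regions)`, producing nested contours whose annuli all
#' have the same area (hull area / n_regions, exactly, by the scaling
#' argument). Region 1 is the innermost disc; hull-boundary cells fall in
#' region `n_regions`.
#'
#' @param positions N x 2 position matrix (um).
#' @param n_regions number of regions (default 8).
#' @return object of class `region_partition`: `region_label` (1 =
#'   innermost), `contour_scales`, `region_areas` (um^2), `hull_area`.
#' @export
concentric_partition <- function(positions, n_regions = 8) {
  n <- nrow(positions)
  hull <- grDevices::chull(positions)
  if (length(hull) < 3) stop("degenerate convex hull: cells are collinear")
  vx <- positions[hull, 1]; vy <- positions[hull, 2]
  # shoelace area and polygon centroid
  k <- length(hull)
  nx <- c(vx[-1], vx[1]); ny <- c(vy[-1], vy[1])
  cross <- vx * ny - nx * vy
  area <- abs(sum(cross)) / 2
  if (area <= .Machine$double.eps^0.5) stop("degenerate convex hull")
  sgn <- sign(sum(cross))
  cx <- sum((vx + nx) * cross) / (6 * area) * sgn
  cy <- sum((vy + ny) * cross) / (6 * area) * sgn
  # minimal scale factor sigma(p): p lies inside the hull scaled by s about
  # the centroid iff s >= sigma(p); per edge, sigma >= n.(p - c) / n.(v - c)
  sigma <- rep(0, n)
  for (e in seq_len(k)) {
    ex <- nx[e] - vx[e]; ey <- ny[e] - vy[e]
    nrm <- c(ey, -ex) * sgn  # outward normal
    num <- nrm[1] * (positions[, 1] - cx) + nrm[2] * (positions[, 2] - cy)
    den <- nrm[1] * (vx[e] - cx) + nrm[2] * (vy[e] - cy)
    sigma <- pmax(sigma, num / den)
  }
  sigma <- pmin(sigma, 1)
  region <- pmax(1L, as.integer(ceiling(n_regions * sigma^2 - 1e-12)))
  structure(list(region_label = region,
                 contour_scales = sqrt(seq_len(n_regions) / n_regions),
                 region_areas = rep(area / n_regions, n_regions),
                 hull_area = area, centroid = c(cx, cy),
                 n_regions = n_regions),
            class = "region_partition")
}

#' Distribution of a flagged subpopulation across concentric regions
#'
#' Reports, per region, the fraction of all flagged cells that fall in it
#' (summing to 1) and the enrichment relative to the region's share of all
#' cells (1 = proportional representation).
#'
#' @param rp a `region_partition`.
#' @param flags per-cell logical subpopulation flags.
#' @return data.frame with columns `region`, `n_cells`, `n_flagged`,
#'   `fraction`, `enrichment`.
#' @export
subpopulation_by_region <- function(rp, flags) {
  stopifnot(inherits(rp, "region_partition"))
  if (length(flags) != length(rp$region_label))
    stop("flags and region partition must cover the same cells")
  if (sum(flags) == 0) stop("no flagged cells")
  n <- length(flags)
  regions <- seq_len(rp$n_regions)
  n_cells <- tabulate(rp$region_label, nbins = rp$n_regions)
  n_flag <- tabulate(rp$region_label[flags], nbins = rp$n_regions)
  fraction <- n_flag / sum(flags)
  enrichment <- ifelse(n_cells > 0, fraction / (n_cells / n), NA_real_)
  data.frame(region = regions, n_cells = n_cells, n_flagged = n_flag,
             fraction = fraction, enrichment = enrichment)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. `U` is the smaller of the two
#' sample statistics (0 under complete separation). The two-sided p value
#' uses exact enumeration of rank assignments when both samples have at most
#' 8 observations and no ties are present, otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param a,b numeric samples.
#' @return list with `U`, `p`, and `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  ties <- any(duplicated(c(a, b)))
  if (!ties && na <= 8 && nb <= 8) {
    # exact null distribution of U by enumeration of rank assignments
    idx <- utils::combn(n, na)
    us <- colSums(matrix(rank(seq_len(n))[idx], nrow = na)) -
      na * (na + 1) / 2
    # folding U to min(U_a, U_b) already pools both tails, so the two-sided
    # p is the plain tail probability of the folded statistic
    us <- pmin(us, na * nb - us)
    p <- min(1, mean(us <= u))
    return(list(U = u, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  tt <- table(c(a, b))
  tie_term <- sum(tt^3 - tt) / (n * (n - 1))
  s2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (s2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (abs(ua - mu) - 0.5) / sqrt(s2)
  z <- max(z, 0)
  list(U = u, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}
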