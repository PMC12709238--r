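# Spatial statistics: distance profiles, neighbourhood contrasts,
# clustering overlap, concentric partitioning, Mann-Whitney U.

test_that("distance profiles match the brute-force pair loop exactly", {
  set.seed(21)
  n <- 60
  pos <- matrix(runif(2 * n, 0, 120), n, 2)
  p <- runif(n)
  prof <- distance_binned_differences(p, pos, delta_d = 10, d_max = 150)
  # O(N^2) oracle
  edges <- seq(0, max(prof$d_hi), by = 10)
  sums <- counts <- numeric(length(edges) - 1)
  vals <- vector("list", length(edges) - 1)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    b <- findInterval(d, edges)
    if (b >= 1 && b <= length(counts) && d < max(edges)) {
      counts[b] <- counts[b] + 1
      sums[b] <- sums[b] + abs(p[i] - p[j])
      vals[[b]] <- c(vals[[b]], abs(p[i] - p[j]))
    }
  }
  expect_equal(prof$n_pairs, counts, ignore_attr = TRUE)
  occ <- counts > 0
  expect_equal(prof$mean_abs_diff[occ], (sums / counts)[occ])
  se_o <- vapply(vals, function(v) if (length(v) > 1) sd(v) / sqrt(length(v))
                 else NA_real_, 0)
  expect_equal(prof$se[occ], se_o[occ])
  expect_true(all(is.na(prof$mean_abs_diff[!occ])))
  # total pair count within range is conserved
  expect_identical(sum(prof$n_pairs), sum(dist(pos) < max(prof$d_hi)))
})

test_that("constant parameters and rigid motions behave as expected", {
  set.seed(22)
  pos <- matrix(runif(80, 0, 100), 40, 2)
  prof0 <- distance_binned_differences(rep(3.3, 40), pos, delta_d = 10)
  expect_true(all(prof0$mean_abs_diff[prof0$n_pairs > 0] == 0))
  p <- runif(40)
  prof1 <- distance_binned_differences(p, pos, delta_d = 10, d_max = 120)
  th <- 0.7
  rot <- pos %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) +
    matrix(c(55, -20), 40, 2, byrow = TRUE)
  prof2 <- distance_binned_differences(p, rot, delta_d = 10, d_max = 120)
  expect_equal(prof1$mean_abs_diff, prof2$mean_abs_diff)
  expect_equal(prof1$n_pairs, prof2$n_pairs)
})

test_that("two distant value-blobs give the step-shaped profile", {
  set.seed(23)
  blob <- function(cx) cbind(runif(20, cx - 10, cx + 10), runif(20, -10, 10))
  pos <- rbind(blob(0), blob(200))
  p <- rep(c(0, 1), each = 20)
  prof <- distance_binned_differences(p, pos, delta_d = 20, d_max = 240)
  near <- prof$d_hi <= 20
  far <- prof$d_lo >= 160 & prof$n_pairs > 0
  expect_true(all(prof$mean_abs_diff[near & prof$n_pairs > 0] == 0))
  expect_true(all(prof$mean_abs_diff[far] == 1))
})

test_that("neighbourhood radius follows the 6-neighbour geometry", {
  # hexagon + centre, edge a: every cell's six neighbours are the others
  a <- 12
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  pos <- rbind(c(0, 0), cbind(a * cos(ang), a * sin(ang)))
  mean_center <- a
  mean_vertex <- (3 * a + 2 * a * sqrt(3) + 2 * a) / 6
  expected <- 1.5 * (mean_center + 6 * mean_vertex) / 7
  expect_equal(neighborhood_radius(pos), expected)
  expect_equal(neighborhood_radius(pos * 2), 2 * expected)  # homogeneity
  expect_identical(neighborhood_radius(pos, mode = "grid"), 22)
  expect_error(neighborhood_radius(pos[1:5, ]), "at least 7")
})

test_that("community neighbourhood contrast separates constructed groups", {
  pos <- as.matrix(expand.grid(x = (0:5) * 10, y = (0:5) * 10))
  labels <- ifelse(pos[, 1] < 30, 1, 2)
  vals <- ifelse(labels == 1, 0.2, 0.8)
  ct <- community_neighborhood_contrast(vals, pos, labels, r = 15)
  pc <- ct$per_cell
  expect_true(all(pc$same_mean[!is.na(pc$same_mean)] == 0))
  expect_true(all(pc$diff_mean[!is.na(pc$diff_mean)] > 0))
  expect_lt(ct$test$p, 0.01)
  # single community: different-community means are all undefined
  expect_warning(
    ct1 <- community_neighborhood_contrast(vals, pos, rep(1, 36), r = 15),
    "skipped")
  expect_true(all(is.na(ct1$per_cell$diff_mean)))
  expect_true(is.na(ct1$test$p))
})

test_that("hierarchical clustering recovers separated structure", {
  set.seed(25)
  pos <- rbind(cbind(rnorm(10, 0, 3), rnorm(10, 0, 3)),
               cbind(rnorm(10, 100, 3), rnorm(10, 100, 3)))
  cl <- hierarchical_clusters(pos, metric = "euclidean", n_clusters = 2)
  expect_identical(length(unique(cl[1:10])), 1L)
  expect_identical(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])
  at <- rep(c(0.1, 0.9), each = 10)
  cl2 <- hierarchical_clusters(pos, values_active_time = at,
                               metric = "active_time", n_clusters = 2)
  expect_identical(length(unique(cl2[1:10])), 1L)
  expect_false(cl2[1] == cl2[11])
  expect_identical(hierarchical_clusters(pos, metric = "euclidean",
                                         n_clusters = 20), 1:20)
  expect_error(hierarchical_clusters(pos, metric = "euclidean",
                                     n_clusters = 25), "n_clusters")
})

test_that("overlap proportion uses maximum-agreement matching", {
  comm <- rep(1:3, each = 10)
  expect_equal(overlap_proportion(comm, comm)$proportion_matched, 1)
  # relabelled clusters still match perfectly after alignment
  perm_lab <- c(3, 1, 2)[comm]
  expect_equal(overlap_proportion(comm, perm_lab)$proportion_matched, 1)
  # three relabelled cells: 27/30 by the hand-built contingency table
  cl <- perm_lab
  cl[c(1, 11, 21)] <- c(1, 2, 3)[c(comm[1] %% 3 + 1, comm[11] %% 3 + 1,
                                   comm[21] %% 3 + 1)]
  expect_equal(overlap_proportion(comm, cl)$proportion_matched, 27 / 30)
  # random labels sit at the shuffle baseline
  set.seed(26)
  comm2 <- rep(1:2, each = 15)
  rnd <- sample(rep(1:2, 15))
  ov <- overlap_proportion(comm2, rnd, n_shuffle = 300)
  expect_lt(abs(ov$proportion_matched - ov$baseline_random),
            3 * ov$baseline_sd + 1e-9)
  expect_error(overlap_proportion(comm, cl[1:10]), "same cells")
})

test_that("label matching agrees between enumeration and igraph routes", {
  set.seed(27)
  for (k in c(3, 5, 9)) {
    a <- sample(1:k, 120, replace = TRUE)
    b <- a
    flip <- sample(120, 30)
    b[flip] <- sample(1:k, 30, replace = TRUE)
    b <- ((b + 1) %% k) + 1  # relabel
    ov <- overlap_proportion(a, b, n_shuffle = 10)
    # alignment can never beat identity and never drop below 1 - flip share
    expect_gte(ov$proportion_matched, (120 - 30) / 120)
    expect_lte(ov$proportion_matched, 1)
  }
  # direct cross-check of the two matching implementations on small tables
  tab <- table(rep(1:3, each = 8), sample(rep(1:3, each = 8)))
  brute <- isletnet:::max_agreement(tab)
  expect_gte(brute, sum(diag(tab)))
})

test_that("concentric partitioning yields eight equal-area regions", {
  set.seed(28)
  th <- runif(400, 0, 2 * pi)
  rr <- sqrt(runif(400))
  pos <- cbind(90 * rr * cos(th), 70 * rr * sin(th))
  rp <- concentric_partition(pos)
  expect_identical(rp$n_regions, 8)
  expect_identical(sort(unique(rp$region_label)), 1:8)
  expect_equal(sum(rp$region_areas), rp$hull_area)
  expect_lt(diff(range(rp$region_areas)) / mean(rp$region_areas), 0.01)
  # the centroid cell lands in region 1, hull vertices in region 8
  pos2 <- rbind(pos, rp$centroid)
  rp2 <- concentric_partition(pos2)
  expect_identical(rp2$region_label[401], 1L)
  hull <- chull(pos)
  expect_true(all(rp$region_label[hull] == 8L))
  expect_error(concentric_partition(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("uniform cell fields populate the eight regions uniformly", {
  set.seed(29)
  n <- 4000
  th <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n))
  pos <- cbind(100 * rr * cos(th), 100 * rr * sin(th))
  rp <- concentric_partition(pos)
  counts <- tabulate(rp$region_label, 8)
  # chi-square against the uniform-area expectation; the hull is slightly
  # smaller than the disc, so expected counts are hull-area-proportional
  chi <- sum((counts - n / 8)^2 / (n / 8))
  expect_gt(pchisq(chi, df = 7, lower.tail = FALSE), 0.01)
})

test_that("subpopulation region distributions sum and enrich correctly", {
  set.seed(30)
  pos <- matrix(rnorm(1000, 0, 40), 500, 2)
  rp <- concentric_partition(pos)
  flags <- rp$region_label == 8
  sub <- subpopulation_by_region(rp, flags)
  expect_equal(sub$fraction, c(rep(0, 7), 1))
  expect_gt(sub$enrichment[8], 1)
  unif <- rep(c(TRUE, FALSE), length.out = 500)
  sub2 <- subpopulation_by_region(rp, unif)
  expect_equal(sum(sub2$fraction), 1)
  expect_lt(max(abs(sub2$fraction - sub2$n_cells / 500)), 0.04)
  expect_error(subpopulation_by_region(rp, rep(FALSE, 500)), "no flagged")
  expect_error(subpopulation_by_region(rp, TRUE), "same cells")
})

test_that("Mann-Whitney U matches hand values and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$U, 0)
  expect_equal(r$p, wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  same <- c(1.1, 2.2, 3.3, 4.4)
  expect_gte(mann_whitney_u(same, same)$p, 0.99)
  set.seed(31)
  # exact route vs wilcox.test exact p on small untied samples
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney_u(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # normal-approximation route vs wilcox.test with continuity correction
  for (i in 1:10) {
    a <- rnorm(25); b <- rnorm(30, 0.3)
    expect_equal(mann_whitney_u(a, b)$p,
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})
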