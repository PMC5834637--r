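# Shared fixture builders: everything is generated in code at test time.

# a labelled point mix: clustered nests (truth) plus a uniform artifact field
# at the package's default study conditions
labelled_detections <- function(seed, extent = 200, artifact_intensity = 0.003,
                                n_subcolonies = 4, nests_per_subcolony = 150) {
  lay <- generate_colony_layout(c(0, extent, 0, extent), n_subcolonies,
                                nests_per_subcolony, cluster_radius = 3,
                                hardcore = 0.7, seed = seed)
  art <- withr::with_seed(seed + 10000, {
    n <- rpois(1, artifact_intensity * extent^2)
    data.frame(x = runif(n, 0, extent), y = runif(n, 0, extent))
  })
  pts <- rbind(
    data.frame(x = lay$nests$x, y = lay$nests$y, class = "nest"),
    data.frame(x = art$x, y = art$y, class = "artifact"))
  list(points = pts,
       detections = detection_set(pts$x, pts$y, raster_id = lay$island_id))
}

# brute-force O(n^2) oracles
oracle_knn <- function(xy, k = 1) {
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  unname(apply(d, 1, function(r) sort(r)[k]))
}

oracle_filter_keep <- function(xy, r, m) {
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  apply(d, 1, function(row) sum(row <= r) >= m)
}

# greedy one-to-one matching of detections to truth at a radius (metres)
match_truth <- function(truth_xy, det_xy, radius = 0.5) {
  if (nrow(det_xy) == 0 || nrow(truth_xy) == 0) return(0L)
  d2 <- outer(truth_xy[, 1], det_xy[, 1], `-`)^2 +
    outer(truth_xy[, 2], det_xy[, 2], `-`)^2
  used <- rep(FALSE, nrow(det_xy))
  matched <- 0L
  for (i in seq_len(nrow(truth_xy))) {
    j <- which.min(ifelse(used, Inf, d2[i, ]))
    if (length(j) && d2[i, j] <= radius^2) {
      matched <- matched + 1L
      used[j] <- TRUE
    }
  }
  matched
}

# dyadic (binary-exact) scene spectra so arithmetic identities hold exactly
dyadic_spectra <- list(guano = c(b1 = 0.5, b2 = 0.75),
                       nonguano = c(b1 = 0.25, b2 = 0.125))
dyadic_offsets <- c(b1 = 0.0625, b2 = -0.25)
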