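# Tiling and the difference-of-Gaussians candidate detector.

test_that("tiling partitions the raster exactly", {
  o <- orthomosaic(matrix(runif(1024 * 1024), 1024, 1024), gsd = 0.05,
                   origin = c(0, 51.2))
  tiles <- tile_raster(o, 512)
  expect_length(tiles, 4)

  o2 <- orthomosaic(matrix(runif(513 * 512), 513, 512), gsd = 0.05,
                    origin = c(0, 25.65))
  tiles2 <- tile_raster(o2, 512)
  expect_length(tiles2, 2)
  expect_identical(nrow(tiles2[[2]]$pixels), 1L)

  # pixel conservation on an awkward size
  o3 <- orthomosaic(matrix(runif(300 * 170), 300, 170), gsd = 0.1,
                    origin = c(0, 30))
  tiles3 <- tile_raster(o3, 128)
  expect_equal(sum(vapply(tiles3, function(t) sum(t$pixels), 0)),
               sum(o3$pixels))
  expect_error(tile_raster(o3, 16), ">= 32")
})

test_that("a blank raster yields an empty detection set", {
  o <- orthomosaic(matrix(0, 200, 200), gsd = 0.05, origin = c(0, 10))
  det <- detect_candidates(o)
  expect_s3_class(det, "detection_set")
  expect_identical(nrow(det), 0L)
})

test_that("a single noiseless nest is detected once, at its position", {
  lay <- generate_colony_layout(c(0, 10, 0, 10), 0, 0, seed = 1)
  lay$nests <- data.frame(x = 5.13, y = 4.71, subcolony = 1L)
  rnd <- render_orthomosaic(lay, gsd = 0.05, seed = 1)
  det <- detect_candidates(rnd$ortho)
  expect_identical(nrow(det), 1L)
  expect_lt(sqrt((det$x - 5.13)^2 + (det$y - 4.71)^2), 0.12 / 2)
  expect_true(all(det$score >= 0 & det$score <= 1))
})

test_that("raising the threshold never increases detections", {
  lay <- generate_colony_layout(c(0, 40, 0, 40), 2, 60, seed = 5)
  rnd <- render_orthomosaic(lay, gsd = 0.05, artifact_intensity = 0.005,
                            noise_sd = 0.02, seed = 6)
  counts <- vapply(c(0.002, 0.01, 0.05, 0.1, 0.2),
                   function(th) nrow(detect_candidates(rnd$ortho,
                                                       threshold = th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("seam merging collapses duplicates and is a fixed point", {
  s1 <- detection_set(1, 1, 0.9, raster_id = "r")
  s2 <- detection_set(1.0001, 1.0001, 0.7, raster_id = "r")
  m <- merge_tile_detections(list(s1, s2), merge_radius = 0.3)
  expect_identical(nrow(m), 1L)
  expect_equal(m$score, 0.9)

  far <- merge_tile_detections(
    list(detection_set(c(0, 1), c(0, 0), raster_id = "r")),
    merge_radius = 0.3)
  expect_identical(nrow(far), 2L)

  pts <- withr::with_seed(11, detection_set(runif(120, 0, 10),
                                            runif(120, 0, 10),
                                            raster_id = "r"))
  once <- merge_tile_detections(pts, merge_radius = 0.6)
  twice <- merge_tile_detections(once, merge_radius = 0.6)
  expect_lte(nrow(once), nrow(pts))
  expect_equal(as.data.frame(once), as.data.frame(twice))

  expect_error(merge_tile_detections(
    list(detection_set(1, 1, raster_id = "a"),
         detection_set(2, 2, raster_id = "b"))), "different rasters")
})

test_that("tiled detection equals full-raster detection up to the merge
           radius", {
  lay <- generate_colony_layout(c(0, 40, 0, 40), 2, 60, seed = 5)
  rnd <- render_orthomosaic(lay, gsd = 0.05, artifact_intensity = 0.005,
                            noise_sd = 0.02, seed = 6)
  # same seam-duplicate merge applied to both paths
  full <- merge_tile_detections(detect_candidates(rnd$ortho),
                                merge_radius = 0.35)
  tiled <- detect_island(rnd$ortho, tile_size = 256, halo = 16,
                         merge_radius = 0.35)
  expect_identical(nrow(full), nrow(tiled))
  o1 <- as.data.frame(full)[order(full$x, full$y), c("x", "y")]
  o2 <- as.data.frame(tiled)[order(tiled$x, tiled$y), c("x", "y")]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("detection on a rendered colony recovers nearly every nest", {
  lay <- generate_colony_layout(c(0, 80, 0, 80), 2, 150, seed = 13,
                                island_id = "recall")
  rnd <- render_orthomosaic(lay, gsd = 0.05, artifact_intensity = 0.003,
                            noise_sd = 0.02, seed = 14)
  det <- detect_island(rnd$ortho)
  matched <- match_truth(as.matrix(lay$nests[, c("x", "y")]),
                         as.matrix(as.data.frame(det)[, c("x", "y")]),
                         radius = 0.5)
  expect_gte(matched / nrow(lay$nests), 0.95)
})
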