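# Colony-layout, rendering, observer and scene generators.

test_that("zero sub-colonies give an empty layout", {
  lay <- generate_colony_layout(c(0, 10, 0, 10), 0, 50, seed = 1)
  expect_s3_class(lay, "colony_layout")
  expect_identical(nrow(lay$nests), 0L)
})

test_that("hard-core spacing and containment hold (all-pairs oracle)", {
  lay <- generate_colony_layout(c(0, 30, 0, 30), 1, 80, cluster_radius = 3,
                                hardcore = 0.7, seed = 7)
  xy <- as.matrix(lay$nests[, c("x", "y")])
  expect_gt(nrow(xy), 0)
  d <- dist(xy)
  expect_gte(min(d), 0.7)
  expect_true(all(xy[, 1] >= 0 & xy[, 1] <= 30 &
                    xy[, 2] >= 0 & xy[, 2] <= 30))
  expect_false(anyNA(lay$nests$subcolony))
})

test_that("layouts are seed-deterministic and seed-sensitive", {
  a <- generate_colony_layout(c(0, 40, 0, 40), 2, 60, seed = 3)
  b <- generate_colony_layout(c(0, 40, 0, 40), 2, 60, seed = 3)
  c <- generate_colony_layout(c(0, 40, 0, 40), 2, 60, seed = 4)
  expect_identical(a$nests, b$nests)
  expect_false(identical(a$nests, c$nests))
})

test_that("infeasible packing fails loudly instead of truncating", {
  expect_error(
    generate_colony_layout(c(0, 3, 0, 3), 1, 500, cluster_radius = 1,
                           hardcore = 0.7, seed = 1, tries_per_nest = 20),
    "infeasible packing")
})

test_that("rendering places each nest as a blob at its world position", {
  lay <- generate_colony_layout(c(0, 10, 0, 10), 0, 0, seed = 1)
  lay$nests <- data.frame(x = 4.2, y = 6.8, subcolony = 1L)
  rnd <- render_orthomosaic(lay, gsd = 0.05, artifact_intensity = 0,
                            noise_sd = 0, seed = 2)
  expect_identical(nrow(rnd$artifacts), 0L)
  px <- rnd$ortho$pixels
  peak <- which(px == max(px), arr.ind = TRUE)[1, ]
  w <- pixel_to_world(rnd$ortho, peak["row"], peak["col"])
  # brightest pixel within half a blob width (2 sigma) of the nest
  expect_lt(sqrt((w[1] - 4.2)^2 + (w[2] - 6.8)^2), 2 * 0.12)
})

test_that("sub-pixel blobs are refused with advice", {
  lay <- generate_colony_layout(c(0, 10, 0, 10), 1, 5, seed = 1)
  expect_error(render_orthomosaic(lay, gsd = 1), "lower the gsd")
})

test_that("artifact count doubles in expectation when the extent doubles", {
  n_art <- function(extent_x, seed) {
    lay <- generate_colony_layout(c(0, extent_x, 0, 10), 0, 0, seed = 1)
    nrow(render_orthomosaic(lay, gsd = 0.25, artifact_intensity = 0.5,
                            seed = seed)$artifacts)
  }
  n1 <- vapply(1:200, function(s) n_art(10, s), 0L)
  n2 <- vapply(1:200, function(s) n_art(20, 10000 + s), 0L)
  # means 50 and 100; difference within 3 standard errors of the doubling
  se <- sqrt(var(n2) / 200 + 4 * var(n1) / 200)
  expect_lt(abs(mean(n2) - 2 * mean(n1)), 3 * se)
})

test_that("observer counts: noiseless identity, pure bias, cv recovery", {
  expect_identical(simulate_observer_count(100, observer_model(cv = 0)), 100L)
  expect_identical(
    simulate_observer_count(100, observer_model(cv = 0, bias = 1.1)), 110L)
  draws <- simulate_observer_count(rep(1000, 1000),
                                   observer_model(cv = 0.05), seed = 9)
  expect_gt(sd(draws) / mean(draws), 0.04)
  expect_lt(sd(draws) / mean(draws), 0.06)
  expect_error(simulate_observer_count(-1, observer_model()), ">= 0")
  expect_error(observer_model(cv = -0.1), "cv")
})

test_that("scene pairs: noiseless identity, exact constant shift, noisy mean", {
  truth <- matrix(rep(c(TRUE, FALSE), length.out = 64^2), 64, 64)
  zero <- setNames(c(0, 0), names(dyadic_offsets))
  p0 <- generate_scene_pair(truth, dyadic_spectra, zero, noise_sd = 0,
                            seed = 1)
  expect_identical(p0$reference$bands, p0$offset$bands)
  p1 <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                            noise_sd = 0, seed = 1)
  expect_true(all(p1$offset$bands$b1 - p1$reference$bands$b1 == 0.0625))
  p2 <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                            noise_sd = 0.01, seed = 2)
  for (b in names(dyadic_offsets)) {
    md <- mean(p2$offset$bands[[b]] - p2$reference$bands[[b]])
    expect_lt(abs(md - dyadic_offsets[[b]]), 0.002)
  }
  expect_error(
    generate_scene_pair(truth, dyadic_spectra, c(b1 = 0, wrong = 0)),
    "band names")
})

test_that("nest NN distances are stochastically smaller than artifact NN
           distances at matched intensity", {
  nest_d <- artifact_d <- numeric(0)
  for (s in 1:5) {
    lay <- generate_colony_layout(c(0, 60, 0, 60), 2, 80, seed = s)
    n <- nrow(lay$nests)
    art <- withr::with_seed(s + 500,
      data.frame(x = runif(n, 0, 60), y = runif(n, 0, 60)))
    nest_d <- c(nest_d, nn_distances(lay$nests))
    artifact_d <- c(artifact_d, nn_distances(art))
  }
  w <- wilcox.test(nest_d, artifact_d, alternative = "less")
  expect_lt(w$p.value, 1e-10)
})
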