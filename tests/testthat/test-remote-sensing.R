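# Cross-sensor calibration, guano classification and grid reduction.

mk_truth <- function(n = 64) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= (n / 4)^2)
}

test_that("offsets are exact on noiseless pairs and zero between identical
           scenes", {
  truth <- mk_truth()
  zero <- setNames(c(0, 0), names(dyadic_offsets))
  p0 <- generate_scene_pair(truth, dyadic_spectra, zero, noise_sd = 0,
                            seed = 1)
  expect_identical(estimate_offsets(p0$offset, p0$reference)$offsets, zero)

  p1 <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                            noise_sd = 0, seed = 1)
  est <- estimate_offsets(p1$offset, p1$reference)
  expect_identical(est$offsets, dyadic_offsets)

  expect_error(estimate_offsets(p1$offset, p1$reference,
                                mask = matrix(FALSE, 64, 64)), "empty")
  bad <- p1$reference
  names(bad$bands) <- c("b1", "zz")
  expect_error(estimate_offsets(p1$offset, bad), "band names")
})

test_that("offset estimation under noise lands within sampling error", {
  truth <- mk_truth()
  errs <- sapply(1:6, function(s) {
    p <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                             noise_sd = 0.01, seed = 100 + s)
    estimate_offsets(p$offset, p$reference)$offsets - dyadic_offsets
  })
  se_pooled <- 0.01 * sqrt(2) / sqrt(64 * 64) / sqrt(6)
  expect_true(all(abs(rowMeans(errs)) < 2 * se_pooled))
})

test_that("applying offsets is the exact inverse when noiseless and a
           contraction under noise", {
  truth <- mk_truth()
  p1 <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                            noise_sd = 0, seed = 1)
  est <- estimate_offsets(p1$offset, p1$reference)
  adj <- apply_offsets(p1$offset, est)
  expect_identical(adj$bands, p1$reference$bands)
  zero_after <- estimate_offsets(adj, p1$reference)$offsets
  expect_identical(unname(zero_after), c(0, 0))

  pn <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                            noise_sd = 0.02, seed = 5)
  pre <- abs(estimate_offsets(pn$offset, pn$reference)$offsets -
               0 * dyadic_offsets)
  adjn <- apply_offsets(pn$offset, estimate_offsets(pn$offset, pn$reference))
  post <- abs(estimate_offsets(adjn, pn$reference)$offsets)
  expect_true(all(post < pre))

  # zero offsets are the identity
  z <- estimate_offsets(pn$reference, pn$reference)
  expect_identical(apply_offsets(pn$reference, z)$bands, pn$reference$bands)
})

test_that("guano classification is exact when classes are separable and
           degrades monotonically with noise", {
  truth <- mk_truth()
  p <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                           noise_sd = 0, seed = 1)
  mask <- classify_guano(p$reference, params = list(spectra = dyadic_spectra))
  expect_identical(mask$cells, truth)

  blank <- generate_scene_pair(matrix(FALSE, 32, 32), dyadic_spectra,
                               dyadic_offsets, noise_sd = 0, seed = 1)
  empty <- classify_guano(blank$reference,
                          params = list(spectra = dyadic_spectra))
  expect_identical(sum(empty$cells), 0L)

  acc <- vapply(c(0.02, 0.06, 0.12, 0.25), function(ns) {
    m <- classify_guano(
      generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                          noise_sd = ns, seed = 9)$reference,
      params = list(spectra = dyadic_spectra))
    mean(m$cells == truth)
  }, 0)
  expect_gte(acc[1], 0.99)
  expect_true(all(diff(acc) <= 0.002))

  expect_error(classify_guano(p$reference), "untrained")
})

test_that("grid reduction applies the majority rule to masks and polygons", {
  fine <- guano_mask(matrix(TRUE, 9, 9), cell_size = 10)
  red <- reduce_to_grid(fine, 30)
  expect_identical(dim(red$cells), c(3L, 3L))
  expect_true(all(red$cells))

  expect_error(reduce_to_grid(guano_mask(matrix(TRUE, 2, 2), 7), 30),
               "integer multiple")

  # 40% coverage of one coarse cell stays unset at the 0.5 rule,
  # 60% coverage is set

  poly_cell <- cbind(c(0, 30, 30, 0), c(0, 0, 30, 30))
  expect_identical(sum(reduce_to_grid(poly_cell, 30)$cells), 1L)
  poly_40 <- cbind(c(0, 12, 12, 0), c(0, 0, 30, 30))
  expect_identical(sum(reduce_to_grid(poly_40, 30)$cells), 0L)
  poly_60 <- cbind(c(0, 18, 18, 0), c(0, 0, 30, 30))
  expect_identical(sum(reduce_to_grid(poly_60, 30)$cells), 1L)
})

test_that("gridded polygon area is within a perimeter ring of the true area", {
  poly <- cbind(c(3, 247, 247, 3), c(7, 7, 152, 152))
  g <- reduce_to_grid(poly, 30)
  true_area <- 244 * 145
  perim <- 2 * (244 + 145)
  expect_lt(abs(guano_area(g) - true_area), perim * 30)
})

test_that("grid reduction is idempotent on the target grid", {
  m <- guano_mask(withr::with_seed(4, matrix(runif(100) > 0.6, 10, 10)),
                  cell_size = 30)
  expect_identical(reduce_to_grid(m, 30)$cells, m$cells)
})

test_that("epoch comparison reports areas, ratios and cell turnover", {
  a <- guano_mask(withr::with_seed(5, matrix(runif(400) > 0.5, 20, 20)),
                  30, epoch = "1957")
  same <- compare_epochs(list(a, guano_mask(a$cells, 30, "1990")))
  expect_equal(same$changes$ratio, 1)
  expect_identical(same$changes$gained, 0L)
  expect_identical(same$changes$lost, 0L)

  b_cells <- a$cells
  b_cells[which(!a$cells)[1:10]] <- TRUE
  plus10 <- compare_epochs(list(a, guano_mask(b_cells, 30, "2000")))
  expect_identical(plus10$changes$gained, 10L)
  expect_identical(plus10$changes$lost, 0L)

  r <- guano_mask(withr::with_seed(6, matrix(runif(400) > 0.5, 20, 20)),
                  30, "2015")
  cmp <- compare_epochs(list(a, r))
  expect_identical(cmp$changes$gained - cmp$changes$lost,
                   sum(r$cells) - sum(a$cells))
  expect_error(compare_epochs(list(a, guano_mask(matrix(TRUE, 5, 5), 30))),
               "common grid")
})

test_that("scenes and masks survive TIFF round trips", {
  truth <- mk_truth(32)
  p <- generate_scene_pair(truth, dyadic_spectra, dyadic_offsets,
                           noise_sd = 0.01, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_ms_scene(p$reference, tf)
  back <- read_ms_scene(tf)
  expect_identical(names(back$bands), names(p$reference$bands))
  expect_lt(max(abs(back$bands$b1 - p$reference$bands$b1)), 1e-7)
  expect_identical(back$cell_size, p$reference$cell_size)

  m <- guano_mask(truth, 30, epoch = "1957")
  tm <- withr::local_tempfile(fileext = ".tif")
  write_guano_mask(m, tm)
  m2 <- read_guano_mask(tm)
  expect_identical(m2$cells, m$cells)
  expect_identical(m2$epoch, "1957")
})
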