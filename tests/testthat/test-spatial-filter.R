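# Nearest-neighbour statistics and the false-positive filter.

test_that("nn_distances matches hand cases and the brute-force oracle", {
  expect_equal(nn_distances(data.frame(x = c(0, 1), y = c(0, 0))), c(1, 1))
  expect_equal(nn_distances(data.frame(x = c(0, 1, 3), y = 0)), c(1, 1, 2))
  xy <- withr::with_seed(21, cbind(x = runif(100, 0, 50),
                                   y = runif(100, 0, 50)))
  for (k in 1:3)
    expect_equal(sort(nn_distances(as.data.frame(xy), k = k)),
                 sort(oracle_knn(xy, k)))
  expect_error(nn_distances(data.frame(x = 1, y = 1)), "at least 2")
  expect_error(nn_distances(data.frame(x = c(1, 2), y = c(1, 2)), k = 2),
               "at least 3")
})

test_that("fixed rules pass through verbatim; quantile follows the
           midpoint-interpolation percentile convention", {
  rule <- fit_filter_rule(NULL, method = "fixed",
                          params = list(r = 1.2, m = 2))
  expect_equal(rule$r, 1.2)
  expect_identical(rule$m, 2L)

  # isolated pairs: three at spacing 1 and three at spacing 2, so the 1-NN
  # distance multiset is {1 x6, 2 x6} and the 50th percentile interpolates
  # to the midpoint 1.5
  pts <- data.frame(
    x = c(0, 1, 100, 101, 200, 201, 0, 2, 100, 102, 200, 202),
    y = rep(c(0, 300), each = 6))
  expect_equal(sort(nn_distances(pts)), rep(c(1, 2), each = 6))
  rq <- fit_filter_rule(pts, method = "quantile", params = list(q = 0.5))
  expect_equal(rq$r, 1.5)
  # q may equivalently be given in percent
  rq2 <- fit_filter_rule(pts, method = "quantile", params = list(q = 50))
  expect_equal(rq2$r, 1.5)
})

test_that("degenerate distance distributions fall back with a warning", {
  grid <- expand.grid(x = seq(0, 9) * 2, y = seq(0, 9) * 2)
  expect_warning(rule <- fit_filter_rule(grid, method = "quantile"),
                 "degenerate")
  expect_equal(rule$r, 1.5)
  expect_match(rule$method, "fallback")
})

test_that("mixture crossover lands between the two classes' NN medians", {
  lab <- labelled_detections(seed = 31)
  rule <- fit_filter_rule(lab$detections, method = "mixture")
  nests <- lab$points[lab$points$class == "nest", ]
  arts <- lab$points[lab$points$class == "artifact", ]
  expect_gt(rule$r, median(nn_distances(nests)))
  expect_lt(rule$r, median(nn_distances(arts)))
})

test_that("apply_filter partitions the input and matches the O(n^2) oracle", {
  # a single isolated point has no neighbours
  single <- detection_set(5, 5)
  out <- apply_filter(single, filter_rule(10, m = 1))
  expect_identical(nrow(out$retained), 0L)
  expect_identical(nrow(out$rejected), 1L)

  # regular grid at spacing d with r > d keeps everything
  grid <- expand.grid(x = seq(0, 9), y = seq(0, 9))
  gd <- detection_set(grid$x, grid$y)
  out <- apply_filter(gd, filter_rule(1.1, m = 1))
  expect_identical(nrow(out$retained), 100L)

  lab <- labelled_detections(seed = 41)
  rule <- fit_filter_rule(lab$detections)
  flt <- apply_filter(lab$detections, rule)
  expect_identical(nrow(flt$retained) + nrow(flt$rejected),
                   nrow(lab$detections))
  keep <- oracle_filter_keep(as.matrix(lab$points[, c("x", "y")]),
                             rule$r, rule$m)
  expect_equal(as.data.frame(flt$retained)[, c("x", "y")],
               lab$points[keep, c("x", "y")], ignore_attr = TRUE)
  # rejected mostly artifacts, retained mostly nests
  expect_gt(mean(lab$points$class[!keep] == "artifact"), 0.5)
  expect_gt(mean(lab$points$class[keep] == "nest"), 0.9)
})

test_that("filtering never increases counts, is deterministic, and is
           single-pass (re-application may erode further)", {
  lab <- labelled_detections(seed = 51)
  rule <- fit_filter_rule(lab$detections)
  a <- apply_filter(lab$detections, rule)
  b <- apply_filter(lab$detections, rule)
  expect_identical(as.data.frame(a$retained), as.data.frame(b$retained))
  expect_lte(nrow(a$retained), nrow(lab$detections))
  again <- apply_filter(a$retained, rule)
  expect_lte(nrow(again$retained), nrow(a$retained))
})

test_that("filter rules survive a JSON round trip", {
  rule <- filter_rule(3.21, 2, "mixture")
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_rule(rule, path)
  expect_equal(read_filter_rule(path), rule)
})
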