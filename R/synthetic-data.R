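#' Simulate a clustered, hard-core colony layout
#'
#' Nesting penguins are strongly spatially structured: nests aggregate into
#' discrete sub-colonies, but territorial pecking distance keeps any two
#' nests at least a hard-core radius apart. The generator draws sub-colony
#' (parent) centres uniformly over the extent, scatters offspring nests
#' around each centre with an isotropic Gaussian displacement of scale
#' `cluster_radius`, and thins proposals that fall within `hardcore` metres
#' of an already accepted nest (a Matern-III style dart throw). Proposals
#' falling outside the extent are redrawn, so the invariants — all nests in
#' the extent, all pairwise distances >= `hardcore` — hold by construction.
#'
#' If the requested intensity cannot be packed at the given hard-core radius
#' the dart-throw budget (`tries_per_nest` proposals per requested nest) is
#' exhausted and the generator fails loudly rather than silently truncating.
#'
#' @param extent numeric length-4, `(xmin, xmax, ymin, ymax)` in metres.
#' @param n_subcolonies number of sub-colony centres.
#' @param nests_per_subcolony mean nests per sub-colony (Poisson-distributed
#'   per sub-colony).
#' @param cluster_radius Gaussian displacement scale of nests around their
#'   sub-colony centre, metres. Must exceed `hardcore`.
#' @param hardcore minimum allowed nest-to-nest distance, metres (> 0).
#' @param seed integer seed; the same seed reproduces the layout exactly.
#' @param island_id identifier carried through the pipeline.
#' @param tries_per_nest dart-throw budget per requested nest.
#' @param parent_margin inset of sub-colony centres from the extent edge,
#'   metres (default twice the cluster radius, clamped to fit small
#'   extents). Real sub-colonies sit back from the shoreline; the inset also
#'   keeps a corner-truncated cluster disk from making the requested
#'   intensity unpackable.
#' @return A `colony_layout`: list with `island_id`, `nests` (data.frame
#'   `x`, `y`, `subcolony`), and `extent`.
#' @export
#' @examples
#' lay <- generate_colony_layout(c(0, 40, 0, 40), n_subcolonies = 2,
#'                               nests_per_subcolony = 50, seed = 1)
#' nrow(lay$nests)
generate_colony_layout <- function(extent, n_subcolonies,
                                   nests_per_subcolony = 150,
                                   cluster_radius = 3, hardcore = 0.7,
                                   seed = NULL, island_id = "island",
                                   tries_per_nest = 500,
                                   parent_margin = 2 * cluster_radius) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (hardcore <= 0) stop("hardcore radius must be > 0")
  if (hardcore >= cluster_radius)
    stop("hardcore must be smaller than cluster_radius")
  n_subcolonies <- as.integer(n_subcolonies)

  nests <- with_seed(seed, {
    if (n_subcolonies == 0) {
      data.frame(x = numeric(0), y = numeric(0), subcolony = integer(0))
    } else {
      mx <- min(parent_margin, 0.25 * (extent[2] - extent[1]))
      my <- min(parent_margin, 0.25 * (extent[4] - extent[3]))
      px <- runif(n_subcolonies, extent[1] + mx, extent[2] - mx)
      py <- runif(n_subcolonies, extent[3] + my, extent[4] - my)
      target <- rpois(n_subcolonies, nests_per_subcolony)
      xs <- ys <- numeric(sum(target))
      sc <- integer(sum(target))
      n_acc <- 0L
      for (j in seq_len(n_subcolonies)) {
        acc_j <- 0L
        tries <- 0L
        budget <- max(1000L, tries_per_nest * target[j])
        while (acc_j < target[j] && tries < budget) {
          tries <- tries + 1L
          cx <- px[j] + rnorm(1, 0, cluster_radius)
          cy <- py[j] + rnorm(1, 0, cluster_radius)
          if (cx < extent[1] || cx > extent[2] ||
              cy < extent[3] || cy > extent[4]) next
          if (n_acc > 0L) {
            d2 <- (xs[seq_len(n_acc)] - cx)^2 + (ys[seq_len(n_acc)] - cy)^2
            if (min(d2) < hardcore^2) next
          }
          n_acc <- n_acc + 1L
          acc_j <- acc_j + 1L
          xs[n_acc] <- cx
          ys[n_acc] <- cy
          sc[n_acc] <- j
        }
        if (acc_j < target[j])
          stop(sprintf(paste0(
            "infeasible packing: sub-colony %d placed %d of %d nests before ",
            "exhausting the dart-throw budget; enlarge the extent, reduce ",
            "nests_per_subcolony, or reduce the hard-core radius"),
            j, acc_j, target[j]))
      }
      data.frame(x = xs[seq_len(n_acc)], y = ys[seq_len(n_acc)],
                 subcolony = sc[seq_len(n_acc)])
    }
  })

  structure(list(island_id = as.character(island_id), nests = nests,
                 extent = as.numeric(extent),
                 params = list(cluster_radius = cluster_radius,
                               hardcore = hardcore, seed = seed)),
            class = "colony_layout")
}

#' @export
print.colony_layout <- function(x, ...) {
  cat(sprintf("colony_layout '%s': %d nests in %d sub-colonies\n",
              x$island_id, nrow(x$nests),
              length(unique(x$nests$subcolony))))
  invisible(x)
}

#' @export
plot.colony_layout <- function(x, ...) {
  cols <- hcl.colors(max(1, length(unique(x$nests$subcolony))), "Dark 3")
  plot(x$nests$x, x$nests$y, col = cols[x$nests$subcolony], pch = 16,
       cex = 0.5, asp = 1, xlab = "x (m)", ylab = "y (m)",
       main = x$island_id,
       xlim = x$extent[1:2], ylim = x$extent[3:4], ...)
  invisible(x)
}

#' Render an orthomosaic-like raster from a colony layout
#'
#' Each nest is painted as a compact isotropic Gaussian blob at its world
#' position. False-positive sources — rocks, shadows and other artifacts that
#' look like nesting birds from above — are drawn from a homogeneous Poisson
#' process over the extent and rendered with the *same* blob appearance
#' (the worst case for any detector, which is why they must be removed by
#' spatial structure, not appearance). Additive Gaussian pixel noise is
#' applied last. The artifact ground-truth points are returned alongside the
#' raster so detector and filter performance can be scored.
#'
#' @param layout a [generate_colony_layout()] result.
#' @param gsd metres per pixel (> 0).
#' @param artifact_intensity artifacts per square metre (homogeneous Poisson
#'   intensity; 0 disables artifacts).
#' @param blob_params list with `sigma` (Gaussian blob scale, metres) and
#'   `amplitude` (peak pixel value).
#' @param noise_sd additive pixel-noise standard deviation.
#' @param seed integer seed.
#' @return List with `ortho` (an [orthomosaic()]) and `artifacts`
#'   (data.frame `x`, `y` of artifact truth points).
#' @export
render_orthomosaic <- function(layout, gsd = 0.05, artifact_intensity = 0,
                               blob_params = list(sigma = 0.12, amplitude = 1),
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(layout, "colony_layout"))
  if (gsd <= 0) stop("gsd must be > 0")
  sigma <- blob_params$sigma %||% 0.12
  amplitude <- blob_params$amplitude %||% 1
  if (4 * sigma < gsd)
    stop(sprintf(paste0(
      "blob diameter (%.3f m) is below one pixel at gsd %.3f m/px; ",
      "lower the gsd or increase blob sigma"), 4 * sigma, gsd))

  ext <- layout$extent
  ncol_px <- max(1L, ceiling((ext[2] - ext[1]) / gsd))
  nrow_px <- max(1L, ceiling((ext[4] - ext[3]) / gsd))
  origin <- c(ext[1], ext[4])

  out <- with_seed(seed, {
    area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
    n_art <- if (artifact_intensity > 0) rpois(1, artifact_intensity * area) else 0L
    artifacts <- data.frame(
      x = runif(n_art, ext[1], ext[2]),
      y = runif(n_art, ext[3], ext[4]))

    m <- matrix(0, nrow_px, ncol_px)
    pts <- rbind(as.matrix(layout$nests[, c("x", "y")]),
                 as.matrix(artifacts))
    if (nrow(pts) > 0) {
      rad_px <- ceiling(4 * sigma / gsd)
      off <- seq(-rad_px, rad_px)
      for (i in seq_len(nrow(pts))) {
        # continuous pixel position of the point (pixel-centre convention)
        pc <- (pts[i, 1] - origin[1]) / gsd + 0.5
        pr <- (origin[2] - pts[i, 2]) / gsd + 0.5
        rows <- round(pr) + off
        cols <- round(pc) + off
        rok <- rows >= 1 & rows <= nrow_px
        cok <- cols >= 1 & cols <= ncol_px
        if (!any(rok) || !any(cok)) next
        rr <- rows[rok]; cc <- cols[cok]
        d2 <- outer((rr - pr)^2, (cc - pc)^2, `+`) * gsd^2
        m[rr, cc] <- m[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
      }
    }
    if (noise_sd > 0)
      m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow_px, ncol_px)
    list(m = m, artifacts = artifacts)
  })

  list(ortho = orthomosaic(out$m, gsd = gsd, origin = origin,
                           island_id = layout$island_id),
       artifacts = out$artifacts)
}

#' Observer model for manual counts
#'
#' A human counting a section of colony is modelled as a truncated-normal
#' draw on the count scale: mean `bias * n`, standard deviation
#' `cv * bias * n`, truncated at zero and rounded to an integer.
#'
#' @param cv relative standard deviation of a single count (>= 0).
#' @param bias multiplicative bias (1 = unbiased, > 0).
#' @return An `observer_model` list.
#' @export
observer_model <- function(cv = 0.03, bias = 1) {
  if (cv < 0) stop("cv must be >= 0")
  if (bias <= 0) stop("bias must be > 0")
  structure(list(cv = cv, bias = bias), class = "observer_model")
}

#' Simulate one (or several) manual counts
#'
#' @param true_count non-negative true number of nests; may be a vector, in
#'   which case one count is drawn per element.
#' @param observer an [observer_model()].
#' @param seed integer seed.
#' @return Integer vector of simulated counts, same length as `true_count`.
#' @export
#' @examples
#' simulate_observer_count(100, observer_model(cv = 0), seed = 1)  # 100
simulate_observer_count <- function(true_count, observer = observer_model(),
                                    seed = NULL) {
  if (any(true_count < 0)) stop("true_count must be >= 0")
  mu <- observer$bias * true_count
  if (observer$cv == 0) return(as.integer(round(mu)))
  with_seed(seed, {
    as.integer(round(rnorm_trunc0(length(mu), mu, observer$cv * mu)))
  })
}

#' Generate a paired pair of multispectral scenes from two "sensors"
#'
#' Emulates cross-sensor differences between satellite platforms: a
#' reference scene is built from per-class band means over a boolean guano
#' truth grid plus Gaussian noise; the second scene shares the class-mean
#' structure but adds a constant per-band offset (the inter-sensor
#' difference to be removed by cross-calibration) and independent noise.
#'
#' @param guano_truth logical matrix; `TRUE` cells are guano.
#' @param spectra list with elements `guano` and `nonguano`, each a named
#'   numeric vector of band reflectance means on identical band names.
#' @param sensor_offsets named numeric vector of per-band additive offsets;
#'   names must match the spectra bands.
#' @param noise_sd per-pixel reflectance noise standard deviation.
#' @param cell_size cell size in metres (default 30, the Landsat grid).
#' @param seed integer seed.
#' @return List with `reference` and `offset`, both [ms_scene()] objects.
#' @export
generate_scene_pair <- function(guano_truth, spectra, sensor_offsets,
                                noise_sd = 0.01, cell_size = 30,
                                seed = NULL) {
  bands <- names(spectra$guano)
  if (is.null(bands) || !identical(sort(bands), sort(names(spectra$nonguano))))
    stop("spectra must define guano and nonguano means on identical band names")
  if (!identical(sort(bands), sort(names(sensor_offsets))))
    stop("sensor_offsets band names do not match the spectra bands")
  guano_truth <- as.matrix(guano_truth)
  storage.mode(guano_truth) <- "logical"

  with_seed(seed, {
    mk <- function(offsets) {
      bl <- lapply(bands, function(b) {
        base <- ifelse(guano_truth, spectra$guano[[b]], spectra$nonguano[[b]]) +
          offsets[[b]]
        if (noise_sd > 0)
          base <- base + matrix(rnorm(length(base), 0, noise_sd),
                                nrow(guano_truth), ncol(guano_truth))
        base
      })
      names(bl) <- bands
      bl
    }
    zero <- setNames(rep(0, length(bands)), bands)
    list(
      reference = ms_scene(mk(zero), sensor_id = "reference",
                           cell_size = cell_size),
      offset = ms_scene(mk(sensor_offsets[bands]), sensor_id = "offset",
                        cell_size = cell_size))
  })
}
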