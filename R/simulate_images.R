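#' Specification for synthetic fluorescence images
#'
#' Describes a 2-D image composed of a constant background, an optional
#' autofluorescence template, diffraction-limited Gaussian spots, an
#' optional exponential intensity gradient around a contour, and i.i.d.
#' Gaussian noise. All coordinates are 0-based pixel centers in
#' `(row, col)` order.
#'
#' @param image_size Integer vector `c(rows, cols)`.
#' @param n_spots Number of planted spots.
#' @param spot_amplitude Peak height of each Gaussian spot.
#' @param spot_sigma Gaussian spot standard deviation in pixels.
#' @param background_level Constant background intensity.
#' @param autofluorescence Optional real matrix added to the background
#'   (scaled by `autofluorescence_scale`).
#' @param autofluorescence_scale Multiplier for the template.
#' @param gradient Optional list `list(lambda, contour, amplitude)`: adds
#'   `amplitude * exp(-d / lambda)` where `d` is the distance (pixels)
#'   from the contour polyline (matrix with columns `row`, `col`).
#' @param roi Optional polygon (matrix with columns `row`, `col`) inside
#'   which spots are placed; default: whole image with a 3-sigma margin.
#' @param min_separation Minimum distance between spot centers in pixels
#'   (default `6 * spot_sigma`): two Gaussian spots separated by `s` have
#'   a saddle at `2 * exp(-(s / (2 * sigma))^2 / 2)` of the peak, so they
#'   are resolved by a component caller with a half-peak global threshold
#'   only for `s` well above `4.7 * sigma`; the generator plants spots a
#'   component-based method can count at all. Set to 0 for unconstrained
#'   placement.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `ImageSimSpec`.
#' @export
image_sim_spec <- function(image_size = c(128, 128), n_spots = 50,
                           spot_amplitude = 10, spot_sigma = 1.5,
                           background_level = 1,
                           autofluorescence = NULL,
                           autofluorescence_scale = 1,
                           gradient = NULL, roi = NULL,
                           min_separation = 6 * spot_sigma, noise_sd = 1,
                           seed = 1) {
  stopifnot(length(image_size) == 2L, all(image_size >= 4))
  assert_scalar_number(n_spots, "n_spots", 0)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  if (!is.null(autofluorescence) &&
      !all(dim(autofluorescence) == image_size)) {
    stopf("autofluorescence template must match image_size")
  }
  if (!is.null(gradient)) {
    if (is.null(gradient$lambda) || is.null(gradient$contour)) {
      stopf("gradient needs `lambda` and `contour`")
    }
    if (nrow(as.matrix(gradient$contour)) < 2L) {
      stopf("degenerate contour: need at least 2 points")
    }
    if (is.null(gradient$amplitude)) gradient$amplitude <- 1
  }
  structure(list(image_size = as.integer(image_size), n_spots = n_spots,
                 spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
                 background_level = background_level,
                 autofluorescence = autofluorescence,
                 autofluorescence_scale = autofluorescence_scale,
                 gradient = gradient, roi = roi,
                 min_separation = min_separation, noise_sd = noise_sd,
                 seed = seed),
            class = "ImageSimSpec")
}

# Rasterize a polygon (columns row, col; 0-based pixel centers) to a
# logical mask using the even-odd crossing rule, vectorized over pixels.
polygon_mask <- function(nrow, ncol, poly) {
  poly <- as.matrix(poly)
  pr <- poly[, 1]; pc <- poly[, 2]
  n <- length(pr)
  rows <- rep(seq_len(nrow) - 1, times = ncol)
  cols <- rep(seq_len(ncol) - 1, each = nrow)
  inside <- rep(FALSE, nrow * ncol)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((pr[i] > rows) != (pr[j] > rows)) &
      (cols < (pc[j] - pc[i]) * (rows - pr[i]) / (pr[j] - pr[i]) + pc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow, ncol)
}

# Distance from every pixel center to a polyline (columns row, col),
# i.e. the minimum point-to-segment distance over all segments.
pixel_distance_to_polyline <- function(nrow, ncol, polyline) {
  p <- as.matrix(polyline)
  if (nrow(p) < 2L) stopf("degenerate contour: need at least 2 points")
  rows <- rep(seq_len(nrow) - 1, times = ncol)
  cols <- rep(seq_len(ncol) - 1, each = nrow)
  d2 <- rep(Inf, nrow * ncol)
  for (i in seq_len(nrow(p) - 1L)) {
    a <- p[i, ]; b <- p[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      di <- (rows - a[1])^2 + (cols - a[2])^2
    } else {
      t <- ((rows - a[1]) * ab[1] + (cols - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      di <- (rows - (a[1] + t * ab[1]))^2 + (cols - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, di)
  }
  matrix(sqrt(d2), nrow, ncol)
}

#' Generate an image of diffraction-limited spots
#'
#' The image equals `background + scale * autofluorescence +
#' sum of Gaussian spots + Gaussian noise`; the true spot centers are
#' recorded in the ground truth.
#'
#' @param spec An [image_sim_spec()].
#' @return A list with `image` (matrix) and `truth` (spot centers as a
#'   matrix with columns `row`, `col`, plus the noiseless image).
#' @export
generate_spot_image <- function(spec) {
  stopifnot(inherits(spec, "ImageSimSpec"))
  with_seed(spec$seed, {
    nr <- spec$image_size[1]; nc <- spec$image_size[2]
    img <- matrix(spec$background_level, nr, nc)
    if (!is.null(spec$autofluorescence)) {
      img <- img + spec$autofluorescence_scale * spec$autofluorescence
    }
    margin <- 3 * spec$spot_sigma
    if (!is.null(spec$roi)) {
      mask <- polygon_mask(nr, nc, spec$roi)
      ok <- which(mask, arr.ind = TRUE) - 1L
      if (spec$n_spots > 0 && nrow(ok) == 0L) {
        stopf("ROI contains no pixels for spot placement")
      }
    }
    centers <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("row", "col")))
    if (spec$n_spots > 0) {
      draw_one <- function() {
        if (is.null(spec$roi)) {
          c(runif(1, margin, nr - 1 - margin),
            runif(1, margin, nc - 1 - margin))
        } else {
          ok[sample(nrow(ok), 1), ] + runif(2, -0.5, 0.5)
        }
      }
      # rejection sampling to honor the minimum spot separation
      kept <- matrix(NA_real_, spec$n_spots, 2)
      n_kept <- 0L
      tries <- 0L
      while (n_kept < spec$n_spots) {
        cand <- draw_one()
        tries <- tries + 1L
        if (tries > 200L * spec$n_spots) {
          stopf("cannot place %d spots at min_separation %g; reduce one",
                spec$n_spots, spec$min_separation)
        }
        if (n_kept > 0L && spec$min_separation > 0) {
          dmin <- min(sqrt(rowSums(sweep(kept[seq_len(n_kept), ,
                                              drop = FALSE], 2,
                                         cand)^2)))
          if (dmin < spec$min_separation) next
        }
        n_kept <- n_kept + 1L
        kept[n_kept, ] <- cand
      }
      centers <- kept
      colnames(centers) <- c("row", "col")
      if (any(centers[, 1] < 0 | centers[, 1] > nr - 1 |
              centers[, 2] < 0 | centers[, 2] > nc - 1)) {
        stopf("spot center outside image bounds")
      }
      rows <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
      cols <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
      for (i in seq_len(spec$n_spots)) {
        img <- img + spec$spot_amplitude *
          exp(-((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2) /
                (2 * spec$spot_sigma^2))
      }
    }
    clean <- img
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    list(image = img, truth = list(centers = centers, clean = clean,
                                   spec = spec))
  })
}

#' Generate an image with an exponential gradient around a contour
#'
#' Intensity is `background + amplitude * exp(-d / lambda)` where `d` is
#' the pixel's distance from the contour polyline, plus Gaussian noise —
#' emulating a signal concentrated near a tubule that decays into the
#' surrounding niche.
#'
#' @param spec An [image_sim_spec()] with the `gradient` field set.
#' @return A list with `image` and `truth` (the distance field, contour,
#'   and decay length).
#' @export
generate_gradient_image <- function(spec) {
  stopifnot(inherits(spec, "ImageSimSpec"))
  if (is.null(spec$gradient)) stopf("spec$gradient must be set")
  with_seed(spec$seed, {
    nr <- spec$image_size[1]; nc <- spec$image_size[2]
    g <- spec$gradient
    d <- pixel_distance_to_polyline(nr, nc, g$contour)
    clean <- spec$background_level + g$amplitude * exp(-d / g$lambda)
    img <- clean
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    list(image = img,
         truth = list(distance = d, contour = as.matrix(g$contour),
                      lambda = g$lambda, clean = clean, spec = spec))
  })
}
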