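#' Annotated multi-channel image
#'
#' Bundles co-registered 2-D fluorescence channels with the manual
#' annotations used by the quantification routines. All geometry is in
#' 0-based pixel-center coordinates, `(row, col)` order; conversion to
#' micrometers happens only at reporting via `pixel_size`.
#'
#' @param channels Named list of numeric matrices sharing dimensions.
#' @param pixel_size Micrometers per pixel (optional).
#' @param roi Region of interest: logical mask or polygon (matrix with
#'   columns `row`, `col`).
#' @param ub_contour Ordered polyline along the tubule of interest
#'   (first point = top of the niche, near the cortex edge).
#' @param cross_sections Optional list of hand-drawn cross-section
#'   polylines.
#' @return An object of class `AnnotatedImage`.
#' @export
annotated_image <- function(channels, pixel_size = NULL, roi = NULL,
                            ub_contour = NULL, cross_sections = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  dims <- dim(channels[[1]])
  for (ch in channels) {
    if (!all(dim(ch) == dims)) stopf("all channels must share dimensions")
  }
  if (!is.null(ub_contour) && nrow(as.matrix(ub_contour)) < 2L) {
    stopf("contour needs at least 2 points")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 roi = roi, ub_contour = ub_contour,
                 cross_sections = cross_sections, dim = dims),
            class = "AnnotatedImage")
}

# Resolve an ROI argument (logical mask, polygon, or NULL) to a mask.
resolve_roi <- function(roi, nr, nc) {
  if (is.null(roi)) return(matrix(TRUE, nr, nc))
  if (is.logical(roi)) {
    if (!all(dim(roi) == c(nr, nc))) stopf("ROI mask dimension mismatch")
    return(roi)
  }
  polygon_mask(nr, nc, roi)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological
#' opening of the image with a disk of the given radius (the standard
#' surrogate for a rolling ball: structures smaller than the disk are
#' removed from the background and therefore preserved in the output)
#' and subtracts it, clipping at zero.
#'
#' @param image Numeric matrix.
#' @param radius Ball radius in pixels (>= 1; 3 for smFISH spots, 100
#'   for immunostaining in the standard workflow).
#' @return Background-subtracted matrix.
#' @export
rolling_ball_subtract <- function(image, radius) {
  image <- as.matrix(image)
  assert_scalar_number(radius, "radius", 1)
  if (2 * radius + 1 >= min(dim(image))) {
    stopf("radius %g too large for a %d x %d image", radius,
          nrow(image), ncol(image))
  }
  rng <- range(image)
  if (diff(rng) == 0) return(matrix(0, nrow(image), ncol(image)))
  # grayscale morphology operates on [0, 1]; rescale around it
  scaled <- (image - rng[1]) / diff(rng)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  bg <- as.matrix(EBImage::opening(scaled, brush)) * diff(rng) + rng[1]
  out <- image - bg
  out[out < 0] <- 0
  out
}

#' Autofluorescence subtraction using a GFP reference channel
#'
#' Estimates the scale of the autofluorescent component as the
#' least-squares regression (through the origin) of the channel on the
#' GFP channel over ROI background pixels — pixels below the channel's
#' spot threshold — and subtracts the scaled GFP image, clipping at 0.
#'
#' @param channel Numeric matrix (signal channel).
#' @param gfp Numeric matrix (autofluorescence reference), co-registered.
#' @param roi Optional ROI (mask or polygon).
#' @param threshold Spot threshold separating background pixels;
#'   `"otsu"` (default) or a number.
#' @return The corrected channel, with attribute `alpha` (the fitted
#'   scale).
#' @export
subtract_autofluorescence <- function(channel, gfp, roi = NULL,
                                      threshold = "otsu") {
  channel <- as.matrix(channel); gfp <- as.matrix(gfp)
  if (!all(dim(channel) == dim(gfp))) stopf("channels must be co-registered")
  if (all(gfp == 0)) {
    warnf("GFP channel is all zero; returning the input unchanged")
    out <- channel
    attr(out, "alpha") <- 0
    return(out)
  }
  mask <- resolve_roi(roi, nrow(channel), ncol(channel))
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(channel[mask])
  } else {
    as.numeric(threshold)
  }
  bgpix <- mask & channel <= thr
  if (!any(bgpix)) bgpix <- mask
  denom <- sum(gfp[bgpix]^2)
  alpha <- if (denom > 0) sum(channel[bgpix] * gfp[bgpix]) / denom else 0
  out <- channel - alpha * gfp
  out[out < 0] <- 0
  attr(out, "alpha") <- alpha
  out
}

# Triangle (Zack) threshold on a numeric vector: anchor a line from the
# histogram peak to its far end and take the bin farthest from it. The
# histogram is computed on pixels above the minimum (background
# subtraction clips at zero, leaving an artifactual spike there) and
# lightly smoothed so single-bin spikes cannot anchor the peak. Suited
# to spot images, whose histograms are unimodal with a long signal tail.
triangle_threshold <- function(v, levels = 256) {
  rng <- range(v)
  if (diff(rng) == 0) {
    stopf(paste("all pixels identical; the global threshold is undefined -",
                "supply an absolute threshold"))
  }
  v <- v[v > rng[1]]
  if (length(unique(v)) == 1L) return(v[1])
  br <- seq(min(v), max(v), length.out = levels + 1)
  h <- hist(v, breaks = br, plot = FALSE)
  n_bin <- length(h$counts)
  cnt <- vapply(seq_len(n_bin), function(i) {
    mean(h$counts[max(1, i - 2):min(n_bin, i + 2)])
  }, numeric(1))
  mids <- h$mids
  pk <- which.max(cnt)
  last <- max(which(cnt > 0))
  if (last <= pk) return(mids[pk])
  xs <- pk:last
  xn <- (xs - pk) / (last - pk)
  yn <- cnt[xs] / cnt[pk]
  y2 <- yn[length(yn)]
  d <- abs((y2 - 1) * xn - yn + 1) / sqrt((y2 - 1)^2 + 1)
  mids[xs[which.max(d)]]
}

# Otsu threshold on a numeric vector, rescaled to the data range.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) {
    stopf(paste("all pixels identical; the global threshold is undefined -",
                "supply an absolute threshold"))
  }
  n <- length(v)
  side <- ceiling(sqrt(n))
  pad <- rep(rng[1], side * side - n)
  img <- matrix(c((v - rng[1]) / diff(rng), pad * 0), side, side)
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  rng[1] + thr * diff(rng)
}

# 8-connected labeling of a logical matrix; returns an integer matrix of
# component labels (0 = background).
label_components8 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  idx <- which(bin)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  pos <- match(idx, idx)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  for (dd in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + dd[1]; c2 <- c + dd[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- match(nb, idx)
    found <- !is.na(hit)
    edges[[length(edges) + 1L]] <- cbind(pos[ok][found], hit[found])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_graph(t(e), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Detect smFISH spots in an ROI
#'
#' Binarizes the image within the ROI at a global threshold, labels
#' 8-connected components, and retains components whose mean intensity
#' exceeds the third quartile of the ROI pixel intensities and whose
#' area is at least `min_area` pixels. The spot density is the retained
#' count divided by the ROI area.
#'
#' @param image Numeric matrix (background-corrected).
#' @param roi ROI (logical mask or polygon); default whole image.
#' @param threshold `"triangle"` (default), `"otsu"`, or an absolute
#'   number. Spots occupy well under 1% of pixels, so the ROI histogram
#'   is unimodal with a long tail; the triangle method is built for that
#'   shape, whereas Otsu assumes two balanced classes and collapses into
#'   the noise band on spot images (it remains available for bimodal
#'   images).
#' @param min_area Minimum component area in pixels (default 3).
#' @param pixel_size Micrometers per pixel, for densities per square
#'   micrometer.
#' @return A `SpotCallResult`: list with `spots` (data frame `row`,
#'   `col`, `area`, `mean_intensity`), `n_spots`, `roi_area` (px),
#'   `density` (spots per px^2), `density_um2` (when `pixel_size`
#'   given), `threshold`, `q3`.
#' @export
detect_spots <- function(image, roi = NULL, threshold = "triangle",
                         min_area = 3, pixel_size = NULL) {
  image <- as.matrix(image)
  mask <- resolve_roi(roi, nrow(image), ncol(image))
  if (!any(mask)) stopf("ROI is empty")
  vals <- image[mask]
  thr <- if (identical(threshold, "triangle")) {
    triangle_threshold(vals)
  } else if (identical(threshold, "otsu")) {
    otsu_threshold(vals)
  } else {
    as.numeric(threshold)
  }
  q3 <- quantile(vals, 0.75, names = FALSE)
  bin <- image > thr & mask
  lab <- label_components8(bin)
  spots <- NULL
  n_comp <- max(lab)
  if (n_comp > 0L) {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    inten <- image[idx]
    r <- ((idx - 1L) %% nrow(image))
    c <- ((idx - 1L) %/% nrow(image))
    area <- tabulate(comp, n_comp)
    msum <- tapply(inten, comp, sum)
    mi <- as.numeric(msum) / area
    cr <- as.numeric(tapply(r, comp, mean))
    cc <- as.numeric(tapply(c, comp, mean))
    keep <- mi > q3 & area >= min_area
    spots <- data.frame(row = cr[keep], col = cc[keep],
                        area = area[keep], mean_intensity = mi[keep])
  }
  if (is.null(spots)) {
    spots <- data.frame(row = numeric(0), col = numeric(0),
                        area = integer(0), mean_intensity = numeric(0))
  }
  roi_area <- sum(mask)
  out <- list(spots = spots, n_spots = nrow(spots), roi_area = roi_area,
              density = nrow(spots) / roi_area,
              density_um2 = if (is.null(pixel_size)) NA_real_ else
                nrow(spots) / (roi_area * pixel_size^2),
              threshold = thr, q3 = q3)
  class(out) <- "SpotCallResult"
  out
}

#' @export
print.SpotCallResult <- function(x, ...) {
  cat(sprintf("SpotCallResult: %d spots in %d px ROI (density %.3g px^-2)\n",
              x$n_spots, x$roi_area, x$density))
  invisible(x)
}

#' Compare spot densities between groups
#'
#' Two-sided Mann-Whitney U test for every unordered pair of groups,
#' Benjamini-Hochberg adjusted across pairs, with significance stars at
#' adjusted p < 0.05 (`*`) and < 0.0005 (`**`).
#'
#' @param groups Named list of numeric density vectors; groups with
#'   fewer than 3 observations are excluded with a warning.
#' @return Data frame with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `p`, `p_adjusted`, `stars`.
#' @export
compare_spot_densities <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  small <- vapply(groups, length, integer(1)) < 3L
  if (any(small)) {
    warnf("excluding groups with n < 3: %s",
          paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
  }
  if (length(groups) < 2L) stopf("need at least 2 groups with n >= 3")
  prs <- utils::combn(names(groups), 2, simplify = FALSE)
  out <- do.call(rbind, lapply(prs, function(pr) {
    p <- suppressWarnings(wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                                      alternative = "two.sided")$p.value)
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(groups[[pr[1]]]), n2 = length(groups[[pr[2]]]),
               p = p, stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- bh_adjust(out$p)
  out$stars <- ifelse(out$p_adjusted < 0.0005, "**",
                      ifelse(out$p_adjusted < 0.05, "*", ""))
  out
}

# Bilinear interpolation of img at fractional 0-based (row, col); NA
# outside the image.
interp_bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  out <- rep(NA_real_, length(r))
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0) * nr + r0 + 1
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + nr] + fr * fc * img[i00 + nr + 1]
  out[ok] <- v
  out
}

# Arc-length parameterization of a polyline: returns a function mapping
# arc length to list(point, tangent), plus the total length.
polyline_param <- function(p) {
  p <- as.matrix(p)
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  at <- function(s) {
    s <- pmin(pmax(s, 0), total)
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- pmin(i, nrow(seg))
    t <- (s - cum[i]) / len[i]
    list(point = p[i, ] + t * seg[i, ],
         tangent = seg[i, ] / len[i])
  }
  list(at = at, total = total)
}

#' Niche intensity profiles in tubule-anchored coordinates
#'
#' Quantifies immunostaining intensity as a function of the distance
#' `d` from a tubule contour and the relative position `s` along it.
#' Cross-sections perpendicular to the contour are generated every
#' `section_spacing` pixels of arc length (or taken from hand-drawn
#' polylines); along each cross-section the intensity is sampled at
#' 1-pixel steps and averaged over a perpendicular line of `line_length`
#' pixels. Per-section profiles are averaged over `s` to give the
#' d-profile (with the SEM over sections) and over `d` to give the
#' s-profile; each channel's profile is max-normalized, and the ratio of
#' the first to the second channel is reported both for the raw and the
#' normalized profiles.
#'
#' @param img An [annotated_image()] with `ub_contour` set.
#' @param channels Character vector of 2 channel names (ratio =
#'   first / second); a single name gives profiles without a ratio.
#' @param section_spacing Arc-length spacing of auto-generated
#'   cross-sections in pixels (default 30).
#' @param line_length Length in pixels of the averaging line
#'   perpendicular to the cross-section (default 30).
#' @param max_d Profile depth in pixels (default 60).
#' @param normal_side `+1` or `-1` to force the side of the contour the
#'   sections extend to; default: the side with more ROI mask coverage
#'   (or `+1` without an ROI).
#' @return A `NicheProfile`: list with `d_profile` (data frame: `d`,
#'   `d_um`, per-channel `mean`, `norm`, `sem`), `s_profile` (per
#'   section: `s`, per-channel values), `ratio_d` (`d`, `ratio_raw`,
#'   `ratio_norm`), and `n_sections`.
#' @export
quantify_niche_profiles <- function(img, channels, section_spacing = 30,
                                    line_length = 30, max_d = 60,
                                    normal_side = NULL) {
  stopifnot(inherits(img, "AnnotatedImage"))
  if (is.null(img$ub_contour)) stopf("annotated image lacks a ub_contour")
  stopifnot(all(channels %in% names(img$channels)))
  nr <- img$dim[1]; nc <- img$dim[2]
  mask <- resolve_roi(img$roi, nr, nc)
  par <- polyline_param(img$ub_contour)
  dsteps <- seq(0, max_d, by = 1)

  sections <- list()
  if (!is.null(img$cross_sections)) {
    for (cs in img$cross_sections) {
      cs <- as.matrix(cs)
      origin <- cs[1, ]
      # s of the nearest contour point to the section origin
      grid <- seq(0, par$total, length.out = 512)
      pts <- t(vapply(grid, function(g) par$at(g)$point, numeric(2)))
      s_arc <- grid[which.min(rowSums(sweep(pts, 2, origin)^2))]
      cpar <- polyline_param(cs)
      sections[[length(sections) + 1L]] <-
        list(s = s_arc / par$total,
             point_at = function(d) cpar$at(d),
             max_d = cpar$total)
    }
  } else {
    s_origins <- seq(0, par$total, by = section_spacing)
    for (s0 in s_origins) {
      loc <- par$at(s0)
      nrm <- c(-loc$tangent[2], loc$tangent[1])
      side <- normal_side
      if (is.null(side)) {
        if (is.null(img$roi)) {
          side <- 1
        } else {
          probe <- function(sg) {
            q <- sweep(outer(dsteps[-1], sg * nrm), 2, loc$point, "+")
            rr <- round(q[, 1]) + 1; cc <- round(q[, 2]) + 1
            okp <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
            sum(mask[cbind(rr[okp], cc[okp])])
          }
          side <- if (probe(1) >= probe(-1)) 1 else -1
        }
      }
      nrm <- side * nrm
      tangent <- loc$tangent
      point <- loc$point
      sections[[length(sections) + 1L]] <- local({
        p0 <- point; nv <- nrm; tv <- tangent
        list(s = s0 / par$total,
             point_at = function(d) list(point = p0 + d * nv, tangent = nv),
             max_d = max_d, along = tv)
      })
    }
  }
  if (length(sections) == 0L) stopf("no usable cross-sections")

  offsets <- seq(-(line_length - 1) / 2, (line_length - 1) / 2, by = 1)
  profile_one <- function(ch, sec) {
    imgm <- img$channels[[ch]]
    vapply(dsteps, function(d) {
      if (d > sec$max_d) return(NA_real_)
      loc <- sec$point_at(d)
      perp <- c(-loc$tangent[2], loc$tangent[1])
      pr <- loc$point[1] + offsets * perp[1]
      pc <- loc$point[2] + offsets * perp[2]
      v <- interp_bilinear(imgm, pr, pc)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }

  d_profiles <- lapply(channels, function(ch) {
    t(vapply(sections, function(sec) profile_one(ch, sec),
             numeric(length(dsteps))))   # sections x d
  })
  names(d_profiles) <- channels
  usable <- rowSums(!is.na(d_profiles[[1]])) > 0
  if (!any(usable)) stopf("no cross-section intersects the image")

  px <- img$pixel_size
  d_df <- data.frame(d = dsteps,
                     d_um = if (is.null(px)) NA_real_ else dsteps * px)
  s_df <- data.frame(s = vapply(sections, `[[`, numeric(1), "s"))
  for (ch in channels) {
    pm <- d_profiles[[ch]]
    mn <- colMeans(pm, na.rm = TRUE)
    nsec <- colSums(!is.na(pm))
    sem <- apply(pm, 2, sd, na.rm = TRUE) / sqrt(pmax(nsec, 1))
    d_df[[paste0(ch, "_mean")]] <- mn
    d_df[[paste0(ch, "_norm")]] <- mn / max(mn, na.rm = TRUE)
    d_df[[paste0(ch, "_sem")]] <- sem
    sv <- rowMeans(pm, na.rm = TRUE)
    s_df[[paste0(ch, "_mean")]] <- sv
    s_df[[paste0(ch, "_norm")]] <- sv / max(sv, na.rm = TRUE)
  }
  ratio_d <- NULL
  if (length(channels) >= 2L) {
    a <- d_df[[paste0(channels[1], "_mean")]]
    b <- d_df[[paste0(channels[2], "_mean")]]
    an <- d_df[[paste0(channels[1], "_norm")]]
    bn <- d_df[[paste0(channels[2], "_norm")]]
    ratio_d <- data.frame(d = dsteps, ratio_raw = a / b,
                          ratio_norm = an / bn)
  }
  structure(list(d_profile = d_df, s_profile = s_df, ratio_d = ratio_d,
                 n_sections = length(sections),
                 channels = channels),
            class = "NicheProfile")
}
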