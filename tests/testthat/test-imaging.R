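test_that("rolling ball removes flat and slow backgrounds, keeps spikes", {
  flat <- matrix(3, 32, 32)
  expect_true(all(rolling_ball_subtract(flat, 3) == 0))
  # isolated impulse survives with its height intact
  imp <- matrix(0, 32, 32); imp[16, 16] <- 7
  out <- rolling_ball_subtract(imp, 3)
  expect_equal(out[16, 16], 7)
  expect_true(all(out[-16, ] == 0))
  # slowly varying background + spots: residual background is small
  set.seed(81)
  rows <- matrix(rep(1:64, 64), 64, 64)
  bg <- 5 + 3 * sin(rows / 25)
  img <- bg
  ctrs <- cbind(sample(10:54, 12), sample(10:54, 12))
  for (i in 1:12) img[ctrs[i, 1], ctrs[i, 2]] <- img[ctrs[i, 1],
                                                     ctrs[i, 2]] + 20
  out2 <- rolling_ball_subtract(img, 5)
  bgpix <- out2[-(ctrs[, 1] + (ctrs[, 2] - 1) * 64)]
  expect_lt(sqrt(mean(bgpix^2)), 0.05 * max(bg))
  expect_error(rolling_ball_subtract(flat, 30), "too large")
})

test_that("autofluorescence scaling is recovered by regression", {
  set.seed(82)
  gfp <- matrix(runif(64 * 64, 1, 3), 64, 64)
  ch <- 0.7 * gfp
  out <- subtract_autofluorescence(ch, gfp)
  expect_equal(attr(out, "alpha"), 0.7, tolerance = 1e-8)
  expect_lt(sqrt(mean(out^2)), 1e-6 * sqrt(mean(ch^2)))
  # gfp all zero: identity with a warning
  expect_warning(out0 <- subtract_autofluorescence(ch, gfp * 0),
                 "all zero")
  expect_equal(unclass(out0)[, ], ch, ignore_attr = TRUE)
  # planted signal + 0.5 gfp: background decorrelates from gfp
  sig <- matrix(0, 64, 64); sig[20:24, 20:24] <- 30
  ch2 <- sig + 0.5 * gfp + matrix(rnorm(64 * 64, 0, 0.02), 64)
  out2 <- subtract_autofluorescence(ch2, gfp)
  bgmask <- sig == 0
  expect_lt(abs(cor(out2[bgmask], gfp[bgmask])), 0.05)
})

test_that("spot calling enforces the area and intensity filters", {
  blank <- matrix(0, 16, 16)
  expect_error(detect_spots(blank), "identical")
  expect_equal(detect_spots(blank, threshold = 0.5)$n_spots, 0)
  # a 2-pixel component is rejected however bright
  img <- matrix(0, 16, 16)
  img[5, 5:6] <- 100
  expect_equal(detect_spots(img, threshold = 1)$n_spots, 0)
  img[10:12, 10] <- 100
  res <- detect_spots(img, threshold = 1)
  expect_equal(res$n_spots, 1)
  expect_equal(res$spots$area, 3)
  expect_equal(res$density, 1 / 256)
  # density in physical units
  expect_equal(detect_spots(img, threshold = 1,
                            pixel_size = 0.13)$density_um2,
               1 / (256 * 0.13^2))
})

test_that("8-connected labeling equals a brute-force oracle", {
  set.seed(83)
  for (i in 1:5) {
    img <- matrix(rbinom(48 * 48, 1, 0.12) * runif(48 * 48, 5, 10), 48, 48)
    res <- detect_spots(img, threshold = 1, min_area = 1)
    # oracle: flood fill with an explicit queue
    bin <- img > 1
    lab <- matrix(0L, 48, 48); cur <- 0L
    for (s in which(bin)) {
      if (lab[s] > 0L) next
      cur <- cur + 1L
      queue <- s
      while (length(queue)) {
        q <- queue[1]; queue <- queue[-1]
        if (lab[q] > 0L) next
        lab[q] <- cur
        r <- (q - 1) %% 48 + 1; cc <- (q - 1) %/% 48 + 1
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- r + dr; c2 <- cc + dc
          if (r2 >= 1 && r2 <= 48 && c2 >= 1 && c2 <= 48) {
            q2 <- (c2 - 1) * 48 + r2
            if (bin[q2] && lab[q2] == 0L) queue <- c(queue, q2)
          }
        }
      }
    }
    # same number of retained components under the same filters
    q3 <- quantile(img, 0.75, names = FALSE)
    keep <- vapply(seq_len(cur), function(k) {
      mean(img[lab == k]) > q3
    }, logical(1))
    expect_equal(res$n_spots, sum(keep))
  }
})

test_that("spot calling is translation invariant with its ROI", {
  spec <- image_sim_spec(image_size = c(96, 96), n_spots = 15,
                         spot_amplitude = 10, spot_sigma = 1.2,
                         background_level = 0, noise_sd = 0.5, seed = 84)
  sim <- generate_spot_image(spec)
  roi <- cbind(row = c(10, 70, 70, 10), col = c(10, 10, 70, 70))
  r1 <- detect_spots(sim$image, roi = roi, threshold = 3)
  shifted <- matrix(0, 96, 96)
  shifted[11:96, 11:96] <- sim$image[1:86, 1:86]
  r2 <- detect_spots(shifted, roi = roi + 10, threshold = 3)
  expect_equal(r2$n_spots, r1$n_spots)
  expect_equal(r2$density, r1$density)
  expect_equal(r2$spots$area, r1$spots$area)
})

test_that("planted spots are recovered with high precision and recall", {
  spec <- image_sim_spec(image_size = c(128, 128), n_spots = 50,
                         spot_amplitude = 10, spot_sigma = 1.2,
                         background_level = 0, noise_sd = 1, seed = 85)
  sim <- generate_spot_image(spec)
  res <- detect_spots(rolling_ball_subtract(sim$image, 3))
  found <- as.matrix(res$spots[, c("row", "col")])
  d2 <- outer(rowSums(found^2), rowSums(sim$truth$centers^2), "+") -
    2 * tcrossprod(found, sim$truth$centers)
  expect_gte(mean(apply(d2, 1, min) <= 4), 0.95)   # precision, 2 px match
  expect_gte(mean(apply(d2, 2, min) <= 4), 0.95)   # recall
})

test_that("density comparisons test every pair with stars", {
  set.seed(86)
  groups <- list(a = runif(10, 1, 2), b = runif(8, 1, 2),
                 c = runif(9, 5, 10))
  out <- compare_spot_densities(groups)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adjusted >= out$p))
  expect_true(all(out$stars[out$group2 == "c" | out$group1 == "c"] != ""))
  expect_warning(compare_spot_densities(c(groups, list(d = 1))),
                 "excluding")
  # identical groups: mostly no significance across null replicates
  hits <- vapply(1:50, function(i) {
    g <- list(x = rnorm(10), y = rnorm(10))
    any(compare_spot_densities(g)$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.12)
})

test_that("niche profiles recover a planted exponential gradient", {
  cont <- cbind(row = seq(10, 118, length.out = 30), col = rep(25, 30))
  lambda <- 20
  spec <- image_sim_spec(image_size = c(128, 128), n_spots = 0,
                         background_level = 0,
                         gradient = list(lambda = lambda, contour = cont,
                                         amplitude = 5),
                         noise_sd = 0, seed = 87)
  g <- generate_gradient_image(spec)
  ai <- annotated_image(channels = list(SIX2 = g$image, CITED1 = g$image),
                        ub_contour = cont, pixel_size = 0.13)
  np <- quantify_niche_profiles(ai, c("CITED1", "SIX2"),
                                section_spacing = 15, line_length = 15,
                                max_d = 3 * lambda, normal_side = 1)
  dd <- np$d_profile
  expect_lt(sqrt(mean((dd$SIX2_norm - exp(-dd$d / lambda))^2)), 0.05)
  # identical channels: ratio identically 1 at every d
  expect_true(all(abs(np$ratio_d$ratio_norm - 1) < 1e-9))
  expect_true(all(abs(np$ratio_d$ratio_raw - 1) < 1e-9))
  # s values lie in [0, 1] and are monotone along the contour
  expect_true(all(np$s_profile$s >= 0 & np$s_profile$s <= 1))
  expect_true(all(diff(np$s_profile$s) > 0))
  # physical units at reporting
  expect_equal(dd$d_um, dd$d * 0.13)
  # a uniform channel gives a flat max-normalized profile
  ai2 <- annotated_image(channels = list(u = matrix(4, 128, 128)),
                         ub_contour = cont)
  np2 <- quantify_niche_profiles(ai2, "u", section_spacing = 20,
                                 line_length = 10, max_d = 30,
                                 normal_side = 1)
  expect_true(all(abs(np2$d_profile$u_norm - 1) < 1e-9))
})
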