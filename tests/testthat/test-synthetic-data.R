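test_that("count generation is seed-deterministic", {
  spec <- count_sim_spec(n_clusters = 3, cells_per_cluster = 40, seed = 7)
  a <- generate_counts(spec)
  b <- generate_counts(spec)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("planted markers reach the requested fold in their cluster", {
  spec <- count_sim_spec(n_clusters = 4, cells_per_cluster = 200,
                         marker_fold = 8, seed = 2)
  sim <- generate_counts(spec)
  m <- as.matrix(sim$counts$counts)
  normal <- sim$truth$cells$designation == "normal"
  cl <- sim$truth$cells$cluster
  gk <- sim$truth$genes
  mk <- gk[gk$role == "marker", ]
  ratios <- vapply(seq_len(nrow(mk)), function(i) {
    v <- m[mk$gene[i], ]
    inc <- normal & cl == mk$marker_cluster[i]
    mean(v[inc]) / mean(v[normal & !inc])
  }, numeric(1))
  expect_true(all(ratios > 4))
})

test_that("zero dispersion gives Poisson-like variance", {
  spec <- count_sim_spec(n_clusters = 2, cells_per_cluster = 400,
                         n_genes = 300, markers_per_cluster = 2,
                         dispersion = 0, n_stressed = 0, n_rbc = 0,
                         n_low_count = 0, seed = 3)
  sim <- generate_counts(spec)
  m <- as.matrix(sim$counts$counts)
  base <- sim$truth$genes$gene[sim$truth$genes$role == "baseline"]
  cl1 <- sim$truth$cells$cluster == 1
  mu <- rowMeans(m[base, cl1])
  vr <- apply(m[base, cl1], 1, var)
  keep <- mu > 1
  expect_lt(abs(median(vr[keep] / mu[keep]) - 1), 0.1)
})

test_that("generated counts match the NB mean-variance law", {
  phi <- 0.2
  spec <- count_sim_spec(n_clusters = 2, cells_per_cluster = 500,
                         n_genes = 300, markers_per_cluster = 2,
                         dispersion = phi, n_stressed = 0, n_rbc = 0,
                         n_low_count = 0, seed = 4)
  sim <- generate_counts(spec)
  m <- as.matrix(sim$counts$counts)
  base <- sim$truth$genes$gene[sim$truth$genes$role == "baseline"]
  cl1 <- sim$truth$cells$cluster == 1
  mu <- rowMeans(m[base, cl1])
  vr <- apply(m[base, cl1], 1, var)
  keep <- mu > 2
  phi_hat <- median((vr[keep] - mu[keep]) / mu[keep]^2)
  expect_lt(abs(phi_hat - phi), 0.05)
})

test_that("spec errors: too many markers, cyclic topology", {
  expect_error(count_sim_spec(n_clusters = 10, markers_per_cluster = 30,
                              n_genes = 100), "too small")
  expect_error(trajectory_spec(topology = c(2L, 1L)), "acyclic")
})

test_that("trajectory latent time is recorded and drives planted genes", {
  spec <- count_sim_spec(n_genes = 800, seed = 5,
                         trajectory = trajectory_spec("linear",
                                                      n_segments = 3,
                                                      cells_per_segment = 200))
  sim <- generate_trajectory_counts(spec)
  tt <- sim$truth$cells
  # latent time increases with segment order
  expect_true(all(tapply(tt$latent_time, tt$segment, min) ==
                    sort(tapply(tt$latent_time, tt$segment, min))))
  # binned empirical mean of a monotone time gene tracks latent time
  tg <- sim$truth$genes$gene[sim$truth$genes$role == "time"][1]
  v <- as.matrix(sim$counts$counts)[tg, ]
  bins <- cut(tt$latent_time, 20)
  bm <- tapply(v, bins, mean)
  bt <- tapply(tt$latent_time, bins, mean)
  expect_gt(cor(bm, bt, method = "spearman"), 0.9)
})

test_that("Y topology records a shared ancestor for the two fates", {
  spec <- count_sim_spec(n_genes = 600, seed = 6,
                         trajectory = trajectory_spec("Y",
                                                      cells_per_segment = 50))
  sim <- generate_trajectory_counts(spec)
  topo <- sim$truth$topology
  expect_identical(topo, c(0L, 1L, 1L))
  expect_identical(topo[2], topo[3])   # both terminal fates descend from 1
})

test_that("spot image generation is exact without spots and noise", {
  af <- matrix(runif(64 * 64), 64, 64)
  spec <- image_sim_spec(image_size = c(64, 64), n_spots = 0,
                         background_level = 2, autofluorescence = af,
                         autofluorescence_scale = 0.5, noise_sd = 0,
                         seed = 1)
  sim <- generate_spot_image(spec)
  expect_equal(sim$image, 2 + 0.5 * af)
  expect_identical(generate_spot_image(spec)$image, sim$image)
})

test_that("bright planted spots form local maxima at their centers", {
  spec <- image_sim_spec(image_size = c(96, 96), n_spots = 20,
                         spot_amplitude = 10, spot_sigma = 1.5,
                         background_level = 0, noise_sd = 1, seed = 2)
  sim <- generate_spot_image(spec)
  img <- sim$image
  ok <- apply(sim$truth$centers, 1, function(ctr) {
    r <- round(ctr[1]) + 1; c <- round(ctr[2]) + 1
    win <- img[(r - 3):(r + 3), (c - 3):(c + 3)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ] - 4
    all(abs(peak + c(r, c) - 1 - ctr) <= 1.5)
  })
  expect_true(all(ok))
})

test_that("gradient image follows the exponential decay law", {
  cont <- cbind(row = c(10, 110), col = c(30, 30))
  spec <- image_sim_spec(image_size = c(120, 120), n_spots = 0,
                         background_level = 0,
                         gradient = list(lambda = 15, contour = cont,
                                         amplitude = 4),
                         noise_sd = 0.01, seed = 3)
  sim <- generate_gradient_image(spec)
  d <- sim$truth$distance
  on_contour <- abs(d) < 0.5
  # expected intensity at d = lambda is e^-1 of the intensity at d = 0
  at0 <- mean(sim$image[d < 0.5])
  atl <- mean(sim$image[abs(d - 15) < 0.5])
  expect_lt(abs(atl / at0 - exp(-1)), 0.05)
  # a contour pixel has maximal expected intensity
  expect_gte(max(sim$truth$clean[on_contour]), max(sim$truth$clean) - 1e-9)
  # lambda -> Inf gives a uniform image up to noise
  spec2 <- image_sim_spec(image_size = c(60, 60), n_spots = 0,
                          background_level = 1,
                          gradient = list(lambda = 1e9, contour = cont,
                                          amplitude = 4),
                          noise_sd = 0, seed = 4)
  sim2 <- generate_gradient_image(spec2)
  expect_lt(diff(range(sim2$image)), 1e-6)
  expect_error(generate_gradient_image(
    image_sim_spec(image_size = c(60, 60),
                   gradient = list(lambda = 5,
                                   contour = cbind(row = 1, col = 1)))),
    "degenerate")
})
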