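test_that("simulation spec validates its correlation and sizes", {
  expect_error(ieg_sim_spec(n_birds = 1), "n_birds")
  expect_error(ieg_sim_spec(rho = c(MATE = -0.9, UNFAMILIAR = 0,
                                    SILENCE = 0)), "PSD")
  expect_error(ieg_sim_spec(rho = c(0.5, 0, 0)), "named")
  expect_error(ieg_sim_spec(log_sd = 0), "positive")
})

test_that("rho = 1 with frame noise off gives parallel log densities", {
  spec <- ieg_sim_spec(n_birds = 4, rho = c(MATE = 1, UNFAMILIAR = 1,
                                            SILENCE = 1),
                       frame_noise = "none",
                       zero_inflation = data.frame(group = character(),
                                                   region = character(),
                                                   ieg = character(),
                                                   prob = numeric()),
                       seed = 40)
  tab <- gen_ieg_counts(spec)
  dens <- density_from_counts(tab$counts)
  z <- subset(dens, ieg == "Zenk" & group == "MATE")
  mat <- log(pairvox:::.region_matrix(z, c("CMM", "dNCM", "vNCM")))
  centred <- sweep(mat, 2, colMeans(mat))
  # identical bird effects across regions, up to region means (tolerance
  # covers the eigendecomposition of the singular covariance)
  expect_lt(max(abs(centred - centred[, 1])), 1e-6)
})

test_that("rho = 0 yields near-zero sample correlation at large n", {
  spec <- ieg_sim_spec(n_birds = 5000, groups = "MATE", regions = c("CMM", "dNCM", "vNCM"),
                       iegs = "Zenk", rho = c(MATE = 0), frame_noise = "none",
                       zero_inflation = data.frame(group = character(),
                                                   region = character(),
                                                   ieg = character(),
                                                   prob = numeric()),
                       seed = 41)
  tab <- gen_ieg_counts(spec)
  dens <- density_from_counts(tab$counts)
  mat <- log(pairvox:::.region_matrix(dens, c("CMM", "dNCM", "vNCM")))
  cors <- cor(mat)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 0.05))
})

test_that("counts are deterministic under the spec seed", {
  s1 <- gen_ieg_counts(ieg_sim_spec(seed = 42))
  s2 <- gen_ieg_counts(ieg_sim_spec(seed = 42))
  expect_identical(s1$counts, s2$counts)
})

test_that("zero inflation empties the designated cell", {
  spec <- ieg_sim_spec(zero_inflation = data.frame(
    group = "SILENCE", region = "vNCM", ieg = "Fos", prob = 1), seed = 43)
  tab <- gen_ieg_counts(spec)$counts
  cell <- subset(tab, group == "SILENCE" & region == "vNCM" & ieg == "Fos")
  expect_true(all(cell$count == 0))
  others <- subset(tab, !(group == "SILENCE" & region == "vNCM" & ieg == "Fos"))
  expect_gt(sum(others$count), 0)
})

test_that("frame-averaged densities are unbiased for the latent density", {
  spec <- ieg_sim_spec(n_birds = 2, n_frames = 10000, groups = "MATE",
                       regions = c("CMM", "dNCM", "vNCM"), iegs = "Zenk",
                       rho = c(MATE = 0),
                       zero_inflation = data.frame(group = character(),
                                                   region = character(),
                                                   ieg = character(),
                                                   prob = numeric()),
                       seed = 44)
  out <- gen_ieg_counts(spec)
  dens <- density_from_counts(out$counts, expected_frames = 10000)
  merged <- merge(dens, out$ground_truth,
                  by = c("bird_id", "group", "region", "ieg"))
  rel_err <- abs(merged$density_per_mm2 - exp(merged$log_density)) /
    exp(merged$log_density)
  # Poisson mean of ~10^4 frames: relative error O(1/sqrt(total count))
  expect_true(all(rel_err < 0.02))
})

test_that("marginal moments of simulated log densities match the spec", {
  spec <- ieg_sim_spec(n_birds = 5000, groups = "MATE",
                       regions = c("CMM", "dNCM", "vNCM"), iegs = "Zenk",
                       log_means = data.frame(group = "MATE",
                                              region = c("CMM", "dNCM", "vNCM"),
                                              ieg = "Zenk", log_mean = log(500)),
                       log_sd = 0.4, rho = c(MATE = 0.9),
                       frame_noise = "none",
                       zero_inflation = data.frame(group = character(),
                                                   region = character(),
                                                   ieg = character(),
                                                   prob = numeric()),
                       seed = 45)
  gt <- gen_ieg_counts(spec)$ground_truth
  expect_equal(mean(gt$log_density), log(500), tolerance = 0.02)
  expect_equal(sd(gt$log_density), 0.4, tolerance = 0.02)
})

test_that("the recovery experiment calibrates type I error and gains power", {
  res <- recovery_experiment(c(0, 0.99), n_birds = 4, n_reps = 400,
                             seed = 46)
  t1 <- subset(res$per_pair, rho == 0)
  expect_true(all(abs(t1$sig_fraction - 0.05) < 0.03))
  pow <- subset(res$all_three, rho == 0.99)
  expect_gt(pow$exclude_zero_fraction,
            subset(res$all_three, rho == 0)$exclude_zero_fraction)
  expect_true(all(res$per_pair$se < 0.03))
})
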