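test_that("prior draws honor the printed constraints", {
  sigs <- TEST_SIGS_10
  # small battery here; the full 10,000-draw battery runs in the acceptance suite
  for (seed in 1:200) {
    dp <- draw_parameters(sim_config(J = 3, N = 10, sigs = sigs, seed = seed))
    p <- dp$params
    expect_equal(p$phi[1], 1)
    expect_true(all(p$phi > 0.1))
    expect_true(all(diff(p$phi) <= -0.05 + 1e-12))
    expect_gt(min(p$xi), 0.05)
    expect_equal(sum(p$xi), 1, tolerance = 1e-12)
    expect_equal(rowSums(p$pi), rep(1, 3), tolerance = 1e-12)
    expect_gte(p$rho, 1)
  }
  # J = 1 is forced to a single clonal clone
  d1 <- draw_parameters(sim_config(J = 1, N = 10, sigs = sigs, seed = 1))
  expect_equal(d1$params$phi, 1)
  expect_equal(d1$params$xi, 1)
})

test_that("benchmark mode tightens the clone constraints", {
  sigs <- TEST_SIGS_10
  for (seed in 1:60) {
    dp <- draw_parameters(sim_config(J = 3, N = 10, sigs = sigs,
                                     benchmark = TRUE, seed = seed))
    p <- dp$params
    expect_gt(min(p$xi), 0.1)
    expect_true(all(diff(p$phi) <= -0.1 + 1e-12))
    prof <- p$pi %*% sigs
    d <- vapply(1:2, function(j) sigclone:::cosine_distance(prof[j, ], prof[j + 1, ]),
                numeric(1))
    expect_true(all(d >= 0.05))
  }
})

test_that("rho draws center on 60 with variance read literally", {
  rhos <- withr::with_seed(10, vapply(1:4000, function(i) {
    max(rnorm(1, 60, sqrt(5)), 1)
  }, numeric(1)))
  # the simulator draws match this law
  sim_rhos <- vapply(1:4000, function(s)
    draw_parameters(sim_config(J = 1, N = 10, sigs = TEST_SIGS_5, seed = s))$params$rho,
    numeric(1))
  expect_lt(abs(mean(sim_rhos) - 60), 3 * sd(sim_rhos) / sqrt(4000))
  expect_lt(abs(sd(sim_rhos) - sqrt(5)), 0.15)
  expect_gt(ks.test(sim_rhos, rhos)$p.value, 1e-3)
})

test_that("copy-number draws respect the diploid fraction and allele bounds", {
  sigs <- TEST_SIGS_5
  cfg_dip <- sim_config(J = 1, N = 500, sigs = sigs, diploid_fraction = 1)
  cn <- withr::with_seed(3, draw_copy_number(cfg_dip, 500))
  expect_true(all(cn$C_normal == 2 & cn$C_major == 1 & cn$C_minor == 1))

  cfg_ln <- sim_config(J = 1, N = 10000, sigs = sigs, diploid_fraction = 0,
                       cn_mode = "lognormal")
  cn2 <- withr::with_seed(4, draw_copy_number(cfg_ln, 10000))
  expect_true(all(cn2$C_minor <= cn2$C_major))
  expect_true(all(cn2$C_major >= 1))
  total <- cn2$C_major + cn2$C_minor
  # modal total copy number of round(exp(N(1, 0.3))) is 3
  expect_equal(as.integer(names(which.max(table(total)))), 3L)

  cfg_bell <- sim_config(J = 1, N = 10000, sigs = sigs, diploid_fraction = 0,
                         cn_mode = "bell")
  cn3 <- withr::with_seed(5, draw_copy_number(cfg_bell, 10000))
  t3 <- cn3$C_major + cn3$C_minor
  expect_equal(as.integer(names(which.max(table(t3)))), 2L)
  expect_gt(mean(t3), 2)  # right-skewed around 2
})

test_that("purity draws are capped at 0.99 and centered near 0.7", {
  ps <- withr::with_seed(6, vapply(1:10000, function(i) draw_purity(), numeric(1)))
  expect_true(all(ps <= 0.99))
  expect_true(all(ps > 0.05))
  expect_lt(abs(median(ps) - 0.7), 0.02)
})

test_that("simulated samples follow the generative chain", {
  sigs <- TEST_SIGS_10
  sim <- simulate_sample(sim_config(J = 2, N = 400, sigs = sigs, seed = 21))
  s <- sim$sample$snvs
  expect_true(all(s$B <= s$D))
  expect_true(all(s$type >= 1 & s$type <= 96))
  expect_true(all(sim$truth$multiplicity <= s$C_major))
  expect_true(all(sim$truth$clone %in% 1:2))

  # byte-identical reruns under the same seed
  sim2 <- simulate_sample(sim_config(J = 2, N = 400, sigs = sigs, seed = 21))
  expect_identical(sim$sample$snvs, sim2$sample$snvs)
  expect_identical(sim$truth$params, sim2$truth$params)

  # fully clonal diploid setting: mean VAF within 3 SE of p/2
  cfgc <- sim_config(J = 1, N = 10000, sigs = sigs, phi = 1, rho = 60,
                     diploid_fraction = 1, depth = 100, purity = 0.8, seed = 8)
  simc <- simulate_sample(cfgc)
  vaf <- simc$sample$snvs$B / simc$sample$snvs$D
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.4), 3 * se)
})

test_that("mutation-type frequencies converge to the exposure-weighted mixture", {
  # sparse profiles, as real signature catalogues are
  sigs <- random_signature_matrix(5, concentration = 0.05, seed = 77)
  pi <- rbind(c(0.7, 0.3, 0, 0, 0), c(0, 0, 0.2, 0.5, 0.3))
  cfg <- sim_config(J = 2, N = 10000, sigs = sigs, xi = c(0.6, 0.4),
                    phi = c(1, 0.5), pi = pi, seed = 99)
  sim <- simulate_sample(cfg)
  emp <- tabulate(sim$sample$snvs$type, nbins = 96) / 10000
  want <- as.vector(c(0.6, 0.4) %*% pi %*% sigs)
  expect_lt(sum(abs(emp - want)) / 2, 0.03)  # total variation
})

test_that("the two-clone grid hits requested gaps with flat cosine coverage", {
  sigs <- TEST_SIGS_10
  grid <- two_clone_grid(sigs, ccf_gaps = c(0.2, 0.6), n_pi_samples = 50,
                         cosine_target = "uniform", pool_size = 3000, seed = 5)
  expect_length(grid, 100)
  for (cfg in grid[c(1, 50, 100)]) {
    expect_equal(cfg$xi, c(0.5, 0.5))
    expect_true(all(cfg$phi %in% c(1, 0.8, 0.4)))
    expect_equal(cfg$phi[1], 1)
  }
  gaps <- vapply(grid, function(cfg) 1 - cfg$phi[2], numeric(1))
  expect_setequal(round(unique(gaps), 10), c(0.2, 0.6))
  # achieved cosine distances approximately uniform: chi-square GOF p > 0.01
  d <- vapply(grid[1:100], function(cfg) attr(cfg, "cosine_distance"), numeric(1))
  h <- table(cut(d, breaks = seq(0, max(d) + 1e-9, length.out = 6)))
  expect_gt(chisq.test(h)$p.value, 0.01)
})

test_that("samples round-trip through the TSV interface", {
  sigs <- TEST_SIGS_5
  sim <- simulate_sample(sim_config(J = 2, N = 60, sigs = sigs, seed = 14))
  f <- tempfile(fileext = ".tsv")
  write_sample_tsv(sim$sample, f)
  back <- read_sample_tsv(f)
  expect_equal(back$snvs, sim$sample$snvs)
  expect_equal(back$purity, sim$sample$purity, tolerance = 1e-12)

  ft <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, ft)
  bt <- read_truth_json(ft)
  expect_equal(bt$params$phi, sim$truth$params$phi, tolerance = 1e-12)
  expect_equal(bt$clone, sim$truth$clone)
})
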