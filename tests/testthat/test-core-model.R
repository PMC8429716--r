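test_that("eta and expected_vaf follow the purity/copy-number algebra", {
  expect_equal(eta(1, 1, 1, 2, 1), 0.5)
  expect_equal(eta(1, 1, 1, 2, 0.5), 0.25)
  expect_equal(eta(2, 2, 1, 2, 0.6), 1.2 / (0.6 * 3 + 0.4 * 2))
  expect_error(eta(3, 2, 1, 2, 0.6), "1..c_major")
  expect_error(eta(0, 2, 1, 2, 0.6), "1..c_major")

  expect_equal(expected_vaf(1, 1, 1, 1, 1, 2), 0.5)
  expect_equal(expected_vaf(0.7, 0.5, 1, 1, 1, 2), 0.175)
  expect_equal(expected_vaf(0.9, 0, 1, 1, 1, 2), 0)
  expect_error(expected_vaf(0.9, 1.2, 1, 1, 1, 2), "\\[0, 1\\]")
})

test_that("corrected CCF inverts the expected-VAF relation", {
  # VAF 0.35 at purity 0.7, diploid heterozygous, m = 1 -> CCF exactly 1
  expect_equal(corrected_ccf(35, 100, 0.7, 1, 1, 1, 2), 1.0)
  expect_equal(corrected_ccf(0, 80, 0.7, 1, 2, 1, 2), 0)
  # pure diploid tumor: CCF = 2 * VAF
  expect_equal(corrected_ccf(12, 100, 1, 1, 1, 1, 2), 0.24)
  # can exceed 1; clip flag truncates
  expect_gt(corrected_ccf(60, 100, 1, 1, 1, 1, 2), 1)
  expect_equal(corrected_ccf(60, 100, 1, 1, 1, 1, 2, clip = TRUE), 1)
  expect_error(corrected_ccf(5, 10, 0, 1, 1, 1, 2), "positive")
  # round trip with expected_vaf at arbitrary parameters
  v <- expected_vaf(0.62, 0.44, 2, 3, 1, 2)
  expect_equal(corrected_ccf(v * 1000, 1000, 0.62, 2, 3, 1, 2), 0.44)
})

test_that("the per-SNV log-likelihood table matches direct beta-binomial evaluation", {
  sigs1 <- signature_matrix(matrix(c(1, rep(0, 95)), 1, 96), names = "only")
  # J = 1, L = 1, mu[1, T] = 1, C_major = 1: all categorical factors are log 1
  snv <- data.frame(B = 5L, D = 10L, type = 1L, C_normal = 2L, C_major = 1L,
                    C_minor = 1L)
  params <- sigclone_params(1, 1, matrix(1, 1, 1), 100)
  tab <- snv_loglik_components(snv, params, sigs1, purity = 1)
  expect_equal(dim(tab), c(1, 1, 1))
  # phi * eta = 0.5 -> BetaBinomial(5; 10, 50, 50)
  expect_equal(tab[1, 1, 1], log(oracle_betabinom(5, 10, 50, 50)), tolerance = 1e-9)

  # phi = 1, eta = 1 would hit the boundary: clamped with a warning
  snv2 <- data.frame(B = 3L, D = 3L, type = 1L, C_normal = 2L, C_major = 1L,
                     C_minor = 0L)
  expect_warning(snv_loglik_components(snv2, params, sigs1, purity = 1), "clamped")

  # two clones identical except weight: entries differ by log xi1 - log xi2
  sigs <- TEST_SIGS_5
  p2 <- sigclone_params(c(0.7, 0.3), c(0.8, 0.8),
                        rbind(rep(0.2, 5), rep(0.2, 5)), 60)
  snv3 <- data.frame(B = 12L, D = 40L, type = 17L, C_normal = 2L, C_major = 2L,
                     C_minor = 1L)
  tab3 <- snv_loglik_components(snv3, p2, sigs, purity = 0.8)
  expect_equal(tab3[1, , ] - tab3[2, , ],
               matrix(log(0.7) - log(0.3), 5, 2), tolerance = 1e-12)
})

test_that("marginal likelihood and posteriors match exhaustive enumeration", {
  for (seed in 1:12) {
    inst <- random_instance(seed)
    ll <- marginal_loglik(inst$sample, inst$params, inst$sigs)
    expect_equal(ll, oracle_marginal_loglik(inst$sample, inst$params, inst$sigs),
                 tolerance = 1e-9)
    resp <- posterior_responsibilities(inst$sample, inst$params, inst$sigs)
    n_check <- min(3, n_snvs(inst$sample))
    for (n in seq_len(n_check)) {
      want <- oracle_posterior(inst$sample, inst$params, inst$sigs, n)
      got <- resp$gamma[n, , , seq_len(dim(want)[3]), drop = FALSE]
      expect_equal(array(got, dim = dim(want)), want, tolerance = 1e-9)
    }
    # normalization per SNV
    expect_equal(apply(resp$gamma, 1, sum), rep(1, n_snvs(inst$sample)),
                 tolerance = 1e-9)
  }
})

test_that("likelihood respects i.i.d. duplication and clone-label symmetry", {
  inst <- random_instance(101, N = 6, J = 3, L = 4)
  ll <- marginal_loglik(inst$sample, inst$params, inst$sigs)

  dup <- sigclone_sample(rbind(inst$sample$snvs, inst$sample$snvs),
                         inst$sample$purity)
  expect_equal(marginal_loglik(dup, inst$params, inst$sigs), 2 * ll,
               tolerance = 1e-9)

  perm <- c(3, 1, 2)
  pp <- sigclone_params(inst$params$xi[perm], inst$params$phi[perm],
                        inst$params$pi[perm, ], inst$params$rho)
  expect_equal(marginal_loglik(inst$sample, pp, inst$sigs), ll, tolerance = 1e-9)

  expect_error(marginal_loglik(sigclone_sample(inst$sample$snvs[0, ], 0.9),
                               inst$params, inst$sigs), "at least one SNV")
})

test_that("posteriors carry forced structure", {
  sigs <- TEST_SIGS_5
  # identical clones with equal weight: clone marginal is (0.5, 0.5)
  params <- sigclone_params(c(0.5, 0.5), c(0.6, 0.6),
                            rbind(rep(0.2, 5), rep(0.2, 5)), 50)
  inst <- random_instance(7, N = 5, J = 1, L = 5)
  resp <- posterior_responsibilities(inst$sample, params, sigs)
  expect_equal(resp$clone, matrix(0.5, 5, 2), ignore_attr = TRUE,
               tolerance = 1e-12)

  # C_major = 1 everywhere: multiplicity marginal is a point mass at m = 1
  snvs <- data.frame(B = c(3, 8), D = c(20, 25), type = c(1, 50),
                     C_normal = 2, C_major = 1, C_minor = 1)
  s <- sigclone_sample(snvs, 0.9)
  r <- posterior_responsibilities(s, params, sigs)
  expect_equal(dim(r$gamma)[4], 1L)
  expect_equal(apply(r$gamma, 1, sum), c(1, 1), tolerance = 1e-12)
})

test_that("MAP assignment takes the joint arg-max with lowest-index ties", {
  inst <- random_instance(55, N = 8, J = 2, L = 3)
  resp <- posterior_responsibilities(inst$sample, inst$params, inst$sigs)
  map <- map_assignments(resp)
  for (n in 1:8) {
    tab <- oracle_posterior(inst$sample, inst$params, inst$sigs, n)
    best <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    expect_equal(unlist(map[n, ]), best, ignore_attr = TRUE)
  }

  # symmetric two-clone case resolves to clone 1
  params <- sigclone_params(c(0.5, 0.5), c(0.7, 0.7),
                            rbind(rep(0.2, 5), rep(0.2, 5)), 50)
  snvs <- data.frame(B = 10, D = 30, type = 4, C_normal = 2, C_major = 1,
                     C_minor = 1)
  r <- posterior_responsibilities(sigclone_sample(snvs, 0.8), params, TEST_SIGS_5)
  expect_equal(map_assignments(r)$clone, 1L)
})

test_that("simulated read counts have the expected VAF mean", {
  withr::with_seed(321, {
    n <- 10000
    phi <- 0.65; m <- 1; p <- 0.8; rho <- 60
    et <- eta(m, 1, 1, 2, p)
    D <- rep(100L, n)
    B <- rbinom(n, D, rbeta(n, rho * phi * et, rho * (1 - phi * et)))
    vaf <- B / D
    want <- expected_vaf(p, phi, m, 1, 1, 2)
    se <- sd(vaf) / sqrt(n)
    expect_lt(abs(mean(vaf) - want), 3 * se)
  })
})
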