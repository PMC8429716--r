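test_that("clone-number adequacy follows the printed formula", {
  expect_equal(score1b(3, 3), 1.0)
  expect_equal(score1b(3, 5), 0.5)
  expect_equal(score1b(1, 8), 0.0)
  expect_equal(score1b(4, 2), (5 - 2) / 5)
})

test_that("the Wasserstein similarity matches closed forms and an atom oracle", {
  expect_equal(score1c(c(1, 0.4), c(0.5, 0.5), c(1, 0.4), c(0.5, 0.5)), 1.0)
  expect_equal(score1c(0.5, 1, 0.6, 1), 0.9)
  # two equal-weight clones (0.4, 1.0) vs one clone at 0.7: each half-mass moves 0.3
  expect_equal(score1c(c(0.4, 1.0), c(0.5, 0.5), 0.7, 1), 0.7)
  # random discrete distributions against the equal-atom expansion oracle
  for (seed in 1:20) {
    withr::with_seed(seed, {
      k1 <- sample(1:5, 1); k2 <- sample(1:5, 1)
      x1 <- runif(k1, 0, 1.5); x2 <- runif(k2, 0, 1.5)
      w1 <- as.vector(rmultinom(1, 1200, rep(1, k1))) / 1200
      w2 <- as.vector(rmultinom(1, 1200, rep(1, k2))) / 1200
    })
    keep1 <- w1 > 0; keep2 <- w2 > 0
    expect_equal(1 - score1c(x1[keep1], w1[keep1], x2[keep2], w2[keep2]),
                 oracle_w1_atoms(x1[keep1], w1[keep1], x2[keep2], w2[keep2]),
                 tolerance = 1e-9)
  }
})

test_that("co-clustering sub-scores match independent textbook formulas", {
  for (seed in 1:25) {
    labs <- withr::with_seed(seed, list(
      t = sample(1:3, 15, replace = TRUE),
      p = sample(1:4, 15, replace = TRUE)))
    m_t <- outer(labs$t, labs$t, "==")
    m_p <- outer(labs$p, labs$p, "==")
    expect_equal(sigclone:::mcc_binary(as.vector(m_t), as.vector(m_p)),
                 oracle_mcc(as.vector(m_t), as.vector(m_p)), tolerance = 1e-8)
    expect_equal(sigclone:::v_measure(labs$t, labs$p),
                 oracle_v_measure(labs$t, labs$p), tolerance = 1e-8)
    expect_equal(stats::cor(as.vector(m_t) * 1, as.vector(m_p) * 1),
                 oracle_pearson(m_t, m_p), tolerance = 1e-8)
  }
})

test_that("score2a anchors bad scenarios at zero and perfection at one", {
  t6 <- c(1, 1, 1, 2, 2, 2)
  expect_equal(score2a(t6, t6), 1.0)
  expect_equal(score2a(t6, rep(1, 6)), 0.0)
  # hand-computable 6-item instance
  p6 <- c(1, 1, 2, 2, 2, 2)
  hand <- {
    m_t <- outer(t6, t6, "=="); m_p <- outer(p6, p6, "==")
    raw <- c(oracle_pearson(m_t, m_p),
             oracle_mcc(as.vector(m_t), as.vector(m_p)),
             oracle_v_measure(t6, p6))
    bad1 <- c(oracle_pearson(m_t, outer(rep(1, 6), rep(1, 6), "==")),
              oracle_mcc(as.vector(m_t), rep(TRUE, 36)),
              oracle_v_measure(t6, rep(1, 6)))
    bad2 <- c(oracle_pearson(m_t, diag(6) == 1),
              oracle_mcc(as.vector(m_t), as.vector(diag(6) == 1)),
              oracle_v_measure(t6, 1:6))
    bad1[is.na(bad1)] <- 0
    s_bad <- pmin(bad1, bad2)
    mean(pmax(0, (raw - s_bad) / (1 - s_bad)))
  }
  expect_equal(score2a(t6, p6), hand, tolerance = 1e-8)
  # label permutation invariance
  expect_equal(score2a(t6, c(2, 2, 1, 1, 1, 1)), score2a(t6, p6), tolerance = 1e-12)
  expect_error(score2a(rep(1, 30), rep(1, 30), max_n = 20), "subsample")
})

test_that("clonal classification scores follow confusion-matrix arithmetic", {
  # truth: clones (1=clonal at CCF 1, 2 subclonal); perfect prediction
  lt <- c(1, 1, 2, 2); ct <- c(1, 0.4)
  s <- score2c(lt, ct, lt, ct)
  expect_equal(s$accuracy, 1)
  expect_equal(s$auc, 1)
  # all predicted clonal, truth half clonal
  s2 <- score2c(lt, ct, rep(1, 4), c(1))
  expect_equal(s2$accuracy, 0.5)
  expect_equal(s2$sensitivity, 1)
  expect_equal(s2$specificity, 0)
  # label swap: accuracy 0
  s3 <- score2c(lt, ct, c(2, 2, 1, 1), ct)
  expect_equal(s3$accuracy, 0)
  # AUC against the rank oracle with probabilistic scores
  withr::with_seed(31, {
    truth_lab <- sample(1:2, 30, replace = TRUE)
    prob <- runif(30)
  })
  s4 <- score2c(truth_lab, c(1, 0.5), ifelse(prob > 0.5, 1, 2), c(1, 0.5),
                prob_clonal_pred = prob)
  expect_equal(s4$auc, oracle_auc(truth_lab == 1, prob), tolerance = 1e-8)
})

test_that("signature profile distances behave geometrically", {
  sigs <- TEST_SIGS_5
  act <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  prof <- as.vector(act %*% sigs)
  counts <- round(prof * 1e6)
  expect_lt(score_sig_1a(counts, act, sigs), 1e-3)
  expect_equal(score_sig_1b(act, act, sigs), 0)
  # orthogonal one-hot profiles: distance sqrt(2)
  one_hot <- matrix(0, 2, 96); one_hot[1, 1] <- 1; one_hot[2, 2] <- 1
  sigs2 <- signature_matrix(one_hot)
  expect_equal(score_sig_1b(c(1, 0), c(0, 1), sigs2), sqrt(2))
  # identical-profile signatures: activity differences are invisible
  dup <- signature_matrix(rbind(sigs[1, ], sigs[1, ]))
  expect_equal(score_sig_1b(c(0.8, 0.2), c(0.3, 0.7), dup), 0, tolerance = 1e-12)
})

test_that("the cumulative-0.95 rule marks present signatures", {
  expect_equal(signature_present(c(0.96, 0.04)), c(TRUE, FALSE))
  expect_equal(signature_present(c(0.5, 0.5)), c(TRUE, TRUE))
  expect_equal(signature_present(c(0, 1, 0)), c(FALSE, TRUE, FALSE))
  expect_equal(signature_present(c(0.5, 0.3, 0.15, 0.05)),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("presence identification is scored by rank", {
  s <- score_sig_1c(c(TRUE, TRUE, FALSE, FALSE), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(s$auc, 1.0)
  s2 <- score_sig_1c(c(FALSE, FALSE, TRUE, TRUE), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(s2$auc, 0.0)
  expect_true(is.na(score_sig_1c(c(TRUE, TRUE), c(0.6, 0.4))$auc))
})

test_that("per-mutation attribution and reconstruction scores summarize correctly", {
  expect_equal(score_sig_1d(c(1, 2, 3, 1), c(1, 2, 3, 2)), 0.75)
  expect_equal(score_sig_1d(rep(1, 5), rep(1, 5)), 1.0)

  sigs <- TEST_SIGS_5
  prof <- unclass(sigs)[c(1, 2, 1, 2), ]
  same <- score_sig_1e(prof, prof)
  expect_equal(same$median, 0)
  expect_equal(same$frac_below_0.05, 1)
  # constant-distance construction: median equals that distance
  d12 <- sigclone:::cosine_distance(sigs[1, ], sigs[2, ])
  swap <- score_sig_1e(prof, prof[c(2, 1, 2, 1), ])
  expect_equal(swap$median, d12, tolerance = 1e-12)
  # 10-SNV fixture with hand-built exposures, checked per SNV
  pi_t <- rbind(c(0.8, 0.2, 0, 0, 0), c(0, 0, 0.5, 0.5, 0))
  pi_p <- rbind(c(0.6, 0.4, 0, 0, 0), c(0, 0, 0.3, 0.3, 0.4))
  cl_t <- rep(1:2, 5); cl_p <- rep(c(1, 2), each = 5)
  tp <- (pi_t %*% sigs)[cl_t, ]
  pp <- (pi_p %*% sigs)[cl_p, ]
  got <- score_sig_1e(tp, pp)
  want <- vapply(1:10, function(n) {
    a <- tp[n, ]; b <- pp[n, ]
    1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_equal(got$distances, want, tolerance = 1e-12)
  expect_equal(got$median, median(want))
})

test_that("clustering scores are invariant to cluster-label permutation", {
  withr::with_seed(77, {
    lt <- sample(1:3, 40, replace = TRUE)
    lp <- sample(1:3, 40, replace = TRUE)
  })
  perm <- c(3, 1, 2)
  expect_equal(score2a(lt, lp), score2a(lt, perm[lp]), tolerance = 1e-12)
  expect_equal(sigclone:::v_measure(lt, lp), sigclone:::v_measure(lt, perm[lp]),
               tolerance = 1e-12)
})

test_that("the end-to-end evaluation wrapper scores a self-fit perfectly on J", {
  sigs <- TEST_SIGS_10
  sim <- simulate_sample(two_clone_test_config(sigs, N = 400, seed = 41))
  fit <- fit_fixed_j(sim$sample, sigs, 2, config = em_config(seed = 41, n_restarts = 2))
  sc <- evaluate_fit(sim$sample, fit, sim$truth, sigs)
  expect_equal(sc$score1b, 1)
  expect_gt(sc$score2a, 0.5)
  expect_gt(sc$score1c, 0.8)
  expect_lt(sc$score_sig_1b, 0.5)
})
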