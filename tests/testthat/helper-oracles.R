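# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: probabilities are accumulated in the
# probability domain with rising-factorial products and exhaustive sums.

# beta-binomial pmf via rising factorials (exact for small D, no lgamma)
oracle_betabinom <- function(B, D, alpha, beta) {
  rising <- function(x, k) if (k == 0) 1 else prod(x + seq_len(k) - 1)
  choose(D, B) * rising(alpha, B) * rising(beta, D - B) / rising(alpha + beta, D)
}

# exhaustive joint probability table over (clone, signature, multiplicity)
# for one SNV; plain probability-domain arithmetic
oracle_joint_table <- function(snv, params, sigs, purity) {
  J <- params$J; L <- nrow(sigs); cm <- snv$C_major
  ct <- snv$C_major + snv$C_minor
  tab <- array(0, dim = c(J, L, cm))
  for (j in seq_len(J)) for (l in seq_len(L)) for (m in seq_len(cm)) {
    et <- purity * m / (purity * ct + (1 - purity) * snv$C_normal)
    f <- min(max(params$phi[j] * et, 1e-10), 1 - 1e-10)
    tab[j, l, m] <- params$xi[j] * params$pi[j, l] * sigs[l, snv$type] *
      (1 / cm) * oracle_betabinom(snv$B, snv$D, params$rho * f,
                                  params$rho * (1 - f))
  }
  tab
}

oracle_marginal_loglik <- function(sample, params, sigs) {
  sum(vapply(seq_len(nrow(sample$snvs)), function(n) {
    log(sum(oracle_joint_table(sample$snvs[n, ], params, sigs, sample$purity)))
  }, numeric(1)))
}

oracle_posterior <- function(sample, params, sigs, n) {
  tab <- oracle_joint_table(sample$snvs[n, ], params, sigs, sample$purity)
  tab / sum(tab)
}

# small random model instance for oracle-equivalence checks
random_instance <- function(seed, N = NULL, J = NULL, L = NULL, cmax = 3) {
  withr::with_seed(seed, {
    if (is.null(N)) N <- sample(2:10, 1)
    if (is.null(J)) J <- sample(1:3, 1)
    if (is.null(L)) L <- sample(1:5, 1)
    sigs <- random_signature_matrix(L)
    C_major <- sample(seq_len(cmax), N, replace = TRUE)
    C_minor <- vapply(C_major, function(cm) sample(0:cm, 1), integer(1))
    D <- sample(20:60, N, replace = TRUE)
    snvs <- data.frame(B = NA, D = D, type = sample(1:96, N, replace = TRUE),
                       C_normal = 2L, C_major = C_major, C_minor = C_minor)
    snvs$B <- vapply(D, function(d) sample(0:d, 1), integer(1))
    purity <- runif(1, 0.3, 0.99)
    xi <- as.vector(prop.table(rgamma(J, 1) + 0.05))
    phi <- sort(runif(J, 0.15, 1), decreasing = TRUE)
    pi <- matrix(rgamma(J * L, 1), J); pi <- pi / rowSums(pi)
    rho <- runif(1, 20, 90)
    list(sample = sigclone_sample(snvs, purity),
         params = sigclone_params(xi, phi, pi, rho),
         sigs = sigs)
  })
}

# Wasserstein-1 oracle by expansion into equal-weight atoms (weights must be
# multiples of 1 / denom)
oracle_w1_atoms <- function(x1, w1, x2, w2, denom = 1200) {
  a1 <- rep(x1, round(w1 / sum(w1) * denom))
  a2 <- rep(x2, round(w2 / sum(w2) * denom))
  stopifnot(length(a1) == denom, length(a2) == denom)
  mean(abs(sort(a1) - sort(a2)))
}

# MCC equals the Pearson correlation of the two binary indicator vectors
oracle_mcc <- function(truth, pred) {
  suppressWarnings(stats::cor(as.numeric(truth), as.numeric(pred)))
}

# V-measure via the mutual-information identity v = 2 MI / (H(C) + H(K))
oracle_v_measure <- function(lc, lk) {
  pt <- table(lc, lk) / length(lc)
  pc <- rowSums(pt); pk <- colSums(pt)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_along(pc)) for (j in seq_along(pk)) {
    if (pt[i, j] > 0) mi <- mi + pt[i, j] * log(pt[i, j] / (pc[i] * pk[j]))
  }
  unname(2 * mi / (H(pc) + H(pk)))
}

# AUC by the Mann-Whitney rank statistic with tie correction
oracle_auc <- function(truth, score) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pearson correlation from explicit moment sums
oracle_pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y); n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# a fixed easy two-clone configuration: CCFs 1.0 / 0.4, disjoint signatures
two_clone_test_config <- function(sigs, N = 1000, depth = 100, seed = NULL) {
  L <- nrow(sigs)
  stopifnot(L >= 6)
  pi <- matrix(0, 2, L)
  pi[1, 1:3] <- c(0.5, 0.3, 0.2)
  pi[2, (L - 2):L] <- c(0.4, 0.4, 0.2)
  sim_config(J = 2, N = N, sigs = sigs, phi = c(1, 0.4), pi = pi,
             depth = depth, seed = seed)
}

# clone-matching by CCF order, for assignment accuracy against truth
clone_accuracy_ccf_order <- function(true_clone, phi_true, map_clone, phi_pred) {
  mean(match(map_clone, order(phi_pred, decreasing = TRUE)) ==
         match(true_clone, order(phi_true, decreasing = TRUE)))
}

TEST_SIGS_10 <- random_signature_matrix(10, seed = 424242)
TEST_SIGS_5 <- random_signature_matrix(5, seed = 515151)
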