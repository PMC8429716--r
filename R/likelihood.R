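#' Expected VAF contribution of one mutated copy
#'
#' For a fully clonal mutation present on `m` of the tumor copies at a locus,
#' the expected variant allele frequency is `purity * m` divided by the
#' purity-weighted total copy number
#' `purity * C_tumor + (1 - purity) * C_normal`. The clone CCF multiplies this
#' factor to give the expected VAF of a subclonal mutation.
#'
#' @param m Multiplicity, integer in `1..c_major` (vectorized).
#' @param c_major,c_minor Major/minor allele tumor copy number.
#' @param c_normal Total copy number in normal cells (default 2).
#' @param purity Tumor purity in (0, 1].
#' @return Numeric vector in (0, 1].
#' @export
#' @examples
#' eta(1, 1, 1, 2, 1)   # 0.5: heterozygous diploid, pure tumor
#' eta(1, 1, 1, 2, 0.5) # 0.25
eta <- function(m, c_major, c_minor, c_normal = 2L, purity) {
  if (any(m < 1) || any(m > c_major)) stop("multiplicity m must lie in 1..c_major")
  if (any(purity <= 0) || any(purity > 1)) stop("purity must be in (0, 1]")
  c_tumor <- c_major + c_minor
  purity * m / (purity * c_tumor + (1 - purity) * c_normal)
}

#' Expected variant allele frequency
#'
#' @inheritParams eta
#' @param ccf Cancer cell fraction in `[0, 1]`.
#' @return `ccf * eta(...)`, in `[0, 1]`.
#' @export
expected_vaf <- function(purity, ccf, m, c_major, c_minor, c_normal = 2L) {
  if (any(ccf < 0) || any(ccf > 1)) stop("ccf must be in [0, 1]")
  ccf * eta(m, c_major, c_minor, c_normal, purity)
}

#' CCF of an SNV corrected for purity, copy number and multiplicity
#'
#' Inverts the expected-VAF relation: given an observed VAF `B/D` and an
#' (estimated) multiplicity, returns the implied cancer cell fraction. Values
#' may exceed 1 through sampling noise; set `clip = TRUE` to truncate at 1 for
#' plotting.
#'
#' @param B,D Variant and total read counts.
#' @inheritParams eta
#' @param clip Truncate the result to `[0, 1]`? Default `FALSE`.
#' @return Numeric vector of corrected CCFs.
#' @export
corrected_ccf <- function(B, D, purity, m, c_major, c_minor, c_normal = 2L,
                          clip = FALSE) {
  if (any(purity <= 0)) stop("purity must be positive")
  if (any(m < 1)) stop("multiplicity m must be >= 1")
  if (any(D < 1)) stop("depth D must be >= 1")
  c_tumor <- c_major + c_minor
  ccf <- (B / D) * (purity * c_tumor + (1 - purity) * c_normal) / (purity * m)
  if (clip) ccf <- pmin(pmax(ccf, 0), 1)
  ccf
}

# beta-binomial log pmf with shape parameters (alpha, beta); log-gamma domain
betabinom_lpmf <- function(B, D, alpha, beta) {
  lchoose(D, B) + lbeta(B + alpha, D - B + beta) - lbeta(alpha, beta)
}

# clamp the success fraction phi*eta away from {0, 1} before forming
# alpha = rho * f, beta = rho * (1 - f)
EPS_FRAC <- 1e-10

clamp_frac <- function(f, warn = TRUE) {
  out <- pmin(pmax(f, EPS_FRAC), 1 - EPS_FRAC)
  if (warn && any(out != f))
    warning("phi * eta clamped to (", EPS_FRAC, ", 1 - ", EPS_FRAC, ")")
  out
}

#' Per-SNV joint log-likelihood table
#'
#' For a single SNV, the log joint density of (clone, signature, multiplicity)
#' and the observed data:
#' `log xi_j + log pi_jl + log mu_{l,T} + log(1/C_major) +
#'  log BetaBinomial(B; D, rho * phi_j * eta(m), rho * (1 - phi_j * eta(m)))`.
#'
#' @param snv A one-row data.frame (or list) with `B`, `D`, `type`, `C_normal`,
#'   `C_major`, `C_minor`.
#' @param params A [sigclone_params()].
#' @param sigs A [signature_matrix()].
#' @param purity Tumor purity.
#' @return A J x L x C_major array of log joint densities.
#' @export
snv_loglik_components <- function(snv, params, sigs, purity) {
  J <- params$J; L <- nrow(sigs); cm <- as.integer(snv$C_major)
  if (cm < 1) stop("C_major must be >= 1")
  et <- eta(seq_len(cm), snv$C_major, snv$C_minor, snv$C_normal, purity)
  out <- array(NA_real_, dim = c(J, L, cm))
  lmu <- log(sigs[, snv$type])
  for (j in seq_len(J)) {
    f <- clamp_frac(params$phi[j] * et)
    lbb <- betabinom_lpmf(snv$B, snv$D, params$rho * f, params$rho * (1 - f))
    for (l in seq_len(L)) {
      out[j, l, ] <- log(params$xi[j]) + log(params$pi[j, l]) + lmu[l] -
        log(cm) + lbb
    }
  }
  out
}

# Per-sample constants reused across every EM iteration: flank data vectors,
# the binomial-coefficient term (an additive constant of the log-likelihood),
# eta factors per multiplicity, and the mutation-type rows of mu.
prepare_model_data <- function(sample, sigs) {
  snv <- sample$snvs
  p <- sample$purity
  cmax <- max(snv$C_major)
  denom <- p * (snv$C_major + snv$C_minor) + (1 - p) * snv$C_normal
  live <- lapply(seq_len(cmax), function(m) which(snv$C_major >= m))
  et <- lapply(seq_len(cmax), function(m) p * m / denom[live[[m]]])
  list(B = snv$B, D = snv$D, N = nrow(snv), cmax = cmax, denom = denom,
       live = live, et = et, lch_total = sum(lchoose(snv$D, snv$B)),
       log_cmaj = log(snv$C_major), lmu_t = sigs[, snv$type, drop = FALSE])
}

# log BetaBinomial(B; D, rho f, rho (1 - f)) without the lchoose(D, B) term,
# using lbeta(a, b) = lgamma(a) + lgamma(b) - lgamma(rho) since a + b = rho
bb_kernel <- function(B, D, rho, f) {
  a <- rho * f
  b <- rho - a
  lgamma(B + a) + lgamma(D - B + b) - lgamma(a) - lgamma(b) -
    lgamma(D + rho) + lgamma(rho)
}

# Vectorized E-step sufficient statistics over a whole sample.
#
# The joint over (j, l, m) factorizes given the SNV: the signature factor
# depends on (j, l) only and the read-count factor on (j, m) only, so the
# per-SNV marginal over clones is
#   log xi_j - log C_major + log(sum_l pi_jl mu_{l,T}) + log(sum_m BB_m).
# Returns the marginal log-likelihood, clone responsibilities W (N x J),
# per-clone signature stats gnl (J x L, already summed over SNVs), and the
# multiplicity weights omega (list over m of N x J matrices) needed by the
# phi / rho updates.
e_step_stats <- function(sample, params, sigs, want_omega = TRUE, data = NULL) {
  if (is.null(data)) data <- prepare_model_data(sample, sigs)
  snv <- sample$snvs
  N <- data$N; J <- params$J; L <- nrow(sigs)
  cmax <- data$cmax

  mix <- params$pi %*% sigs              # J x 96 per-clone mutation-type mixes
  log_sig <- log(mix)[, snv$type, drop = FALSE]   # J x N

  # log BB components per multiplicity (lchoose term deferred to the total):
  # list over m of J x N (-Inf if m > C_major)
  lbb_m <- vector("list", cmax)
  for (m in seq_len(cmax)) {
    live <- data$live[[m]]
    mat <- matrix(-Inf, nrow = J, ncol = N)
    et <- data$et[[m]]
    for (j in seq_len(J)) {
      f <- clamp_frac(params$phi[j] * et, warn = FALSE)
      mat[j, live] <- bb_kernel(data$B[live], data$D[live], params$rho, f)
    }
    lbb_m[[m]] <- mat
  }
  # log sum over m, J x N
  if (cmax == 1L) {
    log_bb <- lbb_m[[1]]
  } else {
    mx <- Reduce(pmax, lbb_m)
    acc <- matrix(0, J, N)
    for (m in seq_len(cmax)) acc <- acc + exp(lbb_m[[m]] - mx)
    log_bb <- mx + log(acc)
  }

  log_joint <- log(params$xi) + log_sig + log_bb -
    rep(data$log_cmaj, each = J)         # J x N
  if (J == 1L) {
    lse <- log_joint[1, ]
    W <- matrix(1, N, 1)
  } else {
    mx <- apply(log_joint, 2, max)
    lse <- mx + log(colSums(exp(sweep(log_joint, 2, mx, "-"))))
    W <- t(exp(sweep(log_joint, 2, lse, "-"))) # N x J clone responsibilities
  }
  loglik <- sum(lse) + data$lch_total

  # signature stats: gnl[j, l] = sum_n W[n, j] * P(l | n, j)
  gnl <- matrix(0, J, L)
  lmu_t <- data$lmu_t                          # L x N
  for (j in seq_len(J)) {
    num <- params$pi[j, ] * lmu_t              # L x N
    cs <- colSums(num)
    cs[cs == 0] <- 1
    gnl[j, ] <- as.vector(num %*% (W[, j] / cs))
  }

  omega <- NULL
  if (want_omega) {
    # omega[[m]][n, j] = W[n, j] * P(m | n, j)
    omega <- vector("list", cmax)
    for (m in seq_len(cmax)) {
      pm <- t(exp(lbb_m[[m]] - log_bb))        # N x J
      pm[!is.finite(pm)] <- 0
      omega[[m]] <- W * pm
    }
  }

  list(loglik = loglik, W = W, gnl = gnl, omega = omega,
       lbb_m = lbb_m, log_bb = log_bb, log_sig = log_sig)
}

#' Marginal log-likelihood of a sample
#'
#' Sums, over SNVs, the log of the exhaustive sum of the joint density over all
#' latent (clone, signature, multiplicity) configurations. Invariant to
#' permutation of clone labels.
#'
#' @param sample A [sigclone_sample()].
#' @param params A [sigclone_params()].
#' @param sigs A [signature_matrix()].
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(sample, params, sigs) {
  e_step_stats(sample, params, sigs, want_omega = FALSE)$loglik
}

#' Posterior responsibilities over (clone, signature, multiplicity)
#'
#' The E-step quantities: for each SNV the posterior probability of every
#' latent configuration, normalized to sum to 1 per SNV.
#'
#' @inheritParams marginal_loglik
#' @return An object of class `sigclone_resp`: a list with `gamma` (an
#'   N x J x L x Cmax array, entries for `m > C_major` equal 0), plus the
#'   marginals `clone` (N x J), `signature` (N x L) and the marginal
#'   log-likelihood `loglik`.
#' @export
posterior_responsibilities <- function(sample, params, sigs) {
  st <- e_step_stats(sample, params, sigs, want_omega = TRUE)
  snv <- sample$snvs
  N <- nrow(snv); J <- params$J; L <- nrow(sigs)
  cmax <- max(snv$C_major)
  lmu_t <- sigs[, snv$type, drop = FALSE]      # L x N
  gamma <- array(0, dim = c(N, J, L, cmax))
  for (j in seq_len(J)) {
    num <- params$pi[j, ] * lmu_t              # L x N
    pl <- sweep(num, 2, colSums(num), "/")     # P(l | n, j), L x N
    pmj <- vapply(seq_len(cmax), function(m) {
      pm <- exp(st$lbb_m[[m]][j, ] - st$log_bb[j, ])
      pm[!is.finite(pm)] <- 0
      pm
    }, numeric(N))
    pmj <- matrix(pmj, nrow = N)               # N x cmax
    for (m in seq_len(cmax)) {
      gamma[, j, , m] <- t(pl) * (st$W[, j] * pmj[, m])
    }
  }
  structure(list(gamma = gamma, clone = st$W,
                 signature = t(apply_sig_marginal(gamma)),
                 loglik = st$loglik),
            class = "sigclone_resp")
}

apply_sig_marginal <- function(gamma) {
  # sum over clones and multiplicities -> L x N
  d <- dim(gamma)
  m <- apply(gamma, c(3, 1), sum)
  matrix(m, nrow = d[3], ncol = d[1])
}

#' @export
print.sigclone_resp <- function(x, ...) {
  d <- dim(x$gamma)
  cat("sigclone_resp:", d[1], "SNVs x", d[2], "clones x", d[3],
      "signatures x", d[4], "multiplicities\n")
  invisible(x)
}

#' Maximum a posteriori latent assignments
#'
#' For each SNV, the (clone, signature, multiplicity) configuration with the
#' largest posterior responsibility; ties are broken toward the lowest index,
#' scanning multiplicity fastest, then signature, then clone.
#'
#' @param resp A `sigclone_resp` from [posterior_responsibilities()].
#' @return A data.frame with integer columns `clone`, `signature`,
#'   `multiplicity` (one row per SNV).
#' @export
map_assignments <- function(resp) {
  g <- resp$gamma
  d <- dim(g)
  out <- data.frame(clone = integer(d[1]), signature = integer(d[1]),
                    multiplicity = integer(d[1]))
  for (n in seq_len(d[1])) {
    tab <- array(g[n, , , ], dim = d[2:4])
    hit <- which(tab == max(tab), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2], hit[, 3]), , drop = FALSE]
    out$clone[n] <- hit[1, 1]
    out$signature[n] <- hit[1, 2]
    out$multiplicity[n] <- hit[1, 3]
  }
  out
}
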