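#' Configure the generative tumor simulator
#'
#' The simulator draws samples from the model's own generative process:
#' clone memberships, signatures, mutation types, multiplicities and
#' beta-binomial read counts, with allele-specific copy number and purity drawn
#' from the default study conditions. Any parameter left `NULL` is drawn from
#' its prior (see [draw_parameters()]).
#'
#' @param J Number of clones, or `"random"` to draw uniformly from `1:6`.
#' @param N Number of SNVs.
#' @param sigs A [signature_matrix()].
#' @param xi,phi,pi,rho Optional fixed parameter values (otherwise drawn).
#' @param diploid_fraction Proportion of SNVs on diploid (2, 1, 1) loci;
#'   default 0.5.
#' @param depth Mean sequencing depth (Poisson, floored at 1); default 100.
#' @param cn_mode Non-diploid total copy number law: `"bell"` (discrete
#'   bell-shaped, centered at 2, right-skewed) or `"lognormal"`
#'   (`round(exp(N(1, 0.3)))`, floored at 1).
#' @param purity Optional fixed purity (otherwise drawn, see [draw_purity()]).
#' @param moments_as_sd If `TRUE`, the stated dispersion values 5 (rho) and 0.1
#'   (purity) are used as standard deviations rather than variances.
#' @param benchmark Benchmark-mode constraints: minimum clone proportion 0.1,
#'   CCF spacing at least 0.1, and cosine distance of at least 0.05 between
#'   the mutation-type profiles of successive clones (the conditions used for
#'   method-comparison simulations). Default `FALSE` (the default conditions).
#' @param seed Optional integer seed; every draw is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(J = 2, N = 300, sigs, xi = NULL, phi = NULL, pi = NULL,
                       rho = NULL, diploid_fraction = 0.5, depth = 100,
                       cn_mode = c("bell", "lognormal"), purity = NULL,
                       moments_as_sd = FALSE, benchmark = FALSE, seed = NULL) {
  cn_mode <- match.arg(cn_mode)
  if (!inherits(sigs, "signature_matrix")) stop("sigs must be a signature_matrix")
  if (!identical(J, "random") && (J < 1 || J != round(J))) stop("J must be a positive integer or 'random'")
  if (N < 1) stop("N must be >= 1")
  if (diploid_fraction < 0 || diploid_fraction > 1) stop("diploid_fraction must be in [0, 1]")
  if (depth < 1) stop("depth must be >= 1")
  structure(list(J = J, N = as.integer(N), sigs = sigs, xi = xi, phi = phi,
                 pi = pi, rho = rho, diploid_fraction = diploid_fraction,
                 depth = depth, cn_mode = cn_mode, purity = purity,
                 moments_as_sd = moments_as_sd, benchmark = isTRUE(benchmark),
                 seed = seed),
            class = "sim_config")
}

MAX_REJECT <- 10000L

rdirichlet1 <- function(d) {
  x <- stats::rgamma(d, shape = 1)
  x / sum(x)
}

#' Draw model parameters from the simulator priors
#'
#' The priors of the default study conditions: the number of active signatures
#' is `min(Poisson(7) + 1, L)` with the active set uniform without replacement;
#' each clone's exposures over the active set are Dirichlet(1); clone CCFs are
#' set so the largest clone has CCF 1 and each subsequent CCF is drawn
#' uniformly, decreasing, each > 0.1 and at least 0.05 below the previous;
#' clone proportions are Dirichlet(1) redrawn until the minimum exceeds 0.05;
#' rho is Normal with mean 60 and variance 5 (floored at 1).
#'
#' With `benchmark = TRUE` in the config, the method-comparison conditions
#' apply instead: minimum clone proportion 0.1, CCF spacing at least 0.1, and
#' exposures redrawn until successive clones' mutation-type profiles are at
#' cosine distance of at least 0.05.
#'
#' @param config A [sim_config()]. Fixed values in the config are respected.
#' @return A list with `params` (a [sigclone_params()]) and `active`
#'   (integer indices of active signatures).
#' @export
draw_parameters <- function(config) {
  run <- function() {
    L <- nrow(config$sigs)
    J <- if (identical(config$J, "random")) sample.int(6, 1) else as.integer(config$J)
    spacing <- if (config$benchmark) 0.1 else 0.05
    min_prop <- if (config$benchmark) 0.1 else 0.05

    pi <- config$pi
    active <- seq_len(L)
    if (is.null(pi)) {
      k <- 0L
      repeat {
        n_active <- min(stats::rpois(1, 7) + 1L, L)
        active <- sort(sample.int(L, n_active))
        pi <- matrix(0, nrow = J, ncol = L)
        for (j in seq_len(J)) pi[j, active] <- rdirichlet1(n_active)
        if (!config$benchmark || J == 1) break
        # benchmark mode: successive clones' mutation-type profiles must be
        # at cosine distance >= 0.05
        prof <- pi %*% config$sigs
        dists <- vapply(seq_len(J - 1), function(j)
          cosine_distance(prof[j, ], prof[j + 1, ]), numeric(1))
        if (all(dists >= 0.05)) break
        k <- k + 1L
        if (k > MAX_REJECT) stop("exposure rejection sampling exceeded ", MAX_REJECT, " attempts")
      }
    } else {
      if (is.vector(pi)) pi <- matrix(pi, nrow = 1)
      active <- which(colSums(pi) > 0)
    }

    phi <- config$phi
    if (is.null(phi)) {
      phi <- numeric(J)
      phi[1] <- 1
      for (j in seq_len(J)[-1]) {
        hi <- phi[j - 1] - spacing
        if (hi <= 0.1) stop("cannot place ", J, " clone CCFs above 0.1 with spacing ", spacing)
        k <- 0L
        repeat {
          cand <- stats::runif(1, 0.1, hi)
          # leave room for the remaining clones
          if (cand - spacing * (J - j) > 0.1 || j == J) break
          k <- k + 1L
          if (k > MAX_REJECT) stop("CCF rejection sampling exceeded ", MAX_REJECT, " attempts")
        }
        phi[j] <- cand
      }
    }

    xi <- config$xi
    if (is.null(xi)) {
      if (J == 1) {
        xi <- 1
      } else {
        k <- 0L
        repeat {
          xi <- rdirichlet1(J)
          if (min(xi) > min_prop) break
          k <- k + 1L
          if (k > MAX_REJECT) stop("clone-proportion rejection sampling exceeded ", MAX_REJECT, " attempts")
        }
      }
    }

    rho <- config$rho
    if (is.null(rho)) {
      sd <- if (config$moments_as_sd) 5 else sqrt(5)
      rho <- max(stats::rnorm(1, mean = 60, sd = sd), 1)
    }
    list(params = sigclone_params(xi, phi, pi, rho), active = active)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# discrete bell-shaped total copy-number law centered at 2, right-skewed
BELL_CN <- c(`1` = 0.15, `2` = 0.40, `3` = 0.25, `4` = 0.12, `5` = 0.05, `6` = 0.03)

#' Draw per-SNV allele-specific copy number
#'
#' A `diploid_fraction` share of SNVs sit on (C_normal, C_major, C_minor) =
#' (2, 1, 1) loci. For the remainder the total tumor copy number follows the
#' configured mode; the minor copy number is `round(Beta(5, 3) * total)`
#' clipped to `[0, floor(total / 2)]` and the major is the rest (always >= 1).
#'
#' @param config A [sim_config()].
#' @param N Number of SNVs to draw.
#' @return A data.frame with columns `C_normal`, `C_major`, `C_minor`.
#' @export
draw_copy_number <- function(config, N) {
  C_normal <- rep(2L, N)
  C_major <- rep(1L, N)
  C_minor <- rep(1L, N)
  non_dip <- which(stats::runif(N) >= config$diploid_fraction)
  if (length(non_dip)) {
    k <- length(non_dip)
    total <- if (config$cn_mode == "lognormal") {
      pmax(round(exp(stats::rnorm(k, 1, 0.3))), 1)
    } else {
      as.integer(sample(as.integer(names(BELL_CN)), k, replace = TRUE, prob = BELL_CN))
    }
    minor <- pmin(pmax(round(stats::rbeta(k, 5, 3) * total), 0), floor(total / 2))
    major <- total - minor
    redo <- which(major < 1)           # unreachable by construction; guard anyway
    while (length(redo)) {
      minor[redo] <- pmin(round(stats::rbeta(length(redo), 5, 3) * total[redo]),
                          floor(total[redo] / 2))
      major <- total - minor
      redo <- which(major < 1)
    }
    C_major[non_dip] <- as.integer(major)
    C_minor[non_dip] <- as.integer(minor)
  }
  data.frame(C_normal = C_normal, C_major = C_major, C_minor = C_minor)
}

#' Draw a tumor purity
#'
#' `min(Normal(0.7, variance 0.1), 0.99)`, redrawn while the draw is <= 0.05.
#'
#' @param moments_as_sd Use 0.1 as the standard deviation instead of the
#'   variance.
#' @return A purity scalar in (0.05, 0.99].
#' @export
draw_purity <- function(moments_as_sd = FALSE) {
  sd <- if (moments_as_sd) 0.1 else sqrt(0.1)
  repeat {
    p <- min(stats::rnorm(1, 0.7, sd), 0.99)
    if (p > 0.05) return(p)
  }
}

rbetabinom <- function(n, size, alpha, beta) {
  stats::rbinom(n, size, stats::rbeta(n, alpha, beta))
}

#' Simulate a tumor sample from the generative model
#'
#' Per SNV: clone `U ~ Cat(xi)`, signature `S | U ~ Cat(pi_U)`, mutation type
#' `T | S ~ Cat(mu_S)`, copy number from [draw_copy_number()], multiplicity
#' uniform on `1..C_major`, depth `D ~ Poisson(depth)` floored at 1, and
#' variant count `B ~ BetaBinomial(D, rho * phi_U * eta, rho * (1 - phi_U *
#' eta))`.
#'
#' @param config A [sim_config()].
#' @return A list with `sample` (a [sigclone_sample()]) and `truth` (a
#'   `sigclone_truth`: true parameters, purity, and per-SNV latent
#'   `clone`, `signature`, `multiplicity`).
#' @export
simulate_sample <- function(config) {
  run <- function() {
    dp <- draw_parameters(strip_seed(config))
    params <- dp$params
    N <- config$N
    L <- nrow(config$sigs)
    p <- if (is.null(config$purity)) draw_purity(config$moments_as_sd) else config$purity

    U <- sample.int(params$J, N, replace = TRUE, prob = params$xi)
    S <- vapply(U, function(u) sample.int(L, 1, prob = params$pi[u, ]), integer(1))
    Tt <- vapply(S, function(s) sample.int(96, 1, prob = config$sigs[s, ]), integer(1))
    cn <- draw_copy_number(config, N)
    M <- vapply(cn$C_major, function(cm) if (cm == 1L) 1L else sample.int(cm, 1), integer(1))
    D <- pmax(stats::rpois(N, config$depth), 1L)
    et <- eta(M, cn$C_major, cn$C_minor, cn$C_normal, p)
    f <- clamp_frac(params$phi[U] * et, warn = FALSE)
    B <- rbetabinom(N, D, params$rho * f, params$rho * (1 - f))

    sample <- sigclone_sample(
      data.frame(B = B, D = D, type = Tt, C_normal = cn$C_normal,
                 C_major = cn$C_major, C_minor = cn$C_minor),
      purity = p)
    truth <- structure(list(params = params, purity = p, active = dp$active,
                            clone = U, signature = S, multiplicity = M),
                       class = "sigclone_truth")
    list(sample = sample, truth = truth)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

strip_seed <- function(config) { config$seed <- NULL; config }

#' Two-clone separating-power grid
#'
#' Emits equal-weight (50/50) two-clone configurations with the larger clone at
#' CCF 1 and the second at `1 - gap`, paired with exposure matrices whose
#' cosine distance between the two clones' mutation-type profiles follows a
#' target law — `"uniform"` over the achievable range, or `"beta(1.5,8)"` to
#' concentrate on small distances. Exposure pairs are obtained by rejection
#' sampling against an empirical proposal pool.
#'
#' @param sigs A [signature_matrix()].
#' @param ccf_gaps Numeric vector of CCF gaps in (0, 1].
#' @param n_pi_samples Number of exposure pairs to keep (default 50).
#' @param cosine_target `"uniform"` or `"beta(1.5,8)"`.
#' @param N,depth,diploid_fraction Passed to each emitted config.
#' @param pool_size Size of the proposal pool (default 10000).
#' @param seed Optional seed.
#' @return A list of [sim_config()] objects (one per gap x exposure pair), each
#'   with attribute `cosine_distance`.
#' @export
two_clone_grid <- function(sigs, ccf_gaps, n_pi_samples = 50,
                           cosine_target = c("uniform", "beta(1.5,8)"),
                           N = 300, depth = 100, diploid_fraction = 0.5,
                           pool_size = 10000, seed = NULL) {
  cosine_target <- match.arg(cosine_target)
  if (any(ccf_gaps <= 0) || any(ccf_gaps > 1)) stop("ccf_gaps must lie in (0, 1]")
  run <- function() {
    L <- nrow(sigs)
    pool <- vector("list", pool_size)
    dist <- numeric(pool_size)
    for (i in seq_len(pool_size)) {
      n_active <- min(stats::rpois(1, 7) + 1L, L)
      active <- sort(sample.int(L, n_active))
      pi <- matrix(0, nrow = 2, ncol = L)
      pi[1, active] <- rdirichlet1(n_active)
      pi[2, active] <- rdirichlet1(n_active)
      pool[[i]] <- pi
      prof <- pi %*% sigs
      dist[i] <- cosine_distance(prof[1, ], prof[2, ])
    }
    # rejection against the empirical proposal: accept with probability
    # proportional to target(d) / empirical_density(d), binned
    brk <- seq(0, max(dist) + 1e-9, length.out = 21)
    bin <- findInterval(dist, brk, rightmost.closed = TRUE)
    emp <- tabulate(bin, nbins = 20) / pool_size
    mid <- (brk[-1] + brk[-21]) / 2
    target <- if (cosine_target == "uniform") rep(1, 20) else
      stats::dbeta(mid / max(dist), 1.5, 8)
    w <- ifelse(emp > 0, target / emp, 0)
    acc_p <- w[bin] / max(w[emp > 0])
    kept <- integer(0)
    tries <- 0L
    while (length(kept) < n_pi_samples) {
      i <- sample.int(pool_size, 1)
      if (stats::runif(1) < acc_p[i]) kept <- c(kept, i)
      tries <- tries + 1L
      if (tries > MAX_REJECT * 50L) stop("cosine-distance rejection sampling failed")
    }
    out <- list()
    for (g in ccf_gaps) {
      for (i in kept) {
        cfg <- sim_config(J = 2, N = N, sigs = sigs, xi = c(0.5, 0.5),
                          phi = c(1, 1 - g), pi = pool[[i]],
                          diploid_fraction = diploid_fraction, depth = depth)
        attr(cfg, "cosine_distance") <- dist[i]
        out[[length(out) + 1L]] <- cfg
      }
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

cosine_distance <- function(x, y) {
  1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}
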