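#' EM configuration
#'
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param n_restarts Random restarts used when no initialization is supplied
#'   (default 5; higher clone numbers normally inherit a split
#'   initialization instead).
#' @param seed Integer seed making the fit deterministic.
#' @param rho_bounds Allowed overdispersion interval (default `c(10, 500)`).
#' @return A list of class `em_config`.
#' @export
em_config <- function(max_iter = 1000, tol = 1e-6, n_restarts = 5, seed = NULL,
                      rho_bounds = c(10, 500)) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  if (any(rho_bounds <= 0) || rho_bounds[1] >= rho_bounds[2])
    stop("rho_bounds must be a strictly positive increasing pair")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 rho_bounds = rho_bounds),
            class = "em_config")
}

#' E-step: posterior responsibilities under current parameters
#'
#' Delegates to [posterior_responsibilities()].
#'
#' @inheritParams marginal_loglik
#' @return A `sigclone_resp`.
#' @export
e_step <- function(sample, params, sigs) {
  posterior_responsibilities(sample, params, sigs)
}

# Flatten the multiplicity responsibilities into per-clone (n, m) vectors so
# the expected complete-data log-likelihood terms that depend on (phi, rho) --
# sum_{n,j,m} omega[n,j,m] * log BB(B_n; D_n, rho * phi_j * eta(m, n)) --
# reduce to a handful of vectorized lgamma calls per objective evaluation.
flatten_omega <- function(omega, data) {
  J <- ncol(omega[[1]])
  lapply(seq_len(J), function(j) {
    w <- B <- D <- et <- numeric(0)
    for (m in seq_along(omega)) {
      live <- data$live[[m]]
      wm <- omega[[m]][live, j]
      keep <- wm > 1e-12
      w <- c(w, wm[keep])
      B <- c(B, data$B[live][keep])
      D <- c(D, data$D[live][keep])
      et <- c(et, data$et[[m]][keep])
    }
    list(w = w, B = B, D = D, et = et)
  })
}

# phi-dependent part only (terms constant in phi dropped)
phi_objective <- function(fl, phi_j, rho) {
  f <- clamp_frac(phi_j * fl$et, warn = FALSE)
  a <- rho * f
  b <- rho - a
  sum(fl$w * (lgamma(fl$B + a) + lgamma(fl$D - fl$B + b) - lgamma(a) - lgamma(b)))
}

rho_objective <- function(flat, phi, rho) {
  tot <- 0
  for (j in seq_along(flat)) {
    fl <- flat[[j]]
    if (!length(fl$w)) next
    f <- clamp_frac(phi[j] * fl$et, warn = FALSE)
    a <- rho * f
    b <- rho - a
    tot <- tot + sum(fl$w * (lgamma(fl$B + a) + lgamma(fl$D - fl$B + b) -
                               lgamma(a) - lgamma(b) - lgamma(fl$D + rho))) +
      lgamma(rho) * sum(fl$w)
  }
  tot
}

#' M-step: maximize the expected complete-data log-likelihood
#'
#' Clone weights and signature exposures have closed-form updates (normalized
#' responsibility sums). The CCFs and the overdispersion have no closed form;
#' each `phi_j` is maximized by bracketed scalar search on (0, 1] holding the
#' others fixed, then `rho` over `rho_bounds` — a generalized EM step. Any
#' coordinate whose search does not improve the objective keeps its previous
#' value, so the expected complete-data log-likelihood never decreases.
#'
#' @param sample A [sigclone_sample()].
#' @param stats_prev Sufficient statistics from the internal E-step (list with
#'   `W`, `gnl`, `omega`, `denom`), or a `sigclone_resp` from [e_step()].
#' @param params_prev Current parameters.
#' @param sigs A [signature_matrix()].
#' @param config An [em_config()].
#' @param tie_pi Share one exposure vector across all clones (used by the
#'   constrained fit of the signature-change test)?
#' @param data Precomputed per-sample constants (internal reuse across
#'   iterations).
#' @return Updated [sigclone_params()].
#' @export
m_step <- function(sample, stats_prev, params_prev, sigs, config = em_config(),
                   tie_pi = FALSE, data = NULL) {
  if (inherits(stats_prev, "sigclone_resp")) stats_prev <- resp_to_stats(stats_prev)
  if (is.null(data)) data <- prepare_model_data(sample, sigs)
  snv <- sample$snvs
  N <- nrow(snv)
  J <- params_prev$J

  xi <- colSums(stats_prev$W) / N
  xi <- pmax(xi, 1e-12); xi <- xi / sum(xi)

  gnl <- stats_prev$gnl
  if (tie_pi) {
    row <- colSums(gnl)
    row <- pmax(row, 1e-12); row <- row / sum(row)
    pi <- matrix(rep(row, each = J), nrow = J)
  } else {
    pi <- gnl / pmax(rowSums(gnl), 1e-12)
    pi <- pmax(pi, 1e-12); pi <- pi / rowSums(pi)
  }

  phi <- params_prev$phi
  rho <- params_prev$rho
  flat <- flatten_omega(stats_prev$omega, data)
  for (j in seq_len(J)) {
    if (!length(flat[[j]]$w)) next
    obj <- function(ph) phi_objective(flat[[j]], ph, rho)
    cur <- obj(phi[j])
    opt <- stats::optimize(obj, interval = c(1e-4, 1), maximum = TRUE, tol = 1e-5)
    if (opt$objective > cur) phi[j] <- opt$maximum
  }
  obj_rho <- function(r) rho_objective(flat, phi, r)
  cur <- obj_rho(rho)
  opt <- stats::optimize(obj_rho, interval = config$rho_bounds, maximum = TRUE,
                         tol = 1e-3)
  if (opt$objective > cur) rho <- opt$maximum

  sigclone_params(xi, phi, pi, min(max(rho, config$rho_bounds[1]), config$rho_bounds[2]))
}

resp_to_stats <- function(resp) {
  g <- resp$gamma
  d <- dim(g)
  omega <- lapply(seq_len(d[4]), function(m) apply(g[, , , m, drop = FALSE], c(1, 2), sum))
  list(W = resp$clone, gnl = apply(g, c(2, 3), sum), omega = omega)
}

em_run <- function(sample, sigs, init, config, tie_pi = FALSE, data = NULL) {
  if (is.null(data)) data <- prepare_model_data(sample, sigs)
  params <- init
  trajectory <- numeric(0)
  converged <- FALSE
  prev <- -Inf
  st <- NULL
  for (it in seq_len(config$max_iter)) {
    st <- e_step_stats(sample, params, sigs, want_omega = TRUE, data = data)
    trajectory <- c(trajectory, st$loglik)
    if (is.finite(prev) &&
        abs(st$loglik - prev) < config$tol * max(abs(st$loglik), 1)) {
      converged <- TRUE
      break
    }
    prev <- st$loglik
    params <- m_step(sample, st, params, sigs, config, tie_pi = tie_pi, data = data)
  }
  list(params = params, loglik = trajectory[length(trajectory)],
       trajectory = trajectory, n_iter = length(trajectory),
       converged = converged)
}

new_fit_result <- function(run, J, config, seed = NULL, tied = FALSE) {
  structure(list(params = run$params, loglik = run$loglik,
                 n_iter = run$n_iter, converged = run$converged,
                 trajectory = run$trajectory, criterion = NA_real_,
                 J = J, tied_pi = tied, config = config, seed = seed),
            class = "sigclone_fit")
}

#' @export
print.sigclone_fit <- function(x, ...) {
  cat("sigclone_fit: J =", x$J, if (x$tied_pi) "(exposures tied across clones)" else "",
      "\n  loglik", format(x$loglik, digits = 8), "after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  if (!is.na(x$criterion)) cat("  selection criterion", format(x$criterion, digits = 8), "\n")
  print(x$params)
  invisible(x)
}

# random initialization reuses the simulator priors (with phi sorted so the
# top clone starts clonal), holding the sample's signature matrix
random_init <- function(sample, sigs, J, config) {
  dp <- draw_parameters(sim_config(J = J, N = 1, sigs = sigs))
  dp$params
}

#' Fit the mixture for a fixed number of clones
#'
#' Runs EM to convergence (relative log-likelihood change below `tol`, or
#' `max_iter`). When no initialization is given, `n_restarts` random
#' initializations drawn from the simulator priors are fitted and the best
#' log-likelihood kept. Deterministic given `config$seed`.
#'
#' @param sample A [sigclone_sample()].
#' @param sigs A [signature_matrix()].
#' @param J Number of clones.
#' @param init Optional [sigclone_params()] initialization.
#' @param config An [em_config()].
#' @param tie_pi Tie exposures across clones (constrained model)?
#' @return A `sigclone_fit`: parameters, final and per-iteration
#'   log-likelihood, iteration count, convergence flag.
#' @export
fit_fixed_j <- function(sample, sigs, J, init = NULL, config = em_config(),
                        tie_pi = FALSE) {
  run_all <- function() {
    data <- prepare_model_data(sample, sigs)
    if (!is.null(init)) {
      if (init$J != J) stop("initialization has ", init$J, " clones, expected ", J)
      best <- em_run(sample, sigs, init, config, tie_pi = tie_pi, data = data)
    } else {
      best <- NULL
      for (r in seq_len(max(config$n_restarts, 1L))) {
        ini <- random_init(sample, sigs, J, config)
        if (tie_pi) {
          row <- colSums(ini$xi * ini$pi)
          ini <- sigclone_params(ini$xi, ini$phi,
                                 matrix(rep(row / sum(row), each = J), nrow = J),
                                 ini$rho)
        }
        run <- em_run(sample, sigs, ini, config, tie_pi = tie_pi, data = data)
        if (is.null(best) || run$loglik > best$loglik) best <- run
      }
    }
    new_fit_result(best, J, config, seed = config$seed, tied = tie_pi)
  }
  if (is.null(config$seed)) run_all() else withr::with_seed(config$seed, run_all())
}

#' Split initialization for one more clone
#'
#' Duplicates the clone with the largest contribution `-xi_j * log(xi_j)` to
#' the mixture entropy: its weight is halved between the two copies and their
#' CCFs perturbed to `phi +/- delta` (clipped to (0, 1]); exposure rows are
#' copied and all other parameters retained.
#'
#' @param params_prev A fitted [sigclone_params()] with J clones.
#' @param delta CCF perturbation (default 0.05).
#' @return A [sigclone_params()] with J + 1 clones.
#' @export
split_init <- function(params_prev, delta = 0.05) {
  ent <- -params_prev$xi * log(params_prev$xi)
  js <- which.max(ent)
  xi <- params_prev$xi
  xi <- append(xi, xi[js] / 2, after = js)
  xi[js] <- xi[js] / 2
  phi <- params_prev$phi
  lo <- min(max(phi[js] - delta, 1e-3), 1)
  hi <- min(max(phi[js] + delta, 1e-3), 1)
  phi <- append(phi, lo, after = js)
  phi[js] <- hi
  pi <- params_prev$pi[c(seq_len(js), js, setdiff(seq_len(params_prev$J), seq_len(js))), ,
                       drop = FALSE]
  sigclone_params(xi, phi, pi, params_prev$rho)
}
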