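#' Constrained fit: one signature mixture shared by all clones
#'
#' The null model of the signature-change test — identical to the full model
#' except that the exposure vector is tied across clones (`pi_jl = pi_l`). The
#' shared exposure update pools responsibilities over clones. By default the
#' fit is initialized from the full fit's solution (with exposures collapsed to
#' their weight-averaged mixture) plus random restarts.
#'
#' @inheritParams fit_fixed_j
#' @param init_from Optional full-model `sigclone_fit` on the same data used to
#'   seed the constrained fit.
#' @return A `sigclone_fit` with `tied_pi = TRUE`.
#' @export
fit_constrained <- function(sample, sigs, J, init_from = NULL,
                            config = em_config()) {
  if (is.null(init_from)) return(fit_fixed_j(sample, sigs, J, config = config, tie_pi = TRUE))
  p <- init_from$params
  if (p$J != J) stop("init_from has ", p$J, " clones, expected ", J)
  row <- colSums(p$xi * p$pi)
  ini <- sigclone_params(p$xi, p$phi,
                         matrix(rep(row / sum(row), each = J), nrow = J), p$rho)
  seeded <- fit_fixed_j(sample, sigs, J, init = ini, config = config, tie_pi = TRUE)
  restarts <- fit_fixed_j(sample, sigs, J, config = config, tie_pi = TRUE)
  if (seeded$loglik >= restarts$loglik) seeded else restarts
}

#' Likelihood-ratio statistic for a signature change
#'
#' `2 * (loglik_full - loglik_constrained)`, floored at 0 (the constrained
#' model is nested in the full one, so a negative value can only arise from
#' local optima).
#'
#' @param fit_full,fit_constrained Fits of the full and tied-exposure models on
#'   identical data with the same number of clones.
#' @return Non-negative scalar.
#' @export
lrt_statistic <- function(fit_full, fit_constrained) {
  if (fit_full$J != fit_constrained$J)
    stop("fits compare different clone numbers (", fit_full$J, " vs ",
         fit_constrained$J, ")")
  max(2 * (fit_full$loglik - fit_constrained$loglik), 0)
}

# chi-square df fitted by maximum likelihood to a sample of statistics;
# zeros (floored statistics) are excluded and carried as a zero-inflation mass
fit_chisq_df <- function(stats, df_max = 500) {
  pos <- stats[stats > 1e-9]
  if (!length(pos)) return(list(df = NA_real_, zero_mass = 1))
  nll <- function(df) -sum(stats::dchisq(pos, df, log = TRUE))
  opt <- stats::optimize(nll, interval = c(1e-3, df_max))
  list(df = opt$minimum, zero_mass = 1 - length(pos) / length(stats))
}

closed_form_ridge <- function(X, y, lambda) {
  # intercept unpenalized
  Xd <- cbind(1, X)
  P <- diag(c(0, rep(lambda, ncol(X))))
  as.vector(solve(crossprod(Xd) + P, crossprod(Xd, y)))
}

#' Calibrate the chi-square degrees of freedom of the test
#'
#' Simulates null samples (shared exposures across clones) over a grid of
#' (J, L), computes the likelihood-ratio statistic of each, fits a chi-square
#' degrees-of-freedom per cell by maximum likelihood (zeros excluded as a
#' zero-inflation mass), and regresses the fitted df on J and L with ridge
#' regularization, averaging coefficients over cross-validation folds.
#'
#' @param sigs_by_L Named list mapping each L in the grid to a
#'   [signature_matrix()] with that many signatures.
#' @param grid Data.frame with columns `J`, `L`.
#' @param n_null_sims Null simulations per cell (>= 50).
#' @param N SNVs per simulated sample (default 300).
#' @param depth Mean depth (default 100).
#' @param em_cfg EM configuration for the per-simulation fits.
#' @param lambda Ridge strength (default 1).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `df_calibration`: list with `coefficients`
#'   (intercept, J, L), `cells` (per-cell fitted df and zero mass), `lambda`,
#'   `cv_folds`.
#' @export
calibrate_df <- function(sigs_by_L, grid, n_null_sims = 50, N = 300,
                         depth = 100, em_cfg = em_config(n_restarts = 2),
                         lambda = 1, cv_folds = 10, seed = 1) {
  if (n_null_sims < 50) stop("need at least 50 null simulations per grid cell")
  cells <- list()
  for (g in seq_len(nrow(grid))) {
    J <- grid$J[g]; L <- grid$L[g]
    sigs <- sigs_by_L[[as.character(L)]]
    if (is.null(sigs) || nrow(sigs) != L) stop("sigs_by_L lacks a matrix with L = ", L)
    stats <- numeric(n_null_sims)
    for (i in seq_len(n_null_sims)) {
      s <- seed + 1000L * g + i
      stats[i] <- null_lrt_statistic(sigs, J, N, depth, em_cfg, seed = s)
    }
    ft <- fit_chisq_df(stats)
    if (is.na(ft$df)) {
      warning("degenerate calibration cell (all statistics 0) at J=", J, ", L=", L,
              "; cell dropped")
      next
    }
    cells[[length(cells) + 1L]] <- data.frame(J = J, L = L, df = ft$df,
                                              zero_mass = ft$zero_mass)
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells) || nrow(cells) < 2) stop("too few usable calibration cells")
  X <- as.matrix(cells[, c("J", "L")])
  y <- cells$df
  n <- nrow(cells)
  folds <- rep(seq_len(cv_folds), length.out = n)
  folds <- withr::with_seed(seed, sample(folds))
  coefs <- matrix(0, nrow = 0, ncol = 3)
  for (f in unique(folds)) {
    keep <- folds != f
    if (sum(keep) < 2) keep <- rep(TRUE, n)
    coefs <- rbind(coefs, closed_form_ridge(X[keep, , drop = FALSE], y[keep], lambda))
  }
  structure(list(coefficients = colMeans(coefs), cells = cells,
                 lambda = lambda, cv_folds = cv_folds),
            class = "df_calibration")
}

# one null draw: simulate with tied exposures, fit full and constrained at the
# true J, return the LRT statistic
null_lrt_statistic <- function(sigs, J, N, depth, em_cfg, seed) {
  L <- nrow(sigs)
  cfg <- sim_config(J = J, N = N, sigs = sigs, depth = depth, seed = seed)
  sim <- withr::with_seed(seed, {
    dp <- draw_parameters(strip_seed(cfg))
    shared <- colSums(dp$params$xi * dp$params$pi)
    cfg2 <- cfg
    cfg2$pi <- matrix(rep(shared / sum(shared), each = J), nrow = J)
    cfg2$xi <- dp$params$xi; cfg2$phi <- dp$params$phi; cfg2$rho <- dp$params$rho
    cfg2$seed <- NULL
    simulate_sample(cfg2)
  })
  cfg_fit <- em_cfg; cfg_fit$seed <- seed
  full <- fit_fixed_j(sim$sample, sigs, J, config = cfg_fit)
  constr <- fit_constrained(sim$sample, sigs, J, init_from = full, config = cfg_fit)
  lrt_statistic(full, constr)
}

#' Predict degrees of freedom from a calibration
#'
#' @param calibration A `df_calibration` (or the shipped default).
#' @param J,L Clone and signature counts.
#' @return Predicted chi-square df (floored at 0.5).
#' @export
predict_df <- function(calibration, J, L) {
  b <- calibration$coefficients
  max(b[1] + b[2] * J + b[3] * L, 0.5)
}

#' The shipped default df calibration
#'
#' Generated once by [calibrate_df()] on simulator null draws; regenerable via
#' the `calibrate` CLI subcommand.
#'
#' @return A `df_calibration`.
#' @export
default_df_calibration <- function() {
  path <- system.file("extdata", "df_calibration.json", package = "sigclone")
  if (!nzchar(path)) stop("default df calibration sidecar is missing")
  read_df_calibration(path)
}

#' Read / write a df calibration
#'
#' @param path JSON file path.
#' @return `read_df_calibration`: a `df_calibration`.
#' @export
read_df_calibration <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(coefficients = as.numeric(x$coefficients),
                 cells = as.data.frame(x$cells),
                 lambda = x$lambda, cv_folds = x$cv_folds),
            class = "df_calibration")
}

#' @rdname read_df_calibration
#' @param calibration A `df_calibration`.
#' @export
write_df_calibration <- function(calibration, path) {
  jsonlite::write_json(list(version = 1L,
                            coefficients = calibration$coefficients,
                            cells = calibration$cells,
                            lambda = calibration$lambda,
                            cv_folds = calibration$cv_folds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Test for a change in signature activity between clones
#'
#' Compares a full fit against the tied-exposure null fit by a likelihood-ratio
#' test with simulation-calibrated chi-square degrees of freedom.
#'
#' @param sample A [sigclone_sample()].
#' @param sigs A [signature_matrix()].
#' @param fit_full A full-model `sigclone_fit` (e.g. from [fit_model()]).
#' @param calibration A `df_calibration` (default: shipped calibration).
#' @param alpha Significance level (default 0.05).
#' @param em_cfg EM configuration for the constrained fit.
#' @return A list of class `sigclone_lrt`: `statistic`, `df_used`, `p_value`,
#'   `significant`, plus the constrained fit. With one clone the statistic is
#'   0 and the p-value 1 (no change is testable).
#' @export
test_change <- function(sample, sigs, fit_full,
                        calibration = default_df_calibration(), alpha = 0.05,
                        em_cfg = fit_full$config) {
  J <- fit_full$J
  if (J == 1) {
    return(structure(list(statistic = 0, df_used = NA_real_, p_value = 1,
                          significant = FALSE, fit_constrained = fit_full,
                          alpha = alpha),
                     class = "sigclone_lrt"))
  }
  constr <- fit_constrained(sample, sigs, J, init_from = fit_full, config = em_cfg)
  stat <- lrt_statistic(fit_full, constr)
  df <- predict_df(calibration, J, nrow(sigs))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df_used = df, p_value = p,
                 significant = p < alpha, fit_constrained = constr,
                 alpha = alpha),
            class = "sigclone_lrt")
}

#' @export
print.sigclone_lrt <- function(x, ...) {
  cat("signature-change likelihood-ratio test\n")
  cat("  statistic", format(x$statistic, digits = 6), "on",
      format(x$df_used, digits = 4), "calibrated df; p =",
      format(x$p_value, digits = 4),
      if (isTRUE(x$significant)) "(significant)" else "", "\n")
  invisible(x)
}

#' Quantify signature-activity changes between clonal and largest subclone
#'
#' The clonal clone is the one with the highest CCF; the largest subclone is
#' the remaining clone with the largest expected number of mutations. Reports,
#' per signature, the clonal and subclonal activities, their absolute
#' difference (only entries with `|diff| > 0.05` are flagged as reported), and
#' the log-fold change `log(A_sub / A_clonal)` with activities below `1e-4`
#' replaced by `1e-4` and pairs where both are below `1e-4` excluded.
#'
#' @param fit_full A `sigclone_fit` with J >= 2 (J = 1 returns an empty report).
#' @param sig_names Optional signature names.
#' @return A data.frame of class `sigclone_changes` with columns `signature`,
#'   `clonal_activity`, `subclonal_activity`, `abs_diff`, `reported`,
#'   `log_fold`; attributes `clonal_clone` and `largest_subclone`.
#' @export
quantify_changes <- function(fit_full, sig_names = NULL) {
  p <- fit_full$params
  L <- ncol(p$pi)
  if (is.null(sig_names)) sig_names <- paste0("S", seq_len(L))
  if (p$J < 2) {
    out <- data.frame(signature = character(0), clonal_activity = numeric(0),
                      subclonal_activity = numeric(0), abs_diff = numeric(0),
                      reported = logical(0), log_fold = numeric(0))
    return(structure(out, class = c("sigclone_changes", "data.frame"),
                     clonal_clone = NA_integer_, largest_subclone = NA_integer_))
  }
  clonal <- which.max(p$phi)
  rest <- setdiff(seq_len(p$J), clonal)
  sub <- rest[which.max(p$xi[rest])]
  a_cl <- p$pi[clonal, ]
  a_sub <- p$pi[sub, ]
  diff <- a_sub - a_cl
  floor4 <- function(x) pmax(x, 1e-4)
  lf <- log(floor4(a_sub) / floor4(a_cl))
  lf[a_sub < 1e-4 & a_cl < 1e-4] <- NA_real_
  out <- data.frame(signature = sig_names, clonal_activity = a_cl,
                    subclonal_activity = a_sub, abs_diff = diff,
                    reported = abs(diff) > 0.05, log_fold = lf)
  structure(out, class = c("sigclone_changes", "data.frame"),
            clonal_clone = clonal, largest_subclone = sub)
}
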