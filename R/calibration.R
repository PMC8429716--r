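#' Calibrate the model-selection penalty scale
#'
#' Fixed penalized-likelihood criteria under- or over-penalize as the number of
#' SNVs varies, so the penalty scale is calibrated against the simulator: for
#' each sample size in `N_grid` and each true clone number in `J_grid`,
#' `n_reps` samples are simulated, the model is fitted at every J up to
#' `j_max`, and each candidate scale is scored by the mean clone-number
#' adequacy ([score1b()]) of the J it selects. The best scale per sample size
#' is returned as an adaptive table.
#'
#' @param sigs A [signature_matrix()].
#' @param N_grid Sample sizes to calibrate (default `c(100, 300, 1000)`).
#' @param J_grid True clone numbers (default `1:4`).
#' @param scales Candidate penalty scales.
#' @param n_reps Simulated samples per (N, J) cell.
#' @param j_max Maximum clones fitted.
#' @param depth Mean sequencing depth.
#' @param em_cfg EM configuration.
#' @param seed Integer seed.
#' @return A data.frame with columns `N`, `L`, `penalty_scale` (one row per
#'   sample size), with attribute `"score_table"` holding the full grid of
#'   mean scores.
#' @export
calibrate_penalty_scale <- function(sigs, N_grid = c(100, 300, 1000),
                                    J_grid = 1:4,
                                    scales = c(0.5, 1, 1.5, 2, 3, 4),
                                    n_reps = 5, j_max = 6, depth = 100,
                                    em_cfg = em_config(), seed = 1) {
  L <- nrow(sigs)
  rows <- list()
  for (N in N_grid) {
    hits <- matrix(0, nrow = length(scales), ncol = 0)
    for (J in J_grid) {
      for (r in seq_len(n_reps)) {
        s <- seed + 7919L * which(N_grid == N) + 101L * J + r
        sim <- simulate_sample(sim_config(J = J, N = N, sigs = sigs,
                                          depth = depth, seed = s))
        cfg <- em_cfg; cfg$seed <- s
        logliks <- numeric(j_max)
        prev <- NULL
        for (jj in seq_len(j_max)) {
          fit <- if (jj == 1) fit_fixed_j(sim$sample, sigs, 1, config = cfg)
          else {
            cfg_j <- cfg; cfg_j$seed <- s + jj
            fit_fixed_j(sim$sample, sigs, jj, init = split_init(prev$params),
                        config = cfg_j)
          }
          logliks[jj] <- fit$loglik
          prev <- fit
        }
        pen <- free_parameter_count(seq_len(j_max), L) * log(N) / 2
        sc <- vapply(scales, function(a) {
          score1b(J, which.max(logliks - a * pen))
        }, numeric(1))
        hits <- cbind(hits, sc)
      }
    }
    mean_sc <- rowMeans(hits)
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, L = L, penalty_scale = scales[which.max(mean_sc)])
    attr(rows[[length(rows)]], "scores") <- mean_sc
  }
  out <- do.call(rbind, rows)
  attr(out, "score_table") <- lapply(rows, attr, "scores")
  out
}
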