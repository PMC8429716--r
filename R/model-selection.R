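#' Number of free parameters of a J-clone, L-signature model
#'
#' `(J - 1)` clone weights + `J` CCFs + `J * (L - 1)` exposure entries + the
#' overdispersion.
#'
#' @param J,L Clone and signature counts.
#' @return Integer parameter count.
#' @export
free_parameter_count <- function(J, L) {
  stopifnot(J >= 1, L >= 1)
  (J - 1) + J + J * (L - 1) + 1
}

#' Model-selection configuration
#'
#' @param j_max Maximum number of clones tried (default 8).
#' @param penalty_scale Multiplier on the complexity penalty (default 1 is
#'   plain BIC; the shipped adaptive table overrides it per sample size).
#' @param adaptive_table Optional calibration table mapping sample size (and
#'   signature count) to a penalty scale, as returned by
#'   [read_adaptive_table()]; `NULL` disables adaptivity.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(j_max = 8, penalty_scale = 1,
                             adaptive_table = default_adaptive_table()) {
  if (j_max < 1) stop("j_max must be >= 1")
  if (penalty_scale <= 0) stop("penalty_scale must be positive")
  structure(list(j_max = as.integer(j_max), penalty_scale = penalty_scale,
                 adaptive_table = adaptive_table),
            class = "selection_config")
}

#' Penalized-likelihood model-selection criterion
#'
#' BIC-shaped: `loglik - scale * k * log(N) / 2` with
#' `k = free_parameter_count(J, L)`; higher is better. With `scale = 1` this is
#' `-BIC / 2`. The scale is taken from the adaptive table when one is
#' configured (keyed on sample size), otherwise from `config$penalty_scale`.
#'
#' @param fit A `sigclone_fit`.
#' @param N Number of SNVs.
#' @param L Number of signatures.
#' @param config A [selection_config()].
#' @return Scalar criterion value.
#' @export
selection_criterion <- function(fit, N, L, config = selection_config()) {
  scale <- lookup_penalty_scale(config, N, L)
  fit$loglik - scale * free_parameter_count(fit$J, L) * log(N) / 2
}

lookup_penalty_scale <- function(config, N, L) {
  tab <- config$adaptive_table
  if (is.null(tab) || nrow(tab) == 0) return(config$penalty_scale)
  # nearest sample-size bucket on the log scale; L is matched when present
  if ("L" %in% names(tab) && any(tab$L == L)) tab <- tab[tab$L == L, , drop = FALSE]
  i <- which.min(abs(log(tab$N) - log(N)))
  tab$penalty_scale[i]
}

#' The shipped adaptive penalty table
#'
#' Calibrated once on simulator-generated samples by
#' [calibrate_penalty_scale()]; regenerable with the `calibrate` CLI
#' subcommand.
#'
#' @return A data.frame with columns `N`, `L`, `penalty_scale`, or `NULL` if
#'   the sidecar is missing.
#' @export
default_adaptive_table <- function() {
  path <- system.file("extdata", "adaptive_penalty.json", package = "sigclone")
  if (!nzchar(path)) return(NULL)
  read_adaptive_table(path)
}

#' Read / write an adaptive penalty table
#'
#' @param path JSON file path.
#' @return `read_adaptive_table`: a data.frame with columns `N`, `L`,
#'   `penalty_scale`.
#' @export
read_adaptive_table <- function(path) {
  as.data.frame(jsonlite::fromJSON(path)$table)
}

#' @rdname read_adaptive_table
#' @param table Data.frame with columns `N`, `L`, `penalty_scale`.
#' @export
write_adaptive_table <- function(table, path) {
  jsonlite::write_json(list(version = 1L, table = table), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit the model with an inferred number of clones
#'
#' Fits J = 1 with random restarts, then increases J one clone at a time,
#' initializing each fit by splitting the highest-entropy clone of the
#' previous solution ([split_init()]). Stops at `j_max` or once the selection
#' criterion has strictly decreased for two successive values of J, and
#' returns the fit maximizing the criterion among those computed.
#'
#' @param sample A [sigclone_sample()].
#' @param sigs A [signature_matrix()].
#' @param em_cfg An [em_config()].
#' @param sel_cfg A [selection_config()].
#' @param keep_all Also return the full list of per-J fits?
#' @return The best `sigclone_fit` (criterion filled in); when
#'   `keep_all = TRUE`, attribute `"all_fits"` carries every fitted J.
#' @export
fit_model <- function(sample, sigs, em_cfg = em_config(),
                      sel_cfg = selection_config(), keep_all = FALSE) {
  N <- n_snvs(sample)
  L <- nrow(sigs)
  fits <- list()
  crit <- numeric(0)
  decreases <- 0L
  for (J in seq_len(sel_cfg$j_max)) {
    fit <- if (J == 1) {
      fit_fixed_j(sample, sigs, 1, config = em_cfg)
    } else {
      cfg_j <- em_cfg
      cfg_j$seed <- if (is.null(em_cfg$seed)) NULL else em_cfg$seed + J
      fit_fixed_j(sample, sigs, J, init = split_init(fits[[J - 1]]$params),
                  config = cfg_j)
    }
    fit$criterion <- selection_criterion(fit, N, L, sel_cfg)
    fits[[J]] <- fit
    crit <- c(crit, fit$criterion)
    if (J >= 2 && crit[J] < crit[J - 1]) decreases <- decreases + 1L else decreases <- 0L
    if (decreases >= 2L) break
  }
  best <- fits[[which.max(crit)]]
  if (keep_all) attr(best, "all_fits") <- fits
  best
}
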