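#' Construct a signature matrix
#'
#' A signature matrix holds L known mutational processes as probability
#' distributions over the 96 SBS mutation types (rows = signatures, columns =
#' mutation types in canonical order, each row summing to 1).
#'
#' @param mu Numeric L x 96 matrix; rows are renormalized only if they sum to 1
#'   within `1e-8`, otherwise an error is raised.
#' @param names Character vector of L signature identifiers; defaults to
#'   rownames of `mu` or `"S1"..."SL"`.
#' @return An object of class `signature_matrix`: the validated matrix with
#'   rownames set to the signature names and colnames to [sbs96_labels()].
#' @export
signature_matrix <- function(mu, names = NULL) {
  mu <- as.matrix(mu)
  if (ncol(mu) != 96) stop("signature matrix must have 96 columns (mutation types)")
  if (nrow(mu) < 1) stop("at least one signature is required")
  if (any(mu < 0)) stop("signature probabilities must be non-negative")
  rs <- rowSums(mu)
  if (any(abs(rs - 1) > 1e-8)) stop("signature rows must sum to 1 (max |deviation| = ",
                                    format(max(abs(rs - 1))), ")")
  if (is.null(names)) names <- rownames(mu)
  if (is.null(names)) names <- paste0("S", seq_len(nrow(mu)))
  if (length(names) != nrow(mu) || anyDuplicated(names))
    stop("signature names must be unique and match the number of rows")
  dimnames(mu) <- list(names, sbs96_labels())
  structure(mu, class = c("signature_matrix", "matrix", "array"))
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", nrow(x), "signatures x 96 mutation types\n")
  cat("signatures:", paste(utils::head(rownames(x), 8), collapse = ", "),
      if (nrow(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read a signature matrix from a tab-separated file
#'
#' Accepts the COSMIC layout (first column the mutation-type label, one column
#' per signature) or its transpose (one row per signature); the orientation is
#' auto-detected by checking which axis has 96 entries. Mutation types are
#' reordered to canonical SBS96 order.
#'
#' @param path Path to a TSV file.
#' @return A [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  first <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) == 96 && all(first %in% sbs96_labels())) {
    # types in rows, signatures in columns
    mu <- t(m[order(mutation_type_index(first)), , drop = FALSE])
    sn <- colnames(df)[-1]
  } else if (ncol(m) == 96 && all(colnames(m) %in% sbs96_labels())) {
    mu <- m[, order(mutation_type_index(colnames(m))), drop = FALSE]
    sn <- first
  } else {
    stop("cannot detect signature-matrix orientation in ", path,
         ": neither axis carries the 96 SBS labels")
  }
  signature_matrix(mu, names = sn)
}

#' Generate a synthetic signature matrix
#'
#' Draws L random signatures as sparse Dirichlet profiles over the 96 mutation
#' types. Useful for simulation studies and tests when a curated catalogue is
#' not needed; these are synthetic profiles, not COSMIC signatures.
#'
#' @param L Number of signatures.
#' @param concentration Dirichlet concentration per type (default 0.15 gives
#'   peaked, realistic-looking profiles).
#' @param seed Optional seed for reproducibility.
#' @return A [signature_matrix()].
#' @export
random_signature_matrix <- function(L, concentration = 0.15, seed = NULL) {
  draw <- function() {
    mu <- matrix(stats::rgamma(L * 96, shape = concentration), nrow = L)
    mu <- mu / rowSums(mu)
    signature_matrix(mu)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
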