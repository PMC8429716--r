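#' Assemble per-sample SNV observations
#'
#' The observed variables of the model, per SNV: variant read count `B`, total
#' depth `D`, mutation-type index `type` (1..96, SBS96 canonical order), and the
#' allele-specific clonal copy-number state (`C_normal`, `C_major`, `C_minor`),
#' together with the tumor purity of the sample.
#'
#' @param snvs A data.frame with integer columns `B`, `D`, `type`, `C_normal`,
#'   `C_major`, `C_minor` (one row per SNV). `type` may instead be a character
#'   column of SBS96 labels, converted on the fly.
#' @param purity Tumor purity, a scalar in (0, 1].
#' @return An object of class `sigclone_sample`: a list with elements `snvs`
#'   (validated data.frame) and `purity`.
#' @export
sigclone_sample <- function(snvs, purity) {
  snvs <- as.data.frame(snvs)
  req <- c("B", "D", "type", "C_normal", "C_major", "C_minor")
  miss <- setdiff(req, names(snvs))
  if (length(miss)) stop("missing SNV columns: ", paste(miss, collapse = ", "))
  if (is.character(snvs$type)) snvs$type <- mutation_type_index(snvs$type)
  snvs <- snvs[req]
  for (cn in req) snvs[[cn]] <- as.integer(snvs[[cn]])
  n <- nrow(snvs)
  if (n < 1) stop("a sample must contain at least one SNV")
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity <= 0 || purity > 1)
    stop("purity must be a scalar in (0, 1]")
  with(snvs, {
    if (any(B < 0) || any(D < 1) || any(B > D)) stop("need 0 <= B <= D and D >= 1")
    if (any(type < 1 | type > 96)) stop("mutation-type index out of 1..96")
    if (any(C_normal < 1)) stop("C_normal must be >= 1")
    if (any(C_major < 1)) stop("C_major must be >= 1: an observed SNV cannot sit on zero copies")
    if (any(C_minor < 0) || any(C_minor > C_major)) stop("need 0 <= C_minor <= C_major")
  })
  structure(list(snvs = snvs, purity = as.numeric(purity)),
            class = "sigclone_sample")
}

#' @export
print.sigclone_sample <- function(x, ...) {
  cat("sigclone_sample:", nrow(x$snvs), "SNVs, purity", format(x$purity, digits = 3), "\n")
  cat("  mean depth", format(mean(x$snvs$D), digits = 4),
      "| mean VAF", format(mean(x$snvs$B / x$snvs$D), digits = 3),
      "| diploid fraction",
      format(mean(x$snvs$C_major == 1 & x$snvs$C_minor == 1 & x$snvs$C_normal == 2),
             digits = 3), "\n")
  invisible(x)
}

#' Number of SNVs in a sample
#' @param sample A [sigclone_sample()].
#' @return Integer count.
#' @export
n_snvs <- function(sample) nrow(sample$snvs)

#' Construct the full model parameter state
#'
#' The free parameters of the mixture: the number of clones `J`, clone weights
#' `xi` (simplex of length J), clone cancer-cell fractions `phi` (each in
#' (0, 1]), per-clone signature exposures `pi` (J x L, rows simplices) and the
#' beta-binomial overdispersion `rho` (> 0; the precision of the read-count
#' emission).
#'
#' @param xi Clone weights.
#' @param phi Clone CCFs.
#' @param pi J x L exposure matrix (a vector is accepted for J = 1).
#' @param rho Overdispersion scalar.
#' @return An object of class `sigclone_params`.
#' @export
sigclone_params <- function(xi, phi, pi, rho) {
  if (is.vector(pi)) pi <- matrix(pi, nrow = 1)
  pi <- as.matrix(pi)
  J <- length(xi)
  if (J < 1) stop("need at least one clone")
  if (length(phi) != J || nrow(pi) != J) stop("xi, phi and rows of pi must share length J")
  if (abs(sum(xi) - 1) > 1e-8 || any(xi < 0)) stop("xi must be a probability simplex")
  if (any(phi <= 0) || any(phi > 1)) stop("phi entries must lie in (0, 1]")
  if (any(pi < 0) || any(abs(rowSums(pi) - 1) > 1e-8)) stop("pi rows must be probability simplices")
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) stop("rho must be a positive scalar")
  structure(list(J = J, xi = as.numeric(xi), phi = as.numeric(phi),
                 pi = unname(pi), rho = as.numeric(rho)),
            class = "sigclone_params")
}

#' @export
print.sigclone_params <- function(x, ...) {
  cat("sigclone_params: J =", x$J, "clones,", ncol(x$pi), "signatures, rho =",
      format(x$rho, digits = 4), "\n")
  tab <- data.frame(clone = seq_len(x$J), weight = round(x$xi, 3), ccf = round(x$phi, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
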