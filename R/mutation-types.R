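#' The SBS96 mutation-type space
#'
#' Somatic single-base substitutions are classified into 96 types: the
#' substitution written with a pyrimidine reference base (C>A, C>G, C>T, T>A,
#' T>C, T>G) together with the 5' and 3' flanking bases. Labels follow the
#' COSMIC convention, e.g. `"A[C>A]A"`. The index of a type is
#' `sub_idx * 16 + five_prime_idx * 4 + three_prime_idx + 1` with the flank
#' alphabet ordered A, C, G, T (substitution-major order).
#'
#' @return Character vector of the 96 labels in canonical order.
#' @export
#' @examples
#' head(sbs96_labels())
#' mutation_type_index("A[C>A]A") # 1
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flank <- c("A", "C", "G", "T")
  labs <- character(96)
  k <- 1L
  for (s in subs) {
    for (f5 in flank) {
      for (f3 in flank) {
        labs[k] <- paste0(f5, "[", s, "]", f3)
        k <- k + 1L
      }
    }
  }
  labs
}

#' Map SBS96 labels to canonical indices
#'
#' @param labels Character vector of labels such as `"A[C>A]A"`.
#' @return Integer vector of indices in `1:96`; unknown labels are an error.
#' @export
mutation_type_index <- function(labels) {
  idx <- match(labels, sbs96_labels())
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown mutation-type label(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  idx
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a substitution with its trinucleotide context
#'
#' Builds the pyrimidine-centric SBS96 label from reference base, alternate
#' base and flanking bases. Purine-reference substitutions are
#' reverse-complemented.
#'
#' @param ref,alt Single reference/alternate bases (vectors accepted).
#' @param five_prime,three_prime Flanking bases on the reference strand.
#' @return Character vector of SBS96 labels.
#' @export
#' @examples
#' context_to_type("C", "A", "A", "A") # "A[C>A]A"
#' context_to_type("G", "T", "T", "T") # reverse complement -> "A[C>A]A"
context_to_type <- function(ref, alt, five_prime, three_prime) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(five_prime) == n, length(three_prime) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  five_prime <- toupper(five_prime); three_prime <- toupper(three_prime)
  ok <- ref %in% names(REV_COMP) & alt %in% names(REV_COMP) &
    five_prime %in% names(REV_COMP) & three_prime %in% names(REV_COMP) & ref != alt
  if (!all(ok)) stop("invalid base in substitution context at row(s) ",
                     paste(utils::head(which(!ok), 5), collapse = ", "))
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, REV_COMP[ref], ref)
  a <- ifelse(flip, REV_COMP[alt], alt)
  f5 <- ifelse(flip, REV_COMP[three_prime], five_prime)
  f3 <- ifelse(flip, REV_COMP[five_prime], three_prime)
  paste0(f5, "[", r, ">", a, "]", f3)
}
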