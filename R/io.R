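#' Read an SNV table from TSV or VCF
#'
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt`, `B`, `D` and either a
#' `mutation_type` column (SBS96 label), a `context` column (reference-strand
#' trinucleotide, e.g. `"ACA"`), or a reference FASTA for context lookup.
#' Optional columns `normal_B`, `normal_D`, `pop_freq`, `in_cosmic` are carried
#' through for [tcga_style_filter()]. VCF input takes `B`/`D` from the first
#' sample's `AD`/`DP` FORMAT fields. Indels and multi-allelic records are
#' dropped (counts reported via attribute `"dropped"`). Mutation types are
#' pyrimidine-centric; purine-reference records are reverse-complemented.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param reference Optional FASTA path for trinucleotide-context extraction.
#' @return A data.frame of SNV rows with a canonical `mutation_type` column;
#'   attribute `"dropped"` holds per-reason drop counts.
#' @export
read_snvs <- function(path, format = c("tsv", "vcf"), reference = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  dropped <- c(indel = 0L, multiallelic = 0L)
  if (format == "tsv") {
    # read everything as character first: "T" in ref/alt must not become logical
    df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    req <- c("chrom", "pos", "ref", "alt", "B", "D")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("missing SNV-table column(s): ", paste(miss, collapse = ", "))
    for (cn in intersect(c("pos", "B", "D", "normal_B", "normal_D"), names(df)))
      df[[cn]] <- as.integer(df[[cn]])
    if ("pop_freq" %in% names(df)) df$pop_freq <- as.numeric(df$pop_freq)
    if ("in_cosmic" %in% names(df)) df$in_cosmic <- as.logical(df$in_cosmic)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    df <- data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                     ref = fx$REF, alt = fx$ALT, stringsAsFactors = FALSE)
    multi <- grepl(",", df$alt)
    dropped["multiallelic"] <- sum(multi)
    ad <- tryCatch(vcfR::extract.gt(v, "AD")[, 1], error = function(e) NULL)
    dp <- tryCatch(as.integer(vcfR::extract.gt(v, "DP")[, 1]), error = function(e) NULL)
    if (is.null(ad)) stop("VCF lacks a FORMAT AD field for read counts")
    B <- as.integer(vapply(strsplit(ad, ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1)))
    D <- if (!is.null(dp) && !all(is.na(dp))) dp else
      as.integer(vapply(strsplit(ad, ","), function(x) sum(as.integer(x)), integer(1)))
    df$B <- B; df$D <- D
    df <- df[!multi, , drop = FALSE]
  }
  snv_like <- nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    toupper(df$ref) %in% c("A", "C", "G", "T") & toupper(df$alt) %in% c("A", "C", "G", "T")
  dropped["indel"] <- dropped["indel"] + sum(!snv_like)
  df <- df[snv_like, , drop = FALSE]
  bad <- which(is.na(df$B) | is.na(df$D) | df$B > df$D | df$D < 1)
  if (length(bad)) stop("malformed read counts at row(s) ", paste(utils::head(bad, 5), collapse = ", "))

  if (!"mutation_type" %in% names(df)) {
    if ("context" %in% names(df)) {
      ctx <- toupper(df$context)
      if (any(nchar(ctx) != 3)) stop("context column must hold trinucleotides")
      df$mutation_type <- context_to_type(df$ref, df$alt,
                                          substr(ctx, 1, 1), substr(ctx, 3, 3))
    } else if (!is.null(reference)) {
      df$mutation_type <- context_from_fasta(df, reference)
    } else {
      stop("no mutation type available: provide a mutation_type or context column, ",
           "or a reference FASTA")
    }
  } else {
    # normalize possibly purine-centered labels
    m <- regmatches(df$mutation_type,
                    regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", df$mutation_type))
    if (any(lengths(m) != 5)) stop("malformed mutation_type label(s)")
    parts <- do.call(rbind, m)
    df$mutation_type <- context_to_type(parts[, 3], parts[, 4], parts[, 2], parts[, 5])
  }
  attr(df, "dropped") <- dropped
  df
}

context_from_fasta <- function(df, reference) {
  fa <- Biostrings::readDNAStringSet(reference)
  names(fa) <- sub("\\s.*$", "", names(fa))
  miss <- setdiff(unique(df$chrom), names(fa))
  if (length(miss)) stop("chromosome(s) absent from reference: ", paste(miss, collapse = ", "))
  f5 <- character(nrow(df)); f3 <- character(nrow(df)); ref_fa <- character(nrow(df))
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    seq <- fa[[ch]]
    if (any(df$pos[i] < 2) || any(df$pos[i] > length(seq) - 1))
      stop("SNV position lacks flanking bases on ", ch)
    tri <- as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(df$pos[i] - 1, df$pos[i] + 1)))
    f5[i] <- substr(tri, 1, 1); f3[i] <- substr(tri, 3, 3)
    ref_fa[i] <- substr(tri, 2, 2)
  }
  mismatch <- toupper(ref_fa) != toupper(df$ref)
  if (any(mismatch)) stop("reference-base mismatch at ", sum(mismatch), " position(s)")
  context_to_type(df$ref, df$alt, f5, f3)
}

#' Validate a copy-number segment table
#'
#' Only clonal segments are accepted. If the table carries a `ccf` column
#' (segment cellular prevalence), overlapping events are collapsed by keeping
#' the one with the largest CCF — the standard treatment of subclonal
#' copy-number calls by methods that assume clonal copy number. Without a
#' `ccf` column, overlapping segments are an error.
#'
#' @param segments Data.frame with `chrom`, `start`, `end`, `major`, `minor`
#'   and optionally `ccf`. Coordinates are interpreted per `coords`:
#'   `"1-based-inclusive"` (the ASCAT convention, default) is converted to the
#'   internal 0-based half-open form.
#' @param coords Input coordinate convention.
#' @return Validated data.frame (0-based half-open), non-overlapping per
#'   chromosome.
#' @export
validate_segments <- function(segments, coords = c("1-based-inclusive", "0-based-half-open")) {
  coords <- match.arg(coords)
  req <- c("chrom", "start", "end", "major", "minor")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("missing segment column(s): ", paste(miss, collapse = ", "))
  has_ccf <- "ccf" %in% names(segments)
  seg <- as.data.frame(segments)[c(req, if (has_ccf) "ccf")]
  if (coords == "1-based-inclusive") seg$start <- seg$start - 1
  if (any(seg$start >= seg$end)) stop("segments must satisfy start < end")
  if (any(seg$major < 0) || any(seg$minor < 0) || any(seg$minor > seg$major))
    stop("need 0 <= minor <= major per segment")
  if (has_ccf) {
    # keep-the-largest-CCF collapsing: greedily accept segments in decreasing
    # CCF order, dropping any that overlap an accepted one
    ord <- order(-seg$ccf)
    kept <- integer(0)
    gr_all <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start + 1, seg$end))
    for (i in ord) {
      if (!length(kept) ||
          !length(GenomicRanges::findOverlaps(gr_all[i], gr_all[kept])))
        kept <- c(kept, i)
    }
    seg <- seg[sort(kept), setdiff(names(seg), "ccf"), drop = FALSE]
  }
  gr <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start + 1, seg$end))
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov))
    stop("overlapping segments at row pairs: ",
         paste(utils::head(paste(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov), sep = "/"), 5),
               collapse = ", "))
  seg
}

#' Annotate SNVs with their covering copy-number segment
#'
#' Joins each SNV to the clonal allele-specific copy-number segment covering
#' its position. SNVs with no covering segment, or covered by a segment with
#' major copy number 0, are excluded (counts in attribute `"excluded"`).
#'
#' @param snvs SNV data.frame from [read_snvs()].
#' @param segments Segment table (validated via [validate_segments()]).
#' @param default_normal Normal-cell total copy number (default 2).
#' @param coords Coordinate convention of `segments`.
#' @param sex `"male"` sets the normal copy number of X/Y SNVs to 1;
#'   `"female"` keeps 2 on X (Y SNVs are excluded); the default `"unknown"`
#'   keeps `default_normal` everywhere with a warning when sex-chromosome
#'   SNVs are present.
#' @return The SNV data.frame with `C_normal`, `C_major`, `C_minor` columns and
#'   a `type` column of mutation-type indices.
#' @export
annotate_copy_number <- function(snvs, segments, default_normal = 2L,
                                 coords = "1-based-inclusive",
                                 sex = c("unknown", "female", "male")) {
  sex <- match.arg(sex)
  seg <- validate_segments(segments, coords)
  gr_seg <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start + 1, seg$end))
  gr_snv <- GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos, snvs$pos))
  hit <- GenomicRanges::findOverlaps(gr_snv, gr_seg, select = "first")
  excluded <- c(no_segment = sum(is.na(hit)), zero_major = 0L)
  keep <- !is.na(hit)
  out <- snvs[keep, , drop = FALSE]
  h <- hit[keep]
  out$C_major <- as.integer(seg$major[h])
  out$C_minor <- as.integer(seg$minor[h])
  out$C_normal <- as.integer(default_normal)
  plain <- sub("^chr", "", out$chrom)
  excluded["y_in_female"] <- 0L
  if (any(plain %in% c("X", "Y"))) {
    if (sex == "male") {
      out$C_normal[plain %in% c("X", "Y")] <- 1L
    } else if (sex == "female") {
      excluded["y_in_female"] <- sum(plain == "Y")
      out <- out[plain != "Y", , drop = FALSE]
    } else {
      warning(sum(plain %in% c("X", "Y")), " X/Y SNV(s) kept with C_normal = ",
              default_normal, "; pass `sex` for haploid handling")
    }
  }
  zero <- out$C_major < 1
  excluded["zero_major"] <- sum(zero)
  out <- out[!zero, , drop = FALSE]
  out$type <- mutation_type_index(out$mutation_type)
  attr(out, "excluded") <- excluded
  out
}

#' Coverage and frequency filters for cohort-style SNV calls
#'
#' Keeps SNVs with: normal depth >= 6 with at most 1 variant read (or normal
#' VAF < 0.01); tumor depth >= 8 with at least 3 variant reads (or tumor
#' VAF > 0.2). When population-frequency annotations are present, SNVs with
#' frequency > 0.01 are additionally dropped unless COSMIC-flagged. Missing
#' normal columns skip the normal rules with a warning.
#'
#' @param rows SNV data.frame with `B`, `D` and optionally `normal_B`,
#'   `normal_D`, `pop_freq`, `in_cosmic`.
#' @return Filtered data.frame; attribute `"drop_counts"` gives per-rule drops.
#' @export
tcga_style_filter <- function(rows) {
  n0 <- nrow(rows)
  keep <- rep(TRUE, n0)
  drops <- c(normal_coverage = 0L, tumor_coverage = 0L, pop_freq = 0L)
  if (all(c("normal_B", "normal_D") %in% names(rows))) {
    nv <- rows$normal_B / pmax(rows$normal_D, 1)
    ok <- rows$normal_D >= 6 & (rows$normal_B <= 1 | nv < 0.01)
    drops["normal_coverage"] <- sum(keep & !ok)
    keep <- keep & ok
  } else {
    warning("normal-sample read counts absent; normal coverage rules skipped")
  }
  tv <- rows$B / pmax(rows$D, 1)
  ok <- rows$D >= 8 & (rows$B >= 3 | tv > 0.2)
  drops["tumor_coverage"] <- sum(keep & !ok)
  keep <- keep & ok
  if ("pop_freq" %in% names(rows)) {
    cosmic <- if ("in_cosmic" %in% names(rows)) as.logical(rows$in_cosmic) else FALSE
    pf <- rows$pop_freq
    ok <- is.na(pf) | pf <= 0.01 | cosmic
    drops["pop_freq"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- rows[keep, , drop = FALSE]
  attr(out, "drop_counts") <- drops
  stopifnot(sum(drops) + nrow(out) == n0)
  out
}

#' Write / read a simulated sample as TSV
#'
#' One SNV per row: placeholder chromosome, mutation-type label, `B`, `D`,
#' `C_normal`, `C_major`, `C_minor`; purity is carried in a `#purity=` header
#' line.
#'
#' @param sample A [sigclone_sample()].
#' @param path Output TSV path.
#' @export
write_sample_tsv <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#purity=", format(sample$purity, digits = 15)), con)
  df <- data.frame(chrom = "sim", mutation_type = sbs96_labels()[sample$snvs$type],
                   B = sample$snvs$B, D = sample$snvs$D,
                   C_normal = sample$snvs$C_normal, C_major = sample$snvs$C_major,
                   C_minor = sample$snvs$C_minor)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' @rdname write_sample_tsv
#' @param purity Purity override when the header line is absent.
#' @export
read_sample_tsv <- function(path, purity = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^#purity=", first)) purity <- as.numeric(sub("^#purity=", "", first))
  if (is.null(purity)) stop("purity not found in header; pass `purity`")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sigclone_sample(data.frame(B = df$B, D = df$D, type = df$mutation_type,
                             C_normal = df$C_normal, C_major = df$C_major,
                             C_minor = df$C_minor),
                  purity = purity)
}

#' Serialize a fit to JSON
#'
#' A versioned document holding the fitted parameters, final and per-iteration
#' log-likelihoods, convergence information, the selection criterion, and an
#' echo of the EM configuration and seed.
#'
#' @param fit A `sigclone_fit`.
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fit, path) {
  doc <- list(version = 1L, J = fit$J, tied_pi = fit$tied_pi,
              params = list(xi = fit$params$xi, phi = fit$params$phi,
                            pi = fit$params$pi, rho = fit$params$rho),
              loglik = fit$loglik, criterion = fit$criterion,
              n_iter = fit$n_iter, converged = fit$converged,
              trajectory = fit$trajectory,
              config = fit$config[c("max_iter", "tol", "n_restarts", "rho_bounds")],
              seed = fit$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  params <- sigclone_params(x$params$xi, x$params$phi, x$params$pi, x$params$rho)
  structure(list(params = params, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, trajectory = x$trajectory,
                 criterion = if (is.null(x$criterion)) NA_real_ else x$criterion,
                 J = x$J, tied_pi = isTRUE(x$tied_pi),
                 config = do.call(em_config, as.list(x$config)),
                 seed = x$seed),
            class = "sigclone_fit")
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth A `sigclone_truth` from [simulate_sample()].
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  doc <- list(version = 1L,
              params = list(xi = truth$params$xi, phi = truth$params$phi,
                            pi = truth$params$pi, rho = truth$params$rho,
                            J = truth$params$J),
              purity = truth$purity, active = truth$active,
              clone = truth$clone, signature = truth$signature,
              multiplicity = truth$multiplicity)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(params = sigclone_params(x$params$xi, x$params$phi,
                                          x$params$pi, x$params$rho),
                 purity = x$purity, active = x$active, clone = x$clone,
                 signature = x$signature, multiplicity = x$multiplicity),
            class = "sigclone_truth")
}
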