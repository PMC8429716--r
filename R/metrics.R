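#' Adequacy of the estimated number of clones (score 1B)
#'
#' `(J_true + 1 - min(J_true + 1, |J_pred - J_true|)) / (J_true + 1)`; 1 for a
#' perfect count, decaying linearly to 0.
#'
#' @param J_true,J_pred True and estimated clone counts (>= 1).
#' @return Value in `[0, 1]`.
#' @export
score1b <- function(J_true, J_pred) {
  stopifnot(J_true >= 1, J_pred >= 1)
  (J_true + 1 - pmin(J_true + 1, abs(J_pred - J_true))) / (J_true + 1)
}

# Wasserstein-1 distance between two weighted point-mass distributions on the
# CCF axis, by integrating |F1 - F2| over the merged support
wasserstein1 <- function(x1, w1, x2, w2) {
  w1 <- w1 / sum(w1); w2 <- w2 / sum(w2)
  xs <- sort(unique(c(x1, x2)))
  if (length(xs) == 1) return(0)
  F1 <- vapply(xs, function(x) sum(w1[x1 <= x]), numeric(1))
  F2 <- vapply(xs, function(x) sum(w2[x2 <= x]), numeric(1))
  k <- length(xs)
  sum(abs(F1[-k] - F2[-k]) * diff(xs))
}

#' Wasserstein similarity of the CCF clusterings (score 1C)
#'
#' 1 minus the Wasserstein-1 distance between the true and predicted clone-CCF
#' distributions, each clone weighted by its fraction of mutations.
#'
#' @param ccf_true,ccf_pred Clone CCF locations.
#' @param w_true,w_pred Per-clone mutation fractions (normalized internally).
#' @return Value `<= 1` (1 for identical distributions).
#' @export
score1c <- function(ccf_true, w_true, ccf_pred, w_pred) {
  1 - wasserstein1(ccf_true, w_true, ccf_pred, w_pred)
}

binary_confusion <- function(truth, pred) {
  # doubles: co-clustering matrices make the products overflow integers
  tp <- as.numeric(sum(truth & pred)); tn <- as.numeric(sum(!truth & !pred))
  fp <- as.numeric(sum(!truth & pred)); fn <- as.numeric(sum(truth & !pred))
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

mcc_binary <- function(truth, pred) {
  cf <- binary_confusion(truth, pred)
  den <- sqrt(prod(c(cf["tp"] + cf["fp"], cf["tp"] + cf["fn"],
                     cf["tn"] + cf["fp"], cf["tn"] + cf["fn"])))
  if (den == 0) return(0)
  unname((cf["tp"] * cf["tn"] - cf["fp"] * cf["fn"]) / den)
}

entropy_counts <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log(p))
}

v_measure <- function(labels_true, labels_pred) {
  ct <- table(labels_true, labels_pred)
  N <- sum(ct)
  h_c <- entropy_counts(rowSums(ct))
  h_k <- entropy_counts(colSums(ct))
  # conditional entropies from the contingency table
  h_ck <- 0; h_kc <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    nij <- ct[i, j]
    if (nij == 0) next
    h_ck <- h_ck - nij / N * log(nij / sum(ct[, j]))
    h_kc <- h_kc - nij / N * log(nij / sum(ct[i, ]))
  }
  hom <- if (h_c == 0) 1 else 1 - h_ck / h_c
  com <- if (h_k == 0) 1 else 1 - h_kc / h_k
  if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
}

#' Co-clustering agreement (score 2A)
#'
#' Average of three agreement coefficients between the true and predicted
#' binary co-clustering matrices: Pearson correlation of the vectorized
#' matrices, the Matthews correlation coefficient, and the V-measure of the
#' label partitions. Each coefficient `s` is rescaled to
#' `max(0, (s - s_bad) / (1 - s_bad))` where `s_bad` is the smaller of its
#' scores under two degenerate predictions (all mutations in one cluster; every
#' mutation its own cluster).
#'
#' @param labels_true,labels_pred Integer clone labels per SNV.
#' @param max_n Guard on the number of SNVs (the co-clustering matrices are
#'   N x N); default 20000.
#' @return Value in `[0, 1]`.
#' @export
score2a <- function(labels_true, labels_pred, max_n = 20000) {
  n <- length(labels_true)
  stopifnot(length(labels_pred) == n)
  if (n > max_n) stop("score2a is quadratic in N; subsample below ", max_n, " SNVs")

  co <- function(lab) outer(lab, lab, "==")
  m_true <- co(labels_true)
  raw <- function(m_pred, lab_pred) {
    pear <- if (stats::sd(m_true) == 0 || stats::sd(m_pred) == 0) 0 else
      stats::cor(as.vector(m_true), as.vector(m_pred))
    c(pear = pear,
      mcc = mcc_binary(as.vector(m_true), as.vector(m_pred)),
      vm = v_measure(labels_true, lab_pred))
  }
  s <- raw(co(labels_pred), labels_pred)
  s_one <- raw(matrix(TRUE, n, n), rep(1L, n))
  s_sing <- raw(diag(n) == 1, seq_len(n))
  s_bad <- pmin(s_one, s_sing)
  resc <- ifelse(1 - s_bad <= 0, as.numeric(s >= 1), pmax(0, (s - s_bad) / (1 - s_bad)))
  mean(resc)
}

auc_binary <- function(truth, score) {
  if (length(unique(truth)) < 2) return(NA_real_)
  r <- suppressMessages(pROC::roc(response = truth, predictor = score,
                                  levels = c(FALSE, TRUE), direction = "<",
                                  quiet = TRUE))
  as.numeric(pROC::auc(r))
}

#' Clonal / subclonal classification accuracy (score 2C)
#'
#' A mutation is clonal when it belongs to the clone of maximal CCF (on each
#' side). Reports accuracy, AUC, sensitivity and specificity of the predicted
#' clonal status; the AUC uses the predicted clonal-clone membership
#' probability when supplied, otherwise the hard label.
#'
#' @param labels_true,labels_pred Clone labels per SNV.
#' @param ccf_true,ccf_pred Per-clone CCFs (indexed by label value).
#' @param prob_clonal_pred Optional per-SNV probability of membership in the
#'   predicted clonal clone.
#' @return List with `accuracy`, `auc` (NA when the truth is one-class),
#'   `sensitivity`, `specificity`.
#' @export
score2c <- function(labels_true, ccf_true, labels_pred, ccf_pred,
                    prob_clonal_pred = NULL) {
  clonal_true <- labels_true == which.max(ccf_true)
  clonal_pred <- labels_pred == which.max(ccf_pred)
  score <- if (is.null(prob_clonal_pred)) as.numeric(clonal_pred) else prob_clonal_pred
  cf <- binary_confusion(clonal_true, clonal_pred)
  list(accuracy = unname((cf["tp"] + cf["tn"]) / sum(cf)),
       auc = auc_binary(clonal_true, score),
       sensitivity = unname(if (cf["tp"] + cf["fn"] == 0) NA_real_ else cf["tp"] / (cf["tp"] + cf["fn"])),
       specificity = unname(if (cf["tn"] + cf["fp"] == 0) NA_real_ else cf["tn"] / (cf["tn"] + cf["fp"])))
}

#' Fit of the reconstructed profile to the observed spectrum (score sig 1A)
#'
#' Euclidean distance between the normalized empirical mutation-type counts
#' and the mutation-type profile implied by the estimated sample-level
#' activities (`activities' * mu`).
#'
#' @param type_counts Integer vector of length 96 of observed counts.
#' @param activities Estimated sample-level signature activities (simplex).
#' @param sigs A [signature_matrix()].
#' @return Non-negative distance.
#' @export
score_sig_1a <- function(type_counts, activities, sigs) {
  stopifnot(length(type_counts) == 96)
  emp <- type_counts / sum(type_counts)
  rec <- as.vector(activities %*% sigs)
  sqrt(sum((emp - rec)^2))
}

#' Distance between true and estimated signature profiles (score sig 1B)
#'
#' Euclidean distance between the mutation-type profiles implied by the true
#' and the estimated sample-level activities.
#'
#' @param true_activities,estimated_activities Simplices over L.
#' @param sigs A [signature_matrix()].
#' @return Non-negative distance.
#' @export
score_sig_1b <- function(true_activities, estimated_activities, sigs) {
  d <- (true_activities - estimated_activities) %*% sigs
  sqrt(sum(d^2))
}

#' Which signatures count as present
#'
#' Signatures are ranked by decreasing activity and marked present until the
#' cumulative activity reaches 0.95 (the signature crossing the threshold is
#' included).
#'
#' @param activities Simplex over L.
#' @param threshold Cumulative mass cutoff (default 0.95).
#' @return Logical vector over L.
#' @export
signature_present <- function(activities, threshold = 0.95) {
  o <- order(activities, decreasing = TRUE)
  cum <- cumsum(activities[o])
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(activities)
  out <- logical(length(activities))
  out[o[seq_len(k)]] <- TRUE
  out
}

#' Identification of present signatures (score sig 1C)
#'
#' AUC of the estimated activities as a score for true signature presence,
#' plus threshold metrics from the cumulative-0.95 presence rule.
#'
#' @param true_present Logical vector over L.
#' @param estimated_activities Simplex over L.
#' @return List with `auc` (NA for one-class truth), `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
score_sig_1c <- function(true_present, estimated_activities) {
  est_present <- signature_present(estimated_activities)
  cf <- binary_confusion(true_present, est_present)
  list(auc = auc_binary(true_present, estimated_activities),
       accuracy = unname((cf["tp"] + cf["tn"]) / sum(cf)),
       sensitivity = unname(if (cf["tp"] + cf["fn"] == 0) NA_real_ else cf["tp"] / (cf["tp"] + cf["fn"])),
       specificity = unname(if (cf["tn"] + cf["fp"] == 0) NA_real_ else cf["tn"] / (cf["tn"] + cf["fp"])))
}

#' Per-mutation signature attribution accuracy (score sig 1D)
#'
#' Fraction of SNVs whose maximum-a-posteriori signature equals the signature
#' that generated them.
#'
#' @param true_sig,map_sig Integer signature indices per SNV.
#' @return Value in `[0, 1]`.
#' @export
score_sig_1d <- function(true_sig, map_sig) {
  stopifnot(length(true_sig) == length(map_sig))
  mean(true_sig == map_sig)
}

#' Per-mutation profile reconstruction distance (score sig 1E)
#'
#' For each SNV, the cosine distance between the mutation-type profile of the
#' clone that generated it (true exposures times mu) and the reconstructed
#' profile of its predicted clone. Returns the distribution summary (median is
#' the headline value).
#'
#' @param true_profiles N x 96 matrix of per-SNV true clone profiles.
#' @param pred_profiles N x 96 matrix of per-SNV reconstructed clone profiles.
#' @return List with `median`, `min`, `max`, `std`, `frac_below_0.05`,
#'   `frac_below_0.1`, and the raw `distances`.
#' @export
score_sig_1e <- function(true_profiles, pred_profiles) {
  stopifnot(nrow(true_profiles) == nrow(pred_profiles))
  d <- vapply(seq_len(nrow(true_profiles)), function(n)
    cosine_distance(true_profiles[n, ], pred_profiles[n, ]), numeric(1))
  list(median = stats::median(d), min = min(d), max = max(d),
       std = stats::sd(d), frac_below_0.05 = mean(d < 0.05),
       frac_below_0.1 = mean(d < 0.1), distances = d)
}

#' Score a fit against simulation ground truth
#'
#' Convenience wrapper computing the full metric suite for one sample:
#' subclonal-reconstruction scores (1B, 1C, 2A, 2C) and signature scores
#' (1A-1E).
#'
#' @param sample A [sigclone_sample()].
#' @param fit A `sigclone_fit`.
#' @param truth A `sigclone_truth` from [simulate_sample()].
#' @param sigs The [signature_matrix()] used for the fit.
#' @return A one-row data.frame of scores.
#' @export
evaluate_fit <- function(sample, fit, truth, sigs) {
  p_t <- truth$params
  p_e <- fit$params
  resp <- posterior_responsibilities(sample, p_e, sigs)
  map <- map_assignments(resp)

  w_true <- tabulate(truth$clone, nbins = p_t$J) / length(truth$clone)
  w_pred <- tabulate(map$clone, nbins = p_e$J) / length(map$clone)

  act_true <- as.vector(p_t$xi %*% p_t$pi)
  act_est <- as.vector(p_e$xi %*% p_e$pi)
  counts <- tabulate(sample$snvs$type, nbins = 96)

  s2c <- score2c(truth$clone, p_t$phi, map$clone, p_e$phi,
                 prob_clonal_pred = resp$clone[, which.max(p_e$phi)])
  s1c_sig <- score_sig_1c(signature_present(act_true), act_est)
  s1e <- score_sig_1e((p_t$pi %*% sigs)[truth$clone, , drop = FALSE],
                      (p_e$pi %*% sigs)[map$clone, , drop = FALSE])

  data.frame(
    score1b = score1b(p_t$J, p_e$J),
    score1c = score1c(p_t$phi, w_true, p_e$phi, w_pred),
    score2a = score2a(truth$clone, map$clone),
    score2c_accuracy = s2c$accuracy,
    score2c_auc = s2c$auc,
    score2c_sensitivity = s2c$sensitivity,
    score2c_specificity = s2c$specificity,
    score_sig_1a = score_sig_1a(counts, act_est, sigs),
    score_sig_1b = score_sig_1b(act_true, act_est, sigs),
    score_sig_1c_auc = s1c_sig$auc,
    score_sig_1c_accuracy = s1c_sig$accuracy,
    score_sig_1d = score_sig_1d(truth$signature, map$signature),
    score_sig_1e_median = s1e$median,
    score_sig_1e_frac05 = s1e$frac_below_0.05
  )
}
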