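#' Cohen's kappa for binary presence ratings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' binary vectors (e.g. microbleed presence per subject by two methods).
#' When both raters are constant and identical, kappa is defined as 1; when
#' expected agreement is 1 but the raters disagree, the statistic is
#' undefined and a flagged `NaN` is returned.
#'
#' @param a,b binary (0/1 or logical) vectors of equal length >= 2.
#' @return Kappa in `[-1, 1]` (or flagged `NaN`).
#' @export
cohen_kappa <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must have equal length >= 2")
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  if (abs(1 - pe) < 1e-12) {
    if (po == 1) return(1)
    out <- NaN
    attr(out, "flag") <- "expected agreement 1 with disagreement"
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' Interpret a kappa value
#'
#' Qualitative bands: below 0.2 poor, 0.2-0.4 fair, 0.4-0.6 moderate,
#' 0.6-0.8 good, above 0.8 excellent. Exact cut-points belong to the upper
#' band (0.4 reads "moderate").
#'
#' @param k kappa in `[-1, 1]`.
#' @return One of "poor", "fair", "moderate", "good", "excellent".
#' @export
interpret_kappa <- function(k) {
  stopifnot(is.finite(k), k >= -1, k <= 1)
  cuts <- c(0.2, 0.4, 0.6, 0.8)
  labels <- c("poor", "fair", "moderate", "good", "excellent")
  labels[1 + sum(k >= cuts)]
}

#' Intraclass correlation for lesion counts
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (ICC(2,1)) between two count vectors, computed from the
#' standard mean-squares decomposition of the subject x rater table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param a,b non-negative count vectors of equal length >= 3.
#' @return ICC scalar, or flagged `NaN` when the table has zero total
#'   variance.
#' @export
icc_counts <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3)
    stop("a and b must have equal length >= 3")
  n <- length(a); k <- 2
  X <- cbind(a, b)
  if (stats::var(as.vector(X)) < 1e-24) {
    out <- NaN
    attr(out, "flag") <- "zero total variance"
    return(out)
  }
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Match automated detections to reference lesions
#'
#' Greedy one-to-one nearest-centroid matching under a distance tolerance:
#' repeatedly pairs the globally closest unmatched (detection, reference)
#' pair within `tol_mm`. Returns true/false positive and false negative
#' counts plus the assignment, with `TP + FN = n_reference` and
#' `TP + FP = n_detections`.
#'
#' @param auto a `midas_report`, or an n x 3 matrix of detection centroids
#'   (world mm).
#' @param reference an m x 3 matrix of reference lesion centres (world mm),
#'   or a data frame with columns `x`, `y`, `z`.
#' @param tol_mm maximum centroid distance for a match (default 5).
#' @return List with `TP`, `FP`, `FN` and `matches` (data frame of paired
#'   indices and distances).
#' @export
match_detections <- function(auto, reference, tol_mm = 5) {
  A <- if (inherits(auto, "midas_report"))
    as.matrix(auto$survivors[, c("x", "y", "z")]) else
    matrix(as.numeric(as.matrix(auto)), ncol = 3)
  R <- if (is.data.frame(reference))
    as.matrix(reference[, c("x", "y", "z")]) else
    matrix(as.numeric(as.matrix(reference)), ncol = 3)
  na <- nrow(A); nr <- nrow(R)
  matches <- data.frame(auto = integer(0), reference = integer(0),
                        dist_mm = numeric(0))
  if (na > 0 && nr > 0) {
    D <- outer(seq_len(na), seq_len(nr), function(i, j)
      sqrt((A[i, 1] - R[j, 1])^2 + (A[i, 2] - R[j, 2])^2 +
             (A[i, 3] - R[j, 3])^2))
    D <- matrix(D, na, nr)
    repeat {
      m <- which.min(D)
      if (!length(m) || D[m] > tol_mm || !is.finite(D[m])) break
      i <- (m - 1) %% na + 1; j <- (m - 1) %/% na + 1
      matches <- rbind(matches, data.frame(auto = i, reference = j,
                                           dist_mm = D[m]))
      D[i, ] <- Inf; D[, j] <- Inf
    }
  }
  tp <- nrow(matches)
  list(TP = tp, FP = na - tp, FN = nr - tp, matches = matches)
}

#' Presence/count agreement summary between two rating tables
#'
#' Convenience wrapper computing the three patient-level agreement
#' statistics used for method-versus-reference comparison: presence kappa
#' per region class, count ICC per region class, and the kappa for the
#' multiple-lobar dichotomy (two or more lobar lesions).
#'
#' @param auto,manual data frames with columns `subject`, `lobar`, `deep`,
#'   `infratentorial` (counts per region).
#' @return Data frame of statistics with interpretation bands where
#'   applicable.
#' @export
agreement_summary <- function(auto, manual) {
  m <- merge(auto, manual, by = "subject", suffixes = c(".auto", ".man"))
  if (nrow(m) < 3) stop("need at least 3 common subjects")
  rows <- list()
  for (reg in c("lobar", "deep", "infratentorial")) {
    ca <- m[[paste0(reg, ".auto")]]; cm <- m[[paste0(reg, ".man")]]
    kap <- cohen_kappa(ca > 0, cm > 0)
    rows[[length(rows) + 1]] <- data.frame(
      region = reg, statistic = "presence_kappa", value = as.numeric(kap),
      band = if (is.finite(kap)) interpret_kappa(kap) else NA_character_)
    rows[[length(rows) + 1]] <- data.frame(
      region = reg, statistic = "count_icc",
      value = as.numeric(icc_counts(ca, cm)), band = NA_character_)
  }
  kap2 <- cohen_kappa(m$lobar.auto >= 2, m$lobar.man >= 2)
  rows[[length(rows) + 1]] <- data.frame(
    region = "lobar", statistic = "multi_cmb_kappa",
    value = as.numeric(kap2),
    band = if (is.finite(kap2)) interpret_kappa(kap2) else NA_character_)
  do.call(rbind, rows)
}
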