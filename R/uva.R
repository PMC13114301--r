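#' Univariate feature screen
#'
#' Spearman rank correlation of every feature with the binary toxicity
#' label (mid-rank ties, asymptotic two-sided p), plus each feature's
#' standalone AUC.  The AUC is orientation-corrected to `max(a, 1 - a)` so
#' a predictor that works in the protective direction (negative rho) still
#' reports its discriminative value above 0.5.  Significance is flagged at
#' p < 0.05 and a trend at p < 0.1; a Benjamini-Hochberg q-value column is
#' reported for transparency but takes no part in the flags.
#'
#' @param X feature matrix (patients x features).
#' @param y binary labels (0/1), both classes present.
#' @return data.frame with one row per feature: `feature`, `rho`,
#'   `p_value`, `auc`, `significant`, `trend`, `bh_q`, `constant`.
#' @export
uva_screen <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 3L) stop("univariate screen needs at least 3 patients")
  if (length(unique(y)) != 2L) stop("both classes must be present")
  p <- ncol(X)
  rho <- pv <- auc <- rep(NA_real_, p)
  const <- logical(p)
  for (j in seq_len(p)) {
    x <- X[, j]
    if (max(x) == min(x)) { const[j] <- TRUE; next }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    rho[j] <- unname(ct$estimate)
    pv[j] <- ct$p.value
    a <- rank_auc(x, y)
    auc[j] <- max(a, 1 - a)
  }
  data.frame(feature = colnames(X) %||% sprintf("F%03d", seq_len(p)),
             rho = rho, p_value = pv, auc = auc,
             significant = !is.na(pv) & pv < 0.05,
             trend = !is.na(pv) & pv >= 0.05 & pv < 0.1,
             bh_q = stats::p.adjust(pv, method = "BH"),
             constant = const,
             row.names = NULL)
}

#' Standalone AUC of one feature
#'
#' Rank (Mann-Whitney) AUC of the raw feature values against the labels,
#' orientation-corrected to `max(a, 1 - a)`.
#'
#' @param x feature values.
#' @param y binary labels (0/1).
#' @return scalar AUC in [0.5, 1].
#' @export
feature_auc <- function(x, y) {
  a <- rank_auc(x, as.integer(y))
  max(a, 1 - a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
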