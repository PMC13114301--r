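#' Shuffle-and-split validation scheme
#'
#' Repeated stratified random train/test partitions; model performance is
#' the mean test AUC over the repeats.
#'
#' @param n_repeats number of random splits (the reference analysis uses
#'   1000; desk-scale runs use fewer).
#' @param test_fraction fraction of the cohort held out per split.
#' @param stratified keep the class ratio in both halves.
#' @param seed master seed for split generation.
#' @return object of class `split_scheme`.
#' @export
split_scheme <- function(n_repeats = 1000, test_fraction = 0.2,
                         stratified = TRUE, seed = 1) {
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_scheme")
}

# Pre-draw test-index sets for every repeat.  Stratified sampling keeps at
# least one member of each class on both sides of every split.
make_splits <- function(y, scheme) {
  n <- length(y)
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  if (length(i1) < 2L || length(i0) < 2L)
    stop("both classes need at least 2 members for stratified splitting")
  k1 <- max(1L, min(length(i1) - 1L, round(length(i1) * scheme$test_fraction)))
  k0 <- max(1L, min(length(i0) - 1L, round(length(i0) * scheme$test_fraction)))
  old <- .Random.seed_save()
  set.seed(scheme$seed)
  sp <- lapply(seq_len(scheme$n_repeats), function(r) {
    if (scheme$stratified) c(sample(i1, k1), sample(i0, k0))
    else {
      k <- max(2L, round(n * scheme$test_fraction))
      repeat {
        te <- sample.int(n, k)
        if (length(unique(y[te])) == 2L && length(unique(y[-te])) == 2L) break
      }
      te
    }
  })
  .Random.seed_restore(old)
  sp
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Rank (Mann-Whitney) AUC of scores for the positive class; mid-ranks
# handle ties.
rank_auc <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Decision scores oriented so that larger = more likely class "1",
# regardless of libsvm's internal level order.
svm_scores <- function(fit, newx) {
  dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
             "decision.values")
  s <- dv[, 1]
  if (!startsWith(colnames(dv)[1], "1")) s <- -s
  s
}

#' Mean shuffle-and-split AUC of an RBF SVM on a feature subset
#'
#' For every repeat, fits an RBF-kernel SVM on the training part and
#' scores the held-out part with the decision function; reports the mean
#' test AUC, the vertically averaged ROC on a fixed FPR grid, and mean
#' accuracy / sensitivity / specificity at the decision-boundary
#' threshold 0.
#'
#' @param X numeric feature matrix (patients x features), already scaled.
#' @param y binary labels (0/1).
#' @param subset column names or indices to use (default all).
#' @param hyper named vector `c(C =, gamma =)`.
#' @param scheme a [split_scheme()].
#' @param splits optional pre-drawn test-index list (for reuse across
#'   candidate subsets, common-random-numbers style).
#' @param roc if `TRUE`, also return the mean ROC curve.
#' @return list with `mean_auc`, `per_split_auc`, `accuracy`,
#'   `sensitivity`, `specificity`, and optionally `roc` (data.frame
#'   `fpr`, `tpr`).
#' @export
shuffle_split_auc <- function(X, y, subset = NULL,
                              hyper = c(C = 1, gamma = NA),
                              scheme = split_scheme(200), splits = NULL,
                              roc = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (is.null(subset)) subset <- seq_len(ncol(X))
  if (is.character(subset)) subset <- match(subset, colnames(X))
  if (length(subset) == 0L) stop("feature subset must be non-empty")
  Xs <- X[, subset, drop = FALSE]
  if (is.na(hyper[["gamma"]])) hyper[["gamma"]] <- 1 / ncol(Xs)
  if (is.null(splits)) splits <- make_splits(y, scheme)
  yf <- factor(y, levels = c(0L, 1L))
  fgrid <- seq(0, 1, by = 0.01)
  aucs <- numeric(length(splits))
  acc <- sens <- spec <- numeric(length(splits))
  tpr_sum <- numeric(length(fgrid))
  for (r in seq_along(splits)) {
    te <- splits[[r]]
    fit <- e1071::svm(Xs[-te, , drop = FALSE], yf[-te], kernel = "radial",
                      cost = max(hyper[["C"]], 1e-3),
                      gamma = hyper[["gamma"]], scale = FALSE)
    s <- svm_scores(fit, Xs[te, , drop = FALSE])
    yt <- y[te]
    aucs[r] <- rank_auc(s, yt)
    pred <- as.integer(s > 0)
    acc[r] <- mean(pred == yt)
    sens[r] <- mean(pred[yt == 1L] == 1L)
    spec[r] <- mean(pred[yt == 0L] == 0L)
    if (roc) tpr_sum <- tpr_sum + roc_at_fpr(s, yt, fgrid)
  }
  out <- list(mean_auc = mean(aucs), per_split_auc = aucs,
              accuracy = mean(acc), sensitivity = mean(sens),
              specificity = mean(spec))
  if (roc) out$roc <- data.frame(fpr = fgrid, tpr = tpr_sum / length(splits))
  out
}

# TPR of the score-threshold ROC at fixed FPR nodes (vertical averaging
# convention: step interpolation, best TPR attainable at each FPR).
roc_at_fpr <- function(scores, y, fgrid) {
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  tpr <- cumsum(ys == 1L) / n1
  fpr <- cumsum(ys == 0L) / n0
  vapply(fgrid, function(f) {
    ok <- fpr <= f + 1e-12
    if (!any(ok)) 0 else max(tpr[ok])
  }, numeric(1))
}

#' Sequential backward feature selection wrapped around a shuffle-split SVM
#'
#' The outer loop removes, at each iteration, the feature whose exclusion
#' yields the highest inner-loop mean AUC (ties break to the lowest column
#' index), until the retained count reaches the one-in-ten stop level
#' (`floor(n/10)` by default).  Splits are redrawn per iteration from the
#' scheme seed and shared across the candidate subsets of that iteration.
#' The returned fit carries the selection trace and a final performance
#' evaluation (optionally at a higher repeat count than the selection).
#'
#' @param X scaled feature matrix (patients x features).
#' @param y binary labels (0/1).
#' @param scheme a [split_scheme()] used for the candidate evaluations.
#' @param stop_level retained-feature target; default `floor(n/10)`.
#' @param hyper SVM hyperparameters `c(C =, gamma =)`; `gamma = NA` means
#'   1/p.  Tuned once before selection when `tune = TRUE`.
#' @param tune run [pso_tune()] on the full feature set first.
#' @param final_scheme scheme for the final performance evaluation
#'   (default: the selection scheme).
#' @param trace_progress print one line per iteration.
#' @return object of class `sbs_svm`.
#' @export
sbs_select <- function(X, y, scheme = split_scheme(200),
                       stop_level = NULL, hyper = c(C = 1, gamma = NA),
                       tune = FALSE, final_scheme = scheme,
                       trace_progress = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (is.null(stop_level)) stop_level <- floor(n / 10)
  if (stop_level < 1L) stop("one-in-ten stop level below 1; cohort too small")
  if (ncol(X) <= stop_level)
    stop("starting feature count must exceed the stop level")
  if (is.null(colnames(X))) colnames(X) <- sprintf("F%03d", seq_len(ncol(X)))
  if (tune) hyper <- pso_tune(X, y, scheme = scheme)
  if (is.na(hyper[["gamma"]])) hyper[["gamma"]] <- 1 / ncol(X)

  remaining <- seq_len(ncol(X))
  trace <- data.frame(iteration = integer(0), removed = character(0),
                      mean_auc = numeric(0))
  it <- 0L
  while (length(remaining) > stop_level) {
    it <- it + 1L
    isch <- scheme
    isch$seed <- scheme$seed + it
    splits <- make_splits(y, isch)
    cand_auc <- vapply(seq_along(remaining), function(k) {
      shuffle_split_auc(X, y, subset = remaining[-k], hyper = hyper,
                        scheme = isch, splits = splits)$mean_auc
    }, numeric(1))
    drop_k <- which.max(cand_auc)   # first max = lowest column index
    if (trace_progress)
      message(sprintf("SBS iter %d: drop %s (mean AUC %.3f), %d left",
                      it, colnames(X)[remaining[drop_k]], cand_auc[drop_k],
                      length(remaining) - 1L))
    trace <- rbind(trace, data.frame(
      iteration = it, removed = colnames(X)[remaining[drop_k]],
      mean_auc = cand_auc[drop_k]))
    remaining <- remaining[-drop_k]
  }
  perf <- shuffle_split_auc(X, y, subset = remaining, hyper = hyper,
                            scheme = final_scheme, roc = TRUE)
  yf <- factor(y, levels = c(0L, 1L))
  full_fit <- e1071::svm(X[, remaining, drop = FALSE], yf, kernel = "radial",
                         cost = max(hyper[["C"]], 1e-3),
                         gamma = hyper[["gamma"]], scale = FALSE)
  structure(list(selected = colnames(X)[remaining],
                 selected_idx = remaining,
                 trace = trace,
                 mean_auc = perf$mean_auc,
                 accuracy = perf$accuracy,
                 sensitivity = perf$sensitivity,
                 specificity = perf$specificity,
                 roc = perf$roc,
                 hyper = hyper,
                 scheme = scheme,
                 final_scheme = final_scheme,
                 stop_level = stop_level,
                 n = n,
                 svm_fit = full_fit,
                 feature_names = colnames(X)),
            class = "sbs_svm")
}

#' @export
print.sbs_svm <- function(x, ...) {
  cat(sprintf("SBS-selected RBF-SVM: %d of %d features retained (n = %d, stop = %d)\n",
              length(x$selected), length(x$feature_names), x$n, x$stop_level))
  cat(sprintf("  mean AUC %.3f | accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$mean_auc, x$accuracy, x$sensitivity, x$specificity))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sbs_svm <- function(object, ...) {
  cat(sprintf("Sequential backward selection, %d iterations\n",
              nrow(object$trace)))
  print(utils::tail(object$trace, 10))
  cat(sprintf("\nFinal model on %d features (C = %.3g, gamma = %.3g):\n",
              length(object$selected), object$hyper[["C"]],
              object$hyper[["gamma"]]))
  print.sbs_svm(object)
  invisible(object)
}

#' @export
predict.sbs_svm <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$selected, drop = FALSE]
  s <- svm_scores(object$svm_fit, newdata)
  if (type == "score") s else as.integer(s > 0)
}

#' @export
plot.sbs_svm <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2, col = "steelblue",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Mean ROC (AUC = %.2f)", x$mean_auc), ...)
  graphics::abline(0, 1, lty = 2, col = "red")
  invisible(x)
}

#' Feature importance by removal
#'
#' Refits the selected model without each retained feature in turn and
#' reports the resulting mean shuffle-split AUC; rows are ranked ascending
#' by that AUC, i.e. descending importance (the larger the AUC drop on
#' removal, the more important the feature).
#'
#' @param fit an `sbs_svm` object.
#' @param X,y the feature matrix and labels the fit was made on.
#' @param scheme evaluation scheme (default: the fit's final scheme).
#' @return data.frame `feature`, `mean_auc_without`, ranked by importance.
#' @export
importance_by_removal <- function(fit, X, y, scheme = fit$final_scheme) {
  stopifnot(inherits(fit, "sbs_svm"))
  sel <- fit$selected
  if (length(sel) == 1L) {
    return(data.frame(feature = sel, mean_auc_without = NA_real_))
  }
  splits <- make_splits(as.integer(y), scheme)
  auc_wo <- vapply(seq_along(sel), function(k) {
    shuffle_split_auc(X, y, subset = setdiff(sel, sel[k]),
                      hyper = fit$hyper, scheme = scheme,
                      splits = splits)$mean_auc
  }, numeric(1))
  out <- data.frame(feature = sel, mean_auc_without = auc_wo)
  out[order(out$mean_auc_without), , drop = FALSE]
}

#' Particle-swarm search for SVM hyperparameters
#'
#' Global-best PSO over the (C, gamma) box, maximizing mean shuffle-split
#' AUC.  C is searched linearly in [0, 100] (evaluated at a small positive
#' floor), gamma on a log10 scale over [1e-5, 100].
#'
#' @param X,y scaled features and binary labels.
#' @param subset feature subset to tune on (default all).
#' @param scheme a [split_scheme()] for the objective.
#' @param bounds list with `C` and `gamma` ranges.
#' @param n_particles,n_iter swarm size and iteration count.
#' @param seed RNG seed for the swarm.
#' @return named vector `c(C =, gamma =)`.
#' @export
pso_tune <- function(X, y, subset = colnames(as.matrix(X)),
                     scheme = split_scheme(25),
                     bounds = list(C = c(0, 100), gamma = c(1e-5, 100)),
                     n_particles = 8, n_iter = 6, seed = scheme$seed) {
  X <- as.matrix(X)
  splits <- make_splits(as.integer(y), scheme)
  obj <- function(C, g) {
    shuffle_split_auc(X, y, subset = subset,
                      hyper = c(C = max(C, 1e-3), gamma = g),
                      scheme = scheme, splits = splits)$mean_auc
  }
  lg <- log10(bounds$gamma)
  old <- .Random.seed_save()
  set.seed(seed)
  pos <- cbind(stats::runif(n_particles, bounds$C[1], bounds$C[2]),
               stats::runif(n_particles, lg[1], lg[2]))
  vel <- cbind(stats::runif(n_particles, -diff(bounds$C), diff(bounds$C)) * 0.1,
               stats::runif(n_particles, -diff(lg), diff(lg)) * 0.1)
  pbest <- pos
  pval <- apply(pos, 1L, function(p) obj(p[1], 10^p[2]))
  g_idx <- which.max(pval)
  gbest <- pos[g_idx, ]; gval <- pval[g_idx]
  w <- 0.72; c1 <- 1.49; c2 <- 1.49
  for (t in seq_len(n_iter)) {
    r1 <- matrix(stats::runif(n_particles * 2), n_particles)
    r2 <- matrix(stats::runif(n_particles * 2), n_particles)
    vel <- w * vel + c1 * r1 * (pbest - pos) +
      c2 * r2 * matrix(gbest, n_particles, 2, byrow = TRUE) - c2 * r2 * pos
    pos <- pos + vel
    pos[, 1] <- pmin(pmax(pos[, 1], bounds$C[1]), bounds$C[2])
    pos[, 2] <- pmin(pmax(pos[, 2], lg[1]), lg[2])
    val <- apply(pos, 1L, function(p) obj(p[1], 10^p[2]))
    imp <- val > pval
    pbest[imp, ] <- pos[imp, ]; pval[imp] <- val[imp]
    if (max(pval) > gval) {
      g_idx <- which.max(pval)
      gbest <- pbest[g_idx, ]; gval <- pval[g_idx]
    }
  }
  .Random.seed_restore(old)
  c(C = gbest[1], gamma = 10^gbest[2])
}
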