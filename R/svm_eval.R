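#' Configuration for SVM training and cross-validation
#'
#' @param C,gamma Optional fixed RBF-SVM hyperparameters. When either is
#'   `NULL`, [cross_validate()] and [incremental_feature_selection()] run a
#'   grid search first.
#' @param C_grid,gamma_grid Candidate grids for the search. Defaults are the
#'   canonical libsvm-guide exponential grids, C in 2^(-5), 2^(-3), ..., 2^15
#'   and gamma in 2^(-15), 2^(-13), ..., 2^3.
#' @param folds Number of cross-validation folds k (>= 2).
#' @param seed Integer seed controlling the stratified fold assignment.
#' @return An `svm_config` list.
#' @export
svm_config <- function(C = NULL, gamma = NULL,
                       C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       folds = 5L, seed = 1L) {
  stopifnot(length(C_grid) >= 1L, length(gamma_grid) >= 1L,
            all(C_grid > 0), all(gamma_grid > 0), folds >= 2L)
  if (!is.null(C)) stopifnot(C > 0)
  if (!is.null(gamma)) stopifnot(gamma > 0)
  structure(list(C = C, gamma = gamma, C_grid = sort(C_grid),
                 gamma_grid = sort(gamma_grid),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "svm_config")
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class independently under the given seed and deals samples
#' to folds round-robin, so every fold's positive fraction is within one
#' sample of the global fraction. Deterministic given (labels, k, seed).
#'
#' @param labels Factor of class labels.
#' @param k Number of folds; must not exceed the smaller class size.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(labels, k, seed) {
  k <- as.integer(k)
  counts <- table(labels)
  if (any(counts < k) || length(counts) < 2L)
    stop("cannot build ", k, " stratified folds: class sizes are ",
         paste(counts, collapse = ", "),
         " (need both classes with at least k samples)", call. = FALSE)
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Classification metrics report
#'
#' Bundles the confusion counts and the three derived rates used throughout:
#' sensitivity Sn = n+/N+, specificity Sp = n-/N-, and overall accuracy
#' OA = (n+ + n-)/(N+ + N-), where n+ and n- are the correctly identified
#' positives and negatives, N+ and N- the class totals.
#'
#' @param n_pos_correct,n_neg_correct Correctly classified positives and
#'   negatives.
#' @param N_pos,N_neg Total positives and negatives.
#' @return A `metrics_report` list with fields `n_pos_correct`,
#'   `n_neg_correct`, `N_pos`, `N_neg`, `Sn`, `Sp`, `OA`.
#' @export
metrics_report <- function(n_pos_correct, n_neg_correct, N_pos, N_neg) {
  stopifnot(n_pos_correct >= 0, n_pos_correct <= N_pos,
            n_neg_correct >= 0, n_neg_correct <= N_neg,
            N_pos >= 1, N_neg >= 1)
  structure(list(n_pos_correct = as.integer(n_pos_correct),
                 n_neg_correct = as.integer(n_neg_correct),
                 N_pos = as.integer(N_pos), N_neg = as.integer(N_neg),
                 Sn = n_pos_correct / N_pos,
                 Sp = n_neg_correct / N_neg,
                 OA = (n_pos_correct + n_neg_correct) / (N_pos + N_neg)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn = %.4f (%d/%d)  Sp = %.4f (%d/%d)  OA = %.4f\n",
              x$Sn, x$n_pos_correct, x$N_pos,
              x$Sp, x$n_neg_correct, x$N_neg, x$OA))
  invisible(x)
}

#' Train an RBF-kernel SVM on a feature matrix
#'
#' Thin wrapper around [e1071::svm()] (libsvm) with `kernel = "radial"` and
#' no additional feature scaling: compositions already live in \[0, 1\].
#' The trained model remembers the gap size, normalization convention and
#' feature subset it was built with and refuses inputs that do not match.
#'
#' @param fm A labelled `feature_matrix`.
#' @param C,gamma RBF-SVM hyperparameters.
#' @param features Optional feature subset: integer indices or dipeptide
#'   names. Default uses all 400 features.
#' @return A `ggap_svm_model`.
#' @export
train_svm <- function(fm, C, gamma, features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), C > 0, gamma > 0)
  check_two_classes(fm, min_per_class = 1L)
  feats <- resolve_features(fm, features)
  fit <- e1071::svm(fm$x[, feats, drop = FALSE], fm$labels,
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, features = feats, g = fm$g,
                 denominator = fm$denominator, C = C, gamma = gamma),
            class = "ggap_svm_model")
}

resolve_features <- function(fm, features) {
  if (is.null(features)) return(colnames(fm$x))
  if (is.numeric(features)) {
    stopifnot(all(features >= 1), all(features <= ncol(fm$x)))
    return(colnames(fm$x)[as.integer(features)])
  }
  missing <- setdiff(features, colnames(fm$x))
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  features
}

#' Predict classes for new sequences or feature rows
#'
#' @param object A `ggap_svm_model`.
#' @param newdata A `feature_matrix` built with the same gap size and
#'   normalization, or a numeric matrix whose columns cover the model's
#'   feature subset.
#' @param decision_values Also return libsvm decision values.
#' @param ... Unused.
#' @return Factor of predicted labels; with `decision_values = TRUE`, the
#'   decision values are attached as attribute `"decision_values"`.
#' @export
predict.ggap_svm_model <- function(object, newdata, decision_values = FALSE,
                                   ...) {
  if (inherits(newdata, "feature_matrix")) {
    if (newdata$g != object$g || newdata$denominator != object$denominator)
      stop("feature matrix was built with g = ", newdata$g, " / ",
           newdata$denominator, " but the model expects g = ", object$g,
           " / ", object$denominator, call. = FALSE)
    newdata <- newdata$x
  }
  if (!is.matrix(newdata))
    stop("`newdata` must be a feature_matrix or numeric matrix", call. = FALSE)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$features))
      stop("model expects ", length(object$features),
           " feature(s) but input has ", ncol(newdata), call. = FALSE)
  } else {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing))
      stop("input is missing ", length(missing), " model feature(s), e.g. ",
           missing[1L], call. = FALSE)
    if (ncol(newdata) != length(object$features))
      stop("model expects exactly ", length(object$features),
           " feature(s) but input has ", ncol(newdata),
           "; subset columns to the model's feature set", call. = FALSE)
    newdata <- newdata[, object$features, drop = FALSE]
  }
  pred <- stats::predict(object$fit, newdata, decision.values = decision_values)
  names(pred) <- NULL
  if (decision_values) {
    dv <- as.numeric(attr(pred, "decision.values"))
    attr(pred, "decision.values") <- NULL
    attr(pred, "names") <- NULL
    attr(pred, "decision_values") <- dv
  }
  pred
}

# Cross-validate with a fixed fold assignment; pooled confusion counts.
cv_with_folds <- function(fm, folds, C, gamma, features = NULL) {
  feats <- resolve_features(fm, features)
  x <- fm$x[, feats, drop = FALSE]
  y <- fm$labels
  pred <- factor(rep(NA_character_, length(y)),
                 levels = c("negative", "positive"))
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (length(unique(y[!test])) < 2L)
      stop("fold ", f, " leaves a training set with a single class",
           call. = FALSE)
    fit <- e1071::svm(x[!test, , drop = FALSE], y[!test], kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    pred[test] <- stats::predict(fit, x[test, , drop = FALSE])
  }
  metrics_report(n_pos_correct = sum(pred == "positive" & y == "positive"),
                 n_neg_correct = sum(pred == "negative" & y == "negative"),
                 N_pos = sum(y == "positive"), N_neg = sum(y == "negative"))
}

#' Grid search for the RBF-SVM hyperparameters
#'
#' Evaluates every (C, gamma) grid point by stratified k-fold
#' cross-validated overall accuracy and returns the maximizer. Ties are
#' broken toward smaller C, then smaller gamma. Deterministic given the
#' config seed (folds are fixed once for the whole search).
#'
#' @param fm A labelled `feature_matrix`.
#' @param config An [svm_config()].
#' @param features Optional feature subset.
#' @param folds Optional precomputed fold assignment (advanced use; defaults
#'   to [make_folds()] under the config seed).
#' @return List with `C`, `gamma`, `OA`, and the full `grid` data frame.
#' @export
grid_search_svm <- function(fm, config = svm_config(), features = NULL,
                            folds = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "svm_config"))
  check_two_classes(fm)
  if (is.null(folds)) folds <- make_folds(fm$labels, config$folds, config$seed)
  grid <- expand.grid(gamma = config$gamma_grid, C = config$C_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  grid <- grid[order(grid$C, grid$gamma), ]
  grid$OA <- vapply(seq_len(nrow(grid)), function(i) {
    cv_with_folds(fm, folds, grid$C[i], grid$gamma[i], features)$OA
  }, numeric(1L))
  best <- which.max(grid$OA)  # first max: smallest C, then smallest gamma
  list(C = grid$C[best], gamma = grid$gamma[best], OA = grid$OA[best],
       grid = grid)
}

#' Stratified k-fold cross-validation of the RBF-SVM
#'
#' Each sample is predicted exactly once, by a model trained without it;
#' confusion counts are pooled over folds before Sn, Sp and OA are computed.
#' When `config$C` or `config$gamma` is `NULL`, a grid search
#' ([grid_search_svm()]) with the same folds picks them first.
#'
#' @inheritParams grid_search_svm
#' @return A `metrics_report`; the hyperparameters used are attached as
#'   attributes `C` and `gamma`.
#' @export
cross_validate <- function(fm, config = svm_config(), features = NULL,
                           folds = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "svm_config"))
  check_two_classes(fm)
  if (is.null(folds)) folds <- make_folds(fm$labels, config$folds, config$seed)
  C <- config$C; gamma <- config$gamma
  if (is.null(C) || is.null(gamma)) {
    best <- grid_search_svm(fm, config, features, folds = folds)
    C <- best$C; gamma <- best$gamma
  }
  rep <- cv_with_folds(fm, folds, C, gamma, features)
  attr(rep, "C") <- C
  attr(rep, "gamma") <- gamma
  rep
}

#' Jackknife (leave-one-out) cross-validation
#'
#' Every sample is predicted by a model trained on all remaining samples.
#' There is no fold randomness, so the report is fully determined by the
#' data and hyperparameters -- two runs are identical regardless of seed.
#'
#' @inheritParams grid_search_svm
#' @return A `metrics_report`.
#' @export
jackknife <- function(fm, config = svm_config(), features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "svm_config"))
  check_two_classes(fm, min_per_class = 2L)
  C <- config$C; gamma <- config$gamma
  if (is.null(C) || is.null(gamma)) {
    best <- grid_search_svm(fm, config, features)
    C <- best$C; gamma <- best$gamma
  }
  folds <- seq_len(nrow(fm$x))  # one sample per fold
  rep <- cv_with_folds(fm, folds, C, gamma, features)
  attr(rep, "C") <- C
  attr(rep, "gamma") <- gamma
  rep
}
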