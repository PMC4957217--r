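#' Incremental feature selection over an F-score ranking
#'
#' Walks the ranked feature list from the top: evaluates the cross-validated
#' overall accuracy of the RBF-SVM on the top-1 feature, then top-2, and so
#' on until all D features (D = 400 for g-gap dipeptide composition) have
#' been used, producing one OA per subset size. The optimal subset is the
#' smallest prefix attaining the maximal OA.
#'
#' The fold assignment is fixed once per (labels, folds, seed) and reused
#' for all D evaluations, so the curve reflects feature-set changes only,
#' not fold-resampling noise.
#'
#' Hyperparameter handling (`hyper`):
#' \describe{
#'   \item{`"global"` (default)}{one grid search on the full feature set
#'     (skipped when `config$C` and `config$gamma` are set), and the chosen
#'     (C, gamma) are reused at every subset size. Keeps the curve a clean
#'     function of the feature subset and costs one search total.}
#'   \item{`"per_step"`}{re-runs a coarse grid search (every other point of
#'     the config grids) at each of the D subset sizes. Roughly 16x slower
#'     at the default grids.}
#' }
#'
#' @param fm A labelled `feature_matrix`.
#' @param ranking Permutation of `1:ncol(fm$x)` (or of the dipeptide names),
#'   most informative feature first, e.g. from [rank_features()].
#' @param config An [svm_config()].
#' @param hyper `"global"` or `"per_step"`, see above.
#' @return An `ifs_curve`: list with `g`, `points` (data frame `size`, `OA`,
#'   `Sn`, `Sp`), `best_size`, `best_OA`, `ranking` (feature names in rank
#'   order), `C`, `gamma` (those used; per-step mode stores per-size values
#'   in `points`).
#' @export
incremental_feature_selection <- function(fm, ranking, config = svm_config(),
                                          hyper = c("global", "per_step")) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "svm_config"))
  hyper <- match.arg(hyper)
  check_two_classes(fm)
  D <- ncol(fm$x)
  if (is.character(ranking)) ranking <- match(ranking, colnames(fm$x))
  if (length(ranking) != D || anyNA(ranking) ||
      !setequal(ranking, seq_len(D)))
    stop("`ranking` must be a permutation of all ", D, " feature indices",
         call. = FALSE)
  folds <- make_folds(fm$labels, config$folds, config$seed)
  ranked_names <- colnames(fm$x)[ranking]

  C <- config$C; gamma <- config$gamma
  if (hyper == "global" && (is.null(C) || is.null(gamma))) {
    best <- grid_search_svm(fm, config, folds = folds)
    C <- best$C; gamma <- best$gamma
  }
  coarse <- svm_config(C_grid = every_other(config$C_grid),
                       gamma_grid = every_other(config$gamma_grid),
                       folds = config$folds, seed = config$seed)

  pts <- vector("list", D)
  for (d in seq_len(D)) {
    feats <- ranked_names[seq_len(d)]
    rep <- tryCatch({
      if (hyper == "per_step") {
        best <- grid_search_svm(fm, coarse, features = feats, folds = folds)
        C <- best$C; gamma <- best$gamma
      }
      cv_with_folds(fm, folds, C, gamma, feats)
    }, error = function(e) {
      stop("IFS failed at subset size ", d, ": ", conditionMessage(e),
           call. = FALSE)
    })
    pts[[d]] <- data.frame(size = d, OA = rep$OA, Sn = rep$Sn, Sp = rep$Sp,
                           C = C, gamma = gamma)
  }
  points <- do.call(rbind, pts)
  best_size <- which.max(points$OA)  # first max = smallest size
  structure(list(g = fm$g, points = points,
                 best_size = as.integer(best_size),
                 best_OA = points$OA[best_size],
                 ranking = ranked_names,
                 C = if (hyper == "global") C else NULL,
                 gamma = if (hyper == "global") gamma else NULL,
                 hyper = hyper, folds = config$folds, seed = config$seed),
            class = "ifs_curve")
}

every_other <- function(x) x[seq(1L, length(x), by = 2L)]

#' @export
print.ifs_curve <- function(x, ...) {
  cat("ifs_curve (g = ", x$g, "): ", nrow(x$points),
      " subset sizes; best OA = ", sprintf("%.4f", x$best_OA),
      " at size ", x$best_size, "\n", sep = "")
  invisible(x)
}

#' Select the optimal feature subset from an IFS curve
#'
#' @param curve An `ifs_curve`.
#' @return List with `best_size` (smallest subset size attaining the
#'   maximal OA), `best_OA`, and `features` (the dipeptide names of that
#'   prefix, in rank order).
#' @export
select_optimal_subset <- function(curve) {
  if (!inherits(curve, "ifs_curve") || nrow(curve$points) == 0L)
    stop("`curve` must be a non-empty ifs_curve", call. = FALSE)
  list(best_size = curve$best_size, best_OA = curve$best_OA,
       features = curve$ranking[seq_len(curve$best_size)])
}

#' Sweep the gap size g: rank, IFS-optimize and compare per g
#'
#' For each g in `g_values`, builds the feature matrix, ranks features by
#' F-score and runs [incremental_feature_selection()], then reports the
#' globally best (g, subset size, OA). Sequences shorter than g + 2 are
#' dropped for that g with a warning; a g whose filtered set loses a whole
#' class is skipped with a warning.
#'
#' @param records A `protein_records` data frame.
#' @param labels Class labels, one per record.
#' @param g_values Integer vector of gaps to try (default 0:9).
#' @param config An [svm_config()].
#' @param denominator Composition normalization, see
#'   [ggap_dipeptide_composition()].
#' @param hyper Passed to [incremental_feature_selection()].
#' @return An `ifs_sweep`: list with `curves` (one `ifs_curve` per retained
#'   g, named `"g0"`, `"g1"`, ...) and `best` (list `g`, `size`, `OA`,
#'   `features`).
#' @export
sweep_g <- function(records, labels, g_values = 0:9, config = svm_config(),
                    denominator = c("positions", "length"),
                    hyper = c("global", "per_step")) {
  denominator <- match.arg(denominator)
  hyper <- match.arg(hyper)
  stopifnot(length(g_values) >= 1L)
  labels <- normalize_labels(labels, nrow(records))
  curves <- list()
  for (g in g_values) {
    keep <- nchar(records$sequence) >= g + 2L
    if (sum(!keep) > 0L)
      warning("g = ", g, ": dropped ", sum(!keep),
              " sequence(s) shorter than g + 2", call. = FALSE)
    lab_g <- droplevels(labels[keep])
    if (sum(keep) == 0L || nlevels(lab_g) < 2L ||
        min(table(lab_g)) < config$folds) {
      warning("g = ", g, ": skipped (not enough samples per class left)",
              call. = FALSE)
      next
    }
    fm <- build_feature_matrix(records[keep, , drop = FALSE], labels[keep],
                               g = g, denominator = denominator)
    tbl <- fscore_table(fm)
    curves[[paste0("g", g)]] <-
      incremental_feature_selection(fm, rank_features(tbl), config, hyper)
  }
  if (length(curves) == 0L)
    stop("no gap size in g_values = {", paste(g_values, collapse = ", "),
         "} left a usable dataset", call. = FALSE)
  best_oas <- vapply(curves, `[[`, numeric(1L), "best_OA")
  b <- which.max(best_oas)  # ties: first (smallest) g wins
  opt <- select_optimal_subset(curves[[b]])
  structure(list(curves = curves,
                 best = list(g = curves[[b]]$g, size = opt$best_size,
                             OA = opt$best_OA, features = opt$features)),
            class = "ifs_sweep")
}

#' @export
print.ifs_sweep <- function(x, ...) {
  cat("ifs_sweep over", length(x$curves), "gap size(s)\n")
  for (cv in x$curves)
    cat(sprintf("  g = %d: best OA %.4f at %d features\n",
                cv$g, cv$best_OA, cv$best_size))
  cat(sprintf("global optimum: g = %d, %d features, OA %.4f\n",
              x$best$g, x$best$size, x$best$OA))
  invisible(x)
}

#' Export an IFS curve as TSV (columns size, OA, Sn, Sp)
#'
#' @param curve An `ifs_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  utils::write.table(curve$points[, c("size", "OA", "Sn", "Sp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sweep summary (global optimum) as JSON
#'
#' @param sweep An `ifs_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_summary <- function(sweep, path) {
  stopifnot(inherits(sweep, "ifs_sweep"))
  per_g <- lapply(sweep$curves, function(cv)
    list(g = cv$g, best_size = cv$best_size, best_OA = cv$best_OA))
  names(per_g) <- NULL
  jsonlite::write_json(list(best = sweep$best, curves = per_g), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot IFS curves (subset size vs overall accuracy), one line per g
#'
#' @param x An `ifs_sweep` or a single `ifs_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of OA values plotted.
#' @export
plot_ifs <- function(x, ...) {
  curves <- if (inherits(x, "ifs_curve")) list(x) else x$curves
  oa <- sapply(curves, function(cv) cv$points$OA)
  graphics::matplot(seq_len(nrow(oa)), oa, type = "l", lty = 1,
                    xlab = "number of top-ranked features",
                    ylab = "cross-validated overall accuracy", ...)
  graphics::legend("bottomright",
                   legend = paste0("g = ", vapply(curves, `[[`, numeric(1L), "g")),
                   col = seq_along(curves), lty = 1, cex = 0.8)
  invisible(oa)
}
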