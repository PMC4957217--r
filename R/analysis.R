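#' Residue preference matrix (signed normalized F-scores as 20 x 20)
#'
#' Reshapes the 400 signed normalized F-scores of an [fscore_table()] into
#' a 20 x 20 matrix: rows are the first residue of the pair, columns the
#' second, both in alphabetical order. Cell (a, b) is +1-ish when pair
#' (a, b) is strongly enriched in the positive class and -1-ish when
#' enriched in the negative class; this is the numeric form of the usual
#' dipeptide-preference heat map.
#'
#' @param tbl An `fscore_table` with all 400 rows.
#' @return A `preference_matrix`: 20 x 20 numeric matrix with residue
#'   dimnames and the gap size in attribute `g`.
#' @export
preference_matrix <- function(tbl) {
  if (!inherits(tbl, "fscore_table") || nrow(tbl) != 400L ||
      !"signed_norm" %in% names(tbl))
    stop("`tbl` must be a complete 400-row fscore_table with signed_norm",
         call. = FALSE)
  if (!identical(tbl$dipeptide, dipeptide_names()))
    stop("fscore_table rows are not in canonical feature order", call. = FALSE)
  m <- matrix(tbl$signed_norm, nrow = 20L, ncol = 20L, byrow = TRUE,
              dimnames = list(first = AA_ALPHABET, second = AA_ALPHABET))
  structure(m, g = attr(tbl, "g"), class = c("preference_matrix", "matrix"))
}

#' Per-residue enrichment summary from a preference matrix
#'
#' Scores each residue by the mean signed score over the 40 cells in which
#' it participates (its row, as first pair member, plus its column, as
#' second member; the diagonal cell counts in both roles). Positive scores
#' mark residues whose g-gap pairings are on balance enriched in the
#' positive class.
#'
#' @param pm A `preference_matrix`.
#' @return Data frame (`residue`, `score`) sorted by descending score.
#' @export
residue_enrichment_summary <- function(pm) {
  stopifnot(inherits(pm, "preference_matrix"))
  score <- vapply(seq_len(20L),
                  function(i) mean(c(pm[i, ], pm[, i])), numeric(1L))
  out <- data.frame(residue = AA_ALPHABET, score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$residue), , drop = FALSE]
}

#' Evaluate the model restricted to the k top-ranked features
#'
#' Cross-validates the RBF-SVM using only the k features with the highest
#' F-scores. With the same config (folds, seed, and explicit C and gamma)
#' this reproduces the IFS curve's point at size k.
#'
#' @param fm A labelled `feature_matrix`.
#' @param tbl The `fscore_table` for `fm`.
#' @param k Number of top features, 1..400.
#' @param config An [svm_config()].
#' @return A `metrics_report`.
#' @export
top_k_model <- function(fm, tbl, k, config = svm_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > nrow(tbl))
    stop("`k` must be in 1..", nrow(tbl), call. = FALSE)
  feats <- tbl$dipeptide[rank_features(tbl)][seq_len(as.integer(k))]
  cross_validate(fm, config, features = feats)
}

#' Export a preference matrix as TSV (21 x 21 with residue headers)
#'
#' Values are written with 6 significant digits (`%.6g`); writing the
#' matrix read back from such a file reproduces the file byte-for-byte.
#'
#' @param pm A `preference_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preference_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "preference_matrix"))
  lines <- c(paste(c("", AA_ALPHABET), collapse = "\t"),
             vapply(seq_len(20L), function(i) {
               paste(c(AA_ALPHABET[i], sprintf("%.6g", pm[i, ])),
                     collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a preference matrix written by [write_preference_matrix()]
#'
#' @param path Path to the TSV file.
#' @param g Gap size to attach (not stored in the TSV).
#' @return A `preference_matrix`.
#' @export
read_preference_matrix <- function(path, g = NULL) {
  tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  stopifnot(identical(rownames(tab), AA_ALPHABET),
            identical(colnames(tab), AA_ALPHABET))
  m <- as.matrix(tab)
  dimnames(m) <- list(first = AA_ALPHABET, second = AA_ALPHABET)
  structure(m, g = g, class = c("preference_matrix", "matrix"))
}

#' Plot a preference matrix as a heat map
#'
#' Base-graphics image with a symmetric diverging palette; by default the
#' positive-class-enriched cells are drawn in red and negative in blue.
#'
#' @param x A `preference_matrix`.
#' @param flip_colors Swap the two ends of the palette.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot_preference_matrix <- function(x, flip_colors = FALSE, ...) {
  stopifnot(inherits(x, "preference_matrix"))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101L)
  if (flip_colors) pal <- rev(pal)
  # image() draws rows along x; transpose + reverse rows to get matrix layout
  z <- t(x[20L:1L, ])
  graphics::image(x = 1:20, y = 1:20, z = z, zlim = c(-1, 1), col = pal,
                  axes = FALSE, xlab = "second residue", ylab = "first residue",
                  ...)
  graphics::axis(1L, at = 1:20, labels = AA_ALPHABET, cex.axis = 0.7)
  graphics::axis(2L, at = 1:20, labels = rev(AA_ALPHABET), cex.axis = 0.7,
                 las = 1L)
  invisible(x)
}
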