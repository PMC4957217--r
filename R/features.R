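#' Count g-gap dipeptides in a protein sequence
#'
#' A g-gap dipeptide is an ordered residue pair at positions (i, i + g + 1),
#' i.e. separated by g intervening residues; g = 0 gives the classical
#' adjoining dipeptides. A sequence of length L contributes L - g - 1 such
#' pairs, so the returned counts always sum to L - g - 1.
#'
#' @param sequence Protein sequence (validated and upper-cased internally).
#' @param g Non-negative integer gap size. Values above 9 are allowed with a
#'   warning; long gaps leave few observable pairs per protein.
#' @param id Optional record id for error messages.
#' @return Named integer vector of length 400 (names from
#'   [dipeptide_names()]).
#' @examples
#' counts <- ggap_dipeptide_counts("ACACA", g = 1)
#' counts[counts > 0]
#' @export
ggap_dipeptide_counts <- function(sequence, g, id = NULL) {
  g <- check_gap(g)
  seq <- validate_sequence(sequence, id = id)
  L <- nchar(seq)
  if (L < g + 2L)
    stop(err_prefix(id), "sequence length ", L,
         " is too short for gap g = ", g, " (need L >= ", g + 2L, ")",
         call. = FALSE)
  chars <- match(strsplit(seq, "", fixed = TRUE)[[1L]], AA_ALPHABET)
  first <- chars[seq_len(L - g - 1L)]
  second <- chars[(g + 2L):L]
  counts <- tabulate((first - 1L) * 20L + second, nbins = 400L)
  names(counts) <- dipeptide_names()
  counts
}

check_gap <- function(g) {
  if (length(g) != 1L || is.na(g) || g < 0 || g != as.integer(g))
    stop("`g` must be a single non-negative integer", call. = FALSE)
  g <- as.integer(g)
  if (g > 9L)
    warning("g = ", g, " is above the usual sweep range 0..9; ",
            "few pairs per sequence will be observable", call. = FALSE)
  g
}

#' g-gap dipeptide composition of a protein sequence
#'
#' The 400-dimensional frequency vector of ordered residue pairs at gap g.
#' With the default `denominator = "positions"` each count is divided by
#' L - g - 1, the number of g-gap dipeptides the sequence actually contains,
#' so the composition is a probability distribution (sums to 1). The
#' alternative `denominator = "length"` divides by L instead, a literal
#' sequence-length normalization some descriptor definitions use; the two
#' differ by the constant factor (L - g - 1)/L per sequence.
#'
#' @inheritParams ggap_dipeptide_counts
#' @param denominator `"positions"` (default, sums to 1) or `"length"`.
#' @return Named numeric vector of length 400.
#' @examples
#' v <- ggap_dipeptide_composition("ACACA", g = 1)
#' sum(v)  # 1
#' @export
ggap_dipeptide_composition <- function(sequence, g,
                                       denominator = c("positions", "length"),
                                       id = NULL) {
  denominator <- match.arg(denominator)
  counts <- ggap_dipeptide_counts(sequence, g, id = id)
  L <- nchar(sequence)
  denom <- if (denominator == "positions") L - as.integer(g) - 1L else L
  counts / denom
}

#' Build a labelled g-gap dipeptide feature matrix
#'
#' One row per sequence (input order preserved), 400 columns of g-gap
#' dipeptide frequencies, plus class labels. This is the container every
#' downstream stage (F-score ranking, SVM evaluation, incremental feature
#' selection) operates on.
#'
#' @param records A `protein_records` data frame from [read_fasta()] (or any
#'   data frame with `id` and `sequence` columns).
#' @param labels Class labels, one per record: a factor/character vector
#'   with values in \{positive, negative\} or numeric/logical with 1/TRUE =
#'   positive. Required for training; may be `NULL` for prediction-only
#'   matrices.
#' @param g Gap size.
#' @param denominator Passed to [ggap_dipeptide_composition()].
#' @return A `feature_matrix` object: list with `x` (n x 400 numeric matrix,
#'   rownames = ids), `labels` (factor, levels negative/positive, or NULL),
#'   `g`, `denominator`.
#' @export
build_feature_matrix <- function(records, labels, g,
                                 denominator = c("positions", "length")) {
  denominator <- match.arg(denominator)
  g <- check_gap(g)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L)
    stop("no records supplied to build_feature_matrix()", call. = FALSE)
  labels <- normalize_labels(labels, nrow(records))
  L <- nchar(records$sequence)
  short <- L < g + 2L
  if (any(short))
    stop("sequence(s) too short for gap g = ", g, " (need L >= ", g + 2L,
         "): ", paste(records$id[short], collapse = ", "), call. = FALSE)
  x <- t(vapply(seq_len(nrow(records)), function(i) {
    ggap_dipeptide_composition(records$sequence[i], g,
                               denominator = denominator,
                               id = records$id[i])
  }, numeric(400L)))
  rownames(x) <- records$id
  colnames(x) <- dipeptide_names()
  structure(list(x = x, labels = labels, g = g, denominator = denominator),
            class = "feature_matrix")
}

normalize_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  if (length(labels) != n)
    stop("got ", length(labels), " labels for ", n, " records", call. = FALSE)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0 (negative) or 1 (positive)", call. = FALSE)
    labels <- ifelse(labels == 1, "positive", "negative")
  }
  labels <- tolower(as.character(labels))
  map <- c(positive = "positive", pos = "positive", "1" = "positive",
           negative = "negative", neg = "negative", "0" = "negative")
  if (!all(labels %in% names(map)))
    stop("labels must be in {positive, negative} (or 1/0)", call. = FALSE)
  factor(unname(map[labels]), levels = c("negative", "positive"))
}

n_pos <- function(fm) sum(fm$labels == "positive")
n_neg <- function(fm) sum(fm$labels == "negative")

check_two_classes <- function(fm, min_per_class = 1L) {
  if (is.null(fm$labels))
    stop("feature matrix has no labels", call. = FALSE)
  mp <- n_pos(fm); mn <- n_neg(fm)
  if (mp < min_per_class || mn < min_per_class)
    stop("need at least ", min_per_class, " sample(s) per class; have ",
         mp, " positive and ", mn, " negative", call. = FALSE)
  invisible(fm)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$x), " x ", ncol(x$x),
      " (g = ", x$g, ", denominator = ", x$denominator, ")\n", sep = "")
  if (!is.null(x$labels))
    cat("labels: ", n_pos(x), " positive, ", n_neg(x), " negative\n", sep = "")
  invisible(x)
}

#' Export a feature matrix as TSV
#'
#' Header row carries the 400 dipeptide names with the gap embedded (e.g.
#' `AA.g3`); the label column, when present, comes last.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$x)
  names(df) <- dipeptide_names(g = fm$g)
  df <- cbind(id = rownames(fm$x), df)
  if (!is.null(fm$labels)) df$label <- as.character(fm$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
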