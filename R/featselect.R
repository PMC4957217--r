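#' Two-group ANOVA F-score of every feature
#'
#' For each of the 400 dipeptide frequencies, the ratio of the between-group
#' mean square to the within-group mean square of a one-way ANOVA with two
#' groups (positive and negative samples):
#' \deqn{F(x) = \frac{[m_p(\bar x_p - \bar x)^2 + m_n(\bar x_n - \bar x)^2]/(K-1)}
#'                  {[\sum_{i \in pos}(x_i-\bar x_p)^2 + \sum_{i \in neg}(x_i-\bar x_n)^2]/(m_p+m_n-K)}, \quad K = 2.}
#' A large F means the feature's class means are far apart relative to the
#' spread within classes. Degenerate cases: a feature constant within each
#' class but different between classes separates the classes perfectly and
#' is scored `Inf`; a feature with zero between-group variance (including
#' one constant across all samples) scores 0.
#'
#' @param fm A labelled `feature_matrix` with at least 2 samples per class.
#' @return Named numeric vector of length 400 (non-negative, possibly `Inf`).
#' @export
fscore <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_two_classes(fm, min_per_class = 2L)
  pos <- fm$x[fm$labels == "positive", , drop = FALSE]
  neg <- fm$x[fm$labels == "negative", , drop = FALSE]
  mp <- nrow(pos); mn <- nrow(neg)
  xp <- colMeans(pos); xn <- colMeans(neg)
  xb <- (mp * xp + mn * xn) / (mp + mn)
  ssb <- mp * (xp - xb)^2 + mn * (xn - xb)^2          # K - 1 = 1
  ssw <- colSums(sweep(pos, 2L, xp)^2) + colSums(sweep(neg, 2L, xn)^2)
  msw <- ssw / (mp + mn - 2L)
  f <- ifelse(ssb == 0, 0, ifelse(msw == 0, Inf, ssb / msw))
  names(f) <- colnames(fm$x)
  f
}

#' F-score table: raw F, signed normalized score, and rank per feature
#'
#' Builds the full per-feature table: class means, raw ANOVA F-score
#' ([fscore()]), the signed min-max normalized score
#' ([signed_normalized_fscore()]), and the 1-based rank after sorting by
#' descending F. Ties are broken deterministically: equal finite F by
#' ascending dipeptide name; perfectly separating (infinite-F) features rank
#' above all finite ones, among themselves by descending absolute class-mean
#' difference, then name.
#'
#' @param fm A labelled `feature_matrix`.
#' @return An `fscore_table` data frame (400 rows, in feature-index order)
#'   with columns `dipeptide`, `F`, `mean_pos`, `mean_neg`, `mean_all`,
#'   `signed_norm`, `rank`; the gap size is kept in attribute `g`.
#' @export
fscore_table <- function(fm) {
  f <- fscore(fm)
  pos <- fm$x[fm$labels == "positive", , drop = FALSE]
  neg <- fm$x[fm$labels == "negative", , drop = FALSE]
  mp <- nrow(pos); mn <- nrow(neg)
  xp <- colMeans(pos); xn <- colMeans(neg)
  tbl <- data.frame(dipeptide = names(f), F = unname(f),
                    mean_pos = unname(xp), mean_neg = unname(xn),
                    mean_all = unname((mp * xp + mn * xn) / (mp + mn)),
                    stringsAsFactors = FALSE)
  tbl$signed_norm <- signed_normalized_fscore(tbl)
  ord <- feature_order(tbl)
  tbl$rank <- integer(nrow(tbl))
  tbl$rank[ord] <- seq_len(nrow(tbl))
  attr(tbl, "g") <- fm$g
  class(tbl) <- c("fscore_table", "data.frame")
  tbl
}

#' Signed min-max normalized F-scores
#'
#' Scales each raw F-score to \[0, 1\] by min-max normalization over the 400
#' finite F values and attaches the enrichment direction as a sign:
#' \deqn{F_{norm}(x) = \mathrm{sgn}(\bar p^+ - \bar p^-) \cdot \frac{F(x) - F_{min}}{F_{max} - F_{min}}}
#' so +1 marks the strongest positively-enriched feature and -1 the
#' strongest negatively-enriched one. Perfectly separating features
#' (infinite F) map to +/-1 and the finite features are scaled against the
#' finite maximum, preserving the \[-1, 1\] range.
#'
#' @param tbl A data frame with columns `F`, `mean_pos`, `mean_neg`
#'   (typically built inside [fscore_table()]).
#' @return Numeric vector in \[-1, 1\], one value per row.
#' @export
signed_normalized_fscore <- function(tbl) {
  stopifnot(all(c("F", "mean_pos", "mean_neg") %in% names(tbl)))
  f <- tbl$F
  fin <- is.finite(f)
  sg <- sign(tbl$mean_pos - tbl$mean_neg)
  if (!any(fin)) return(sg)  # every feature separates perfectly
  fmin <- min(f[fin]); fmax <- max(f[fin])
  if (fmax == fmin) {
    if (!any(!fin))
      stop("all 400 F-scores are identical; scores cannot be normalized ",
           "(check the input for signal, e.g. with a synthetic spike-in)",
           call. = FALSE)
    norm <- rep(0, length(f))  # finite rows carry no contrast
  } else {
    norm <- (f - fmin) / (fmax - fmin)
  }
  norm[!fin] <- 1
  sg * norm
}

# Deterministic ordering: descending F (Inf first), infinite ties by
# descending |mean_pos - mean_neg|, then ascending dipeptide name.
feature_order <- function(tbl) {
  sep_gap <- ifelse(is.infinite(tbl$F), abs(tbl$mean_pos - tbl$mean_neg), 0)
  order(-tbl$F, -sep_gap, tbl$dipeptide)
}

#' Rank features by descending F-score
#'
#' @param tbl An `fscore_table` (or any data frame with `F`, `mean_pos`,
#'   `mean_neg`, `dipeptide`).
#' @return Integer vector: a permutation of `1:nrow(tbl)`; the first element
#'   is the index of the top-ranked feature.
#' @export
rank_features <- function(tbl) {
  stopifnot(all(c("F", "dipeptide") %in% names(tbl)))
  feature_order(tbl)
}

#' Two-sided ANOVA p-values from an F-score table
#'
#' Under the no-signal null, each feature's F-score follows an
#' F(1, m_p + m_n - 2) distribution; this converts raw scores to upper-tail
#' p-values. Used mainly for type-I-error calibration of the pipeline.
#'
#' @param f Numeric vector of raw F-scores.
#' @param n_samples Total sample count m_p + m_n.
#' @return Numeric vector of p-values.
#' @export
fscore_pvalues <- function(f, n_samples) {
  stats::pf(f, df1 = 1, df2 = n_samples - 2, lower.tail = FALSE)
}

#' Export an F-score table as TSV
#'
#' @param tbl An `fscore_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fscore_table <- function(tbl, path) {
  out <- tbl[, c("dipeptide", "F", "signed_norm", "rank",
                 "mean_pos", "mean_neg")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
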