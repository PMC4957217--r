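# Independent oracles and small fixture builders shared across tests.

# Brute-force g-gap pair counter: tests every (pair, position) combination.
# O(L * 400); deliberately naive and independent of the package's tabulate().
brute_force_ggap_counts <- function(sequence, g) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  counts <- setNames(integer(400L), dipeptide_names())
  for (a in AA_ALPHABET) for (b in AA_ALPHABET) {
    pair <- paste0(a, b)
    for (i in seq_len(L - g - 1L)) {
      if (chars[i] == a && chars[i + g + 1L] == b)
        counts[pair] <- counts[pair] + 1L
    }
  }
  counts
}

# Same contract as brute_force_ggap_counts but with the position test
# vectorized per pair, so it stays usable at L = 500; still O(L * 400) and
# independent of the package's index-arithmetic + tabulate() route.
pairwise_scan_counts <- function(sequence, g) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  counts <- setNames(integer(400L), dipeptide_names())
  idx <- seq_len(L - g - 1L)
  for (a in AA_ALPHABET) for (b in AA_ALPHABET) {
    counts[paste0(a, b)] <- sum(chars[idx] == a & chars[idx + g + 1L] == b)
  }
  counts
}

# Classical one-way ANOVA F for one feature, via base R's linear-model
# ANOVA table (independent of the package's vectorized sum-of-squares).
anova_oracle_f <- function(pos_values, neg_values) {
  y <- c(pos_values, neg_values)
  grp <- factor(rep(c("p", "n"), c(length(pos_values), length(neg_values))))
  stats::anova(stats::lm(y ~ grp))[["F value"]][1L]
}

random_protein <- function(L) paste(sample(AA_ALPHABET, L, replace = TRUE),
                                    collapse = "")

# Tiny labelled dataset with a deterministic, strongly separable signal:
# positives are A/C-rich at gap g, negatives D/E-rich.
separable_dataset <- function(n_per_class = 10L, L = 60L, seed = 101L) {
  withr::with_seed(seed, {
    pos <- replicate(n_per_class, paste(
      sample(c("A", "C"), L, replace = TRUE), collapse = ""))
    neg <- replicate(n_per_class, paste(
      sample(c("D", "E"), L, replace = TRUE), collapse = ""))
  })
  list(records = data.frame(id = c(paste0("p", seq_len(n_per_class)),
                                   paste0("n", seq_len(n_per_class))),
                            sequence = c(pos, neg),
                            stringsAsFactors = FALSE),
       labels = rep(c("positive", "negative"), each = n_per_class))
}

# Feature matrix with given rows injected as exact feature values
# (bypasses sequences; for featselect unit tests on controlled numbers).
matrix_fixture <- function(x, labels, g = 6L) {
  colnames(x) <- dipeptide_names()
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  structure(list(x = x,
                 labels = factor(labels, levels = c("negative", "positive")),
                 g = g, denominator = "positions"),
            class = "feature_matrix")
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
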