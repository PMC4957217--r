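#' Default planted dipeptide pairs
#'
#' Twenty ordered residue pairs used as the default planted signal: ten
#' built from the hydrophobic residues L, F, I and W, enriched in the
#' positive class, and ten from C, E, K and P, enriched in the negative
#' class -- the residue groups that dominate the two directions of the
#' apolipoprotein preference map that motivated this toolkit.
#'
#' @return Data frame with columns `first`, `second`, `class`
#'   (`"positive"`/`"negative"`).
#' @export
default_planted_pairs <- function() {
  pos <- c("LL", "LF", "FI", "IW", "WL", "FL", "IL", "WF", "LI", "FW")
  neg <- c("CC", "CE", "EK", "KP", "PC", "EC", "KC", "PE", "CK", "EP")
  data.frame(first = substr(c(pos, neg), 1L, 1L),
             second = substr(c(pos, neg), 2L, 2L),
             class = rep(c("positive", "negative"), each = 10L),
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic two-class protein dataset
#'
#' Describes a dataset of random background sequences with g-gap dipeptide
#' signal planted at a single known gap, so that feature extraction,
#' ranking, selection and classification can all be validated against a
#' known ground truth.
#'
#' Defaults mirror the scale of a small curated two-class protein
#' benchmark: 53 positives vs 136 negatives, lengths uniform on
#' \[100, 500\], uniform residue background, signal at gap 6.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Integer pair (min, max); lengths drawn uniformly.
#' @param g_star Gap at which the signal is planted.
#' @param planted_pairs Data frame (`first`, `second`, `class`) of distinct
#'   ordered residue pairs and the class each is enriched in; default
#'   [default_planted_pairs()].
#' @param effect Per-position injection probability in \[0, 1): for each
#'   planted pair enriched in class c, each valid position of a class-c
#'   sequence is overwritten with that pair with this probability.
#'   `effect = 0` gives an exchangeable null. The per-class sum of effects
#'   must stay below 1.
#' @param background Length-20 residue probability vector in the order of
#'   [AA_ALPHABET]; `NULL` (default) = uniform.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_pos = 53L, n_neg = 136L, length_range = c(100L, 500L),
                       g_star = 6L, planted_pairs = default_planted_pairs(),
                       effect = 0.02, background = NULL, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L])
  g_star <- check_gap(g_star)
  if (length_range[1L] < g_star + 2L)
    stop("minimum length ", length_range[1L], " is below g_star + 2 = ",
         g_star + 2L, call. = FALSE)
  stopifnot(is.data.frame(planted_pairs),
            all(c("first", "second", "class") %in% names(planted_pairs)))
  if (nrow(planted_pairs)) {
    stopifnot(all(planted_pairs$first %in% AA_ALPHABET),
              all(planted_pairs$second %in% AA_ALPHABET),
              all(planted_pairs$class %in% c("positive", "negative")))
    key <- paste0(planted_pairs$first, planted_pairs$second)
    if (anyDuplicated(key))
      stop("planted_pairs must be distinct ordered pairs", call. = FALSE)
  }
  if (effect < 0 || effect >= 1)
    stop("`effect` must be in [0, 1)", call. = FALSE)
  per_class <- table(factor(planted_pairs$class,
                            levels = c("positive", "negative")))
  if (any(per_class * effect > 1))
    stop("infeasible effect: ", effect, " x ", max(per_class),
         " same-class pairs implies total planted frequency > 1",
         call. = FALSE)
  if (!is.null(background)) {
    stopifnot(length(background) == 20L, all(background >= 0),
              sum(background) > 0)
    background <- background / sum(background)
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 g_star = g_star, planted_pairs = planted_pairs,
                 effect = effect, background = background,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic two-class protein dataset
#'
#' Sequences are i.i.d. draws from the background residue distribution.
#' Then, for every planted pair (a, b) enriched in class c, each position
#' i in 1..L-g*-1 of every class-c sequence is independently overwritten
#' with residue a at i and b at i + g* + 1, with probability `effect`
#' (later pairs overwrite earlier ones at overlapping positions). The
#' signal therefore lives at gap g* by construction; other gaps see it only
#' through the induced shift in single-residue usage.
#'
#' @param spec A [synth_spec()].
#' @return List with `records` (a `protein_records` data frame; ids
#'   `pos_1..n_pos` then `neg_1..n_neg`), `labels` (factor), and `truth`
#'   (the planted pairs, `g_star`, `effect`, `seed`).
#' @examples
#' d <- generate_dataset(synth_spec(n_pos = 5, n_neg = 5, seed = 42))
#' d$records$id
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  bg <- spec$background
  n <- spec$n_pos + spec$n_neg
  labels <- factor(rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)),
                   levels = c("negative", "positive"))
  ids <- c(paste0("pos_", seq_len(spec$n_pos)),
           paste0("neg_", seq_len(spec$n_neg)))
  gap1 <- spec$g_star + 1L
  seqs <- withr::with_seed(spec$seed, {
    vapply(seq_len(n), function(i) {
      # sample.int avoids sample()'s scalar expansion when min == max
      L <- spec$length_range[1L] +
        sample.int(spec$length_range[2L] - spec$length_range[1L] + 1L, 1L) - 1L
      chars <- sample(AA_ALPHABET, L, replace = TRUE, prob = bg)
      if (spec$effect > 0 && nrow(spec$planted_pairs)) {
        mine <- spec$planted_pairs[spec$planted_pairs$class ==
                                     as.character(labels[i]), , drop = FALSE]
        for (p in seq_len(nrow(mine))) {
          hit <- which(stats::runif(L - gap1) < spec$effect)
          if (length(hit)) {
            chars[hit] <- mine$first[p]
            chars[hit + gap1] <- mine$second[p]
          }
        }
      }
      paste(chars, collapse = "")
    }, character(1L))
  })
  list(records = new_protein_records(ids, seqs), labels = labels,
       truth = list(planted_pairs = spec$planted_pairs, g_star = spec$g_star,
                    effect = spec$effect, seed = spec$seed))
}

#' Write a generated dataset to FASTA files plus a truth JSON
#'
#' Produces `positive.fasta`, `negative.fasta` and `truth.json` under
#' `dir`. Byte-identical for identical specs (seed included).
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pos <- dataset$labels == "positive"
  write_fasta(dataset$records[pos, , drop = FALSE],
              file.path(dir, "positive.fasta"))
  write_fasta(dataset$records[!pos, , drop = FALSE],
              file.path(dir, "negative.fasta"))
  truth <- dataset$truth
  truth$planted_pairs <- paste0(truth$planted_pairs$first,
                                truth$planted_pairs$second, ":",
                                truth$planted_pairs$class)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
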