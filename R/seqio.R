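#' Validate a protein sequence against the 20-letter alphabet
#'
#' Upper-cases the input and checks every character against the standard
#' amino-acid alphabet. Ambiguity codes (B, J, O, U, X, Z), stop characters
#' (`*`) and gaps (`-`) are all rejected: a dipeptide composition is
#' undefined for them.
#'
#' @param sequence Single character string.
#' @param id Optional record identifier used in error messages.
#' @return The validated, upper-cased sequence.
#' @examples
#' validate_sequence("mklv")
#' @export
validate_sequence <- function(sequence, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single string", call. = FALSE)
  seq <- toupper(sequence)
  if (nchar(seq) == 0L)
    stop(err_prefix(id), "sequence is empty", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop(err_prefix(id), "illegal character '", chars[bad[1L]],
         "' at position ", bad[1L],
         if (length(bad) > 1L) paste0(" (and ", length(bad) - 1L, " more)"),
         call. = FALSE)
  }
  seq
}

err_prefix <- function(id) if (is.null(id)) "" else paste0("record '", id, "': ")

new_protein_records <- function(id, sequence) {
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Parses FASTA (multi-line sequences, CRLF tolerated) via
#' [Biostrings::readAAStringSet()], upper-cases, and validates every record
#' against the 20-letter amino-acid alphabet. Records carrying characters
#' outside the alphabet -- e.g. the ambiguity codes B, J, O, U, X, Z -- are
#' handled according to `policy`.
#'
#' @param path Path to a FASTA file.
#' @param policy How to treat sequences with illegal characters:
#'   `"reject"` (default) errors on the first offending record, `"skip"`
#'   drops offending records with a message, `"strip"` removes the illegal
#'   characters with a message.
#' @return A `protein_records` data frame with columns `id`, `sequence`,
#'   `length`, in file order.
#' @export
read_fasta <- function(path, policy = c("reject", "skip", "strip")) {
  policy <- match.arg(policy)
  if (!file.exists(path))
    stop("cannot read FASTA file: '", path, "' does not exist", call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("failed to parse FASTA file '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("no sequences found in FASTA file '", path, "'", call. = FALSE)
  # headers: first whitespace-delimited token is the id
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1L), 1L)
  if (any(!nzchar(ids)))
    stop("empty FASTA header in '", path, "'", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ids in '", path, "': ", paste(dup, collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  ok <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs)
  ok <- ok & nchar(seqs) > 0L
  if (policy == "reject" && any(!ok)) {
    first <- which(!ok)[1L]
    validate_sequence(seqs[first], id = ids[first])  # raises with position
  }
  if (policy == "skip" && any(!ok)) {
    message("read_fasta: skipped ", sum(!ok),
            " record(s) with illegal characters")
    ids <- ids[ok]; seqs <- seqs[ok]
  }
  if (policy == "strip") {
    n_bad <- sum(!ok)
    seqs <- gsub(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), "", seqs)
    keep <- nchar(seqs) > 0L
    if (n_bad > 0L)
      message("read_fasta: stripped illegal characters from ", n_bad,
              " record(s)", if (any(!keep)) paste0("; dropped ", sum(!keep),
                                                   " emptied record(s)"))
    ids <- ids[keep]; seqs <- seqs[keep]
  }
  if (length(ids) == 0L)
    stop("no valid records left in '", path, "' after applying policy '",
         policy, "'", call. = FALSE)
  new_protein_records(ids, seqs)
}

#' Write protein records to a FASTA file
#'
#' @param records A `protein_records` data frame (or any data frame with
#'   `id` and `sequence` columns).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read class labels from a two-column TSV
#'
#' Expects columns `id` and `label` (header optional), with labels in
#' \{1, 0\} or \{"positive", "negative"\}. Used to attach labels to a single
#' FASTA file; the alternative is two FASTA files, one per class.
#'
#' @param path Path to the TSV file.
#' @return Named factor (levels `negative`, `positive`) indexed by id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path))
    stop("cannot read label file: '", path, "' does not exist", call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("label file '", path, "' must have two columns (id, label)",
         call. = FALSE)
  if (tolower(tab[1L, 1L]) == "id") tab <- tab[-1L, , drop = FALSE]
  lab <- tolower(tab[[2L]])
  lev <- ifelse(lab %in% c("1", "positive", "pos"), "positive",
                ifelse(lab %in% c("0", "negative", "neg"), "negative", NA))
  if (anyNA(lev))
    stop("label file '", path, "' has labels outside {1,0,positive,negative}",
         call. = FALSE)
  out <- factor(lev, levels = c("negative", "positive"))
  names(out) <- tab[[1L]]
  out
}

#' @export
print.protein_records <- function(x, ...) {
  cat("protein_records: ", nrow(x), " sequence(s), lengths ",
      min(x$length), "-", max(x$length), "\n", sep = "")
  print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more)\n", sep = "")
  invisible(x)
}
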