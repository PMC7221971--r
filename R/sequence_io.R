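# FASTA and pair-list input, prediction and feature-matrix output.

#' Read a protein FASTA file
#'
#' Parses a (multi-line) FASTA file into a named character vector of
#' validated amino-acid sequences. Sequences are upper-cased and the residue
#' policy of [clean_sequence()] is applied. Identifiers are the first
#' whitespace-delimited token of each header; duplicates are an error, as is
#' a sequence that is empty after cleaning.
#'
#' @param path Path to a FASTA file.
#' @param policy Residue policy, see [clean_sequence()].
#' @return Named character vector: names are protein ids, values sequences.
#' @seealso [write_fasta()], [read_pairs()]
#' @export
read_fasta <- function(path, policy = c("drop", "error", "zero")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- as.character(set)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    out[i] <- clean_sequence(seqs[i], policy = policy, id = ids[i])
    if (!nzchar(out[i])) stop("sequence '", ids[i], "' is empty after cleaning")
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' Deterministic writer (60-column wrap) so that identical inputs produce
#' byte-identical files.
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(proteins)) {
    seq <- proteins[[id]]
    body <- gsub("(.{60})", "\\1\n", seq)
    if (!endsWith(body, "\n")) body <- paste0(body, "\n")
    writeChar(paste0(">", id, "\n", body), con, eos = NULL)
  }
  invisible(path)
}

# Detect the field separator of a delimited text file (tab or comma).
.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a protein-pair list
#'
#' Reads a tab- or comma-delimited file (auto-detected) with at least three
#' columns: id of protein A, id of protein B, and a binary interaction label
#' (1 = interacting, 0 = non-interacting). An optional header line is
#' detected by a non-numeric third field. Every id must resolve against
#' `proteins`.
#'
#' @param path Path to the pair file.
#' @param proteins Named character vector of sequences (see [read_fasta()]).
#' @return A `data.frame` with columns `id_a`, `id_b`, `label`.
#' @export
read_pairs <- function(path, proteins) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  sep <- .detect_sep(path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "", comment.char = "#",
                           strip.white = TRUE)
  if (ncol(tab) < 3L) stop("pair file needs >= 3 columns (id_a, id_b, label)")
  if (nrow(tab) > 0L && is.na(suppressWarnings(as.numeric(tab[1L, 3L])))) {
    tab <- tab[-1L, , drop = FALSE]  # header line
  }
  if (nrow(tab) == 0L) {
    return(data.frame(id_a = character(), id_b = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  lab_num <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(lab_num) || !all(lab_num %in% c(0, 1))) {
    stop("pair labels must be binary (0/1); offending value(s): ",
         paste(unique(tab[[3L]][is.na(lab_num) | !(lab_num %in% c(0, 1))]),
               collapse = ", "))
  }
  ids <- unique(c(tab[[1L]], tab[[2L]]))
  missing_ids <- setdiff(ids, names(proteins))
  if (length(missing_ids)) {
    stop("pair file references unknown protein id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  data.frame(id_a = tab[[1L]], id_b = tab[[2L]], label = as.integer(lab_num),
             stringsAsFactors = FALSE)
}

#' Write a pair list
#'
#' Tab-separated with a header, the dialect accepted by [read_pairs()].
#'
#' @param pairs `data.frame` with columns `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-pair predictions
#'
#' One row per pair: ids, true label (if present in `pairs`), predicted
#' label, and the real-valued decision score (larger = more
#' interaction-like). Tab-separated with a header.
#'
#' @param pairs `data.frame` with `id_a`, `id_b` and optionally `label`.
#' @param labels Integer vector of predicted labels, aligned with `pairs`.
#' @param scores Numeric decision scores, aligned with `pairs`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pairs, labels, scores, path) {
  stopifnot(nrow(pairs) == length(labels), nrow(pairs) == length(scores))
  out <- data.frame(id_a = pairs$id_a, id_b = pairs$id_b,
                    stringsAsFactors = FALSE)
  if (!is.null(pairs$label)) out$label <- pairs$label
  out$predicted <- labels
  out$score <- scores
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#'
#' @param path Path to the predictions TSV.
#' @return A `data.frame`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
}

#' Write a per-protein feature matrix
#'
#' Tab-separated, one protein per row, id in the first column, feature names
#' in the header.
#'
#' @param X Numeric matrix with row names (protein ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with protein ids as row names.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  storage.mode(X) <- "double"
  X
}
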