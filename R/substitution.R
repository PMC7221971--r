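# Substitution matrices: the identity ("unit") matrix driving the
# physicochemical graph energy, and the real-valued contact-energy matrix
# driving the contact graph energy.

#' Unit substitution matrix
#'
#' The 20x20 identity matrix in the physicochemical-ordering basis
#' ([aa_order()]). Encoding a sequence with it yields one-hot residue
#' columns, so each sliding-window bipartite graph links window positions to
#' residue types.
#'
#' @return 20x20 numeric matrix with residue dimnames.
#' @export
unit_matrix <- function() {
  M <- diag(20)
  dimnames(M) <- list(aa_order(), aa_order())
  M
}

.check_contact <- function(M) {
  if (!is.matrix(M) || nrow(M) != 20L || ncol(M) != 20L)
    stop("contact matrix must be 20x20, got ",
         paste(dim(as.matrix(M)), collapse = "x"))
  if (!is.numeric(M) || any(!is.finite(M)))
    stop("contact matrix must be finite numeric")
  invisible(M)
}

#' Load an amino-acid contact-energy matrix
#'
#' Reads a delimited 20x20 numeric file whose header row and first column
#' carry one-letter residue codes (any order), and re-indexes it into the
#' internal physicochemical ordering ([aa_order()]). Tab- or comma-delimited
#' files are auto-detected.
#'
#' @param path Path to the matrix file.
#' @return 20x20 numeric matrix in [aa_order()] basis, with attribute
#'   `name = "contact"`.
#' @seealso [default_contact_matrix()], [write_contact_matrix()]
#' @export
load_contact_matrix <- function(path) {
  if (!file.exists(path)) stop("contact matrix file not found: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("contact matrix contains non-numeric cells")
  if (nrow(M) != 20L || ncol(M) != 20L)
    stop("contact matrix must be 20x20 (after labels), got ",
         nrow(M), "x", ncol(M))
  rl <- toupper(rownames(M)); cl <- toupper(colnames(M))
  unknown <- setdiff(unique(c(rl, cl)), aa_order())
  if (length(unknown))
    stop("unknown residue label(s) in contact matrix: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(rl) || anyDuplicated(cl) ||
      !setequal(rl, aa_order()) || !setequal(cl, aa_order()))
    stop("contact matrix labels must be a permutation of the 20 canonical codes")
  rownames(M) <- rl; colnames(M) <- cl
  M <- M[aa_order(), aa_order()]
  .check_contact(M)
  attr(M, "name") <- "contact"
  M
}

#' Write a contact matrix
#'
#' Inverse of [load_contact_matrix()]: tab-separated with residue labels on
#' both axes (written in the internal ordering).
#'
#' @param M 20x20 numeric matrix with residue dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(M, path) {
  .check_contact(M)
  df <- data.frame(aa = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled synthetic contact-energy matrix
#'
#' Loads the contact matrix shipped with the package
#' (`extdata/contact_energy_synthetic.tsv`). This fixture is a clearly
#' labelled *synthetic stand-in*, not measured interface statistics: it is a
#' smooth symmetric surface derived from the Kyte-Doolittle hydropathy
#' scale, chosen so that hydrophobic residue pairs receive favourable
#' (negative) contact energies. For scientific use, supply a measured
#' contact-energy matrix through [load_contact_matrix()].
#'
#' @return 20x20 numeric matrix in [aa_order()] basis.
#' @export
default_contact_matrix <- function() {
  path <- system.file("extdata", "contact_energy_synthetic.tsv",
                      package = "geppi", mustWork = TRUE)
  load_contact_matrix(path)
}
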