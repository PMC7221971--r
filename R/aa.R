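# Residue alphabet and the fixed physicochemical ordering used by the
# graph-energy encodings.

# Descending isoelectric-point / ionization-equilibrium ordering of the 20
# canonical residues. Column t of a substitution matrix corresponds to the
# t-th residue of this ordering.
.AA_ORDER <- c("D", "E", "C", "N", "M", "F", "Q", "Y", "S", "P",
               "T", "V", "L", "I", "W", "H", "G", "A", "R", "K")

#' Amino-acid ordering used by the graph-energy encodings
#'
#' Returns the fixed ordering of the 20 canonical one-letter amino-acid
#' codes, ranked by isoelectric point and ionization equilibrium constant
#' (descending: D, E, C, N, M, F, Q, Y, S, P, T, V, L, I, W, H, G, A, R, K).
#' All substitution matrices, adjacency profiles and dipeptide indices in
#' the package are expressed in this basis.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_order()
aa_order <- function() .AA_ORDER

# Named lookup: residue code -> position in the ordering (1..20).
aa_index <- function() stats::setNames(seq_along(.AA_ORDER), .AA_ORDER)

#' Canonicalize and validate an amino-acid sequence
#'
#' Upper-cases a raw sequence, strips whitespace, and applies the residue
#' policy to characters outside the 20 canonical codes (e.g. X, B, Z, U, O,
#' gap characters):
#' \describe{
#'   \item{`"drop"`}{(default) the residue is removed with a warning and the
#'     length recomputed;}
#'   \item{`"error"`}{any non-canonical residue aborts;}
#'   \item{`"zero"`}{the residue is kept in place but contributes an
#'     all-zero column to adjacency profiles and is skipped by dipeptide
#'     counting.}
#' }
#'
#' @param seq Character scalar, the raw sequence.
#' @param policy One of `"drop"`, `"error"`, `"zero"`.
#' @param id Identifier used in messages.
#' @return The cleaned sequence (character scalar).
#' @export
clean_sequence <- function(seq, policy = c("drop", "error", "zero"), id = "?") {
  policy <- match.arg(policy)
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- gsub("[[:space:]]", "", toupper(seq))
  chars <- strsplit(s, "")[[1]]
  bad <- !(chars %in% .AA_ORDER)
  if (any(bad)) {
    codes <- unique(chars[bad])
    if (policy == "error") {
      stop("sequence '", id, "' contains non-canonical residues: ",
           paste(codes, collapse = ", "))
    }
    if (policy == "drop") {
      warning("sequence '", id, "': dropped ", sum(bad),
              " non-canonical residue(s) (", paste(codes, collapse = ", "), ")")
      chars <- chars[!bad]
    } else {
      warning("sequence '", id, "': ", sum(bad),
              " non-canonical residue(s) kept as zero columns (",
              paste(codes, collapse = ", "), ")")
    }
  }
  paste(chars, collapse = "")
}
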