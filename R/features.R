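# Per-protein descriptors: sliding-window graph-energy profiles
# (physicochemical and contact) and dipeptide composition, plus their
# fusion into one 800-entry vector.

#' Encode a sequence as an adjacency profile
#'
#' Maps a protein of length n to a 20 x n matrix whose j-th column is the
#' substitution-matrix column for the residue type at position j (column t
#' of `S`, where t is the residue's position in [aa_order()]). With the
#' unit matrix this is a one-hot encoding; with a contact matrix each
#' column carries the residue's contact energies against all 20 types.
#' Non-canonical residues retained under the `"zero"` policy contribute
#' all-zero columns.
#'
#' @param seq Character scalar, a validated amino-acid sequence.
#' @param S 20x20 substitution matrix ([unit_matrix()] or a contact matrix).
#' @return 20 x nchar(seq) numeric matrix, rows named by [aa_order()].
#' @export
encode_adjacency <- function(seq, S) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.matrix(S) || any(dim(S) != 20L)) stop("S must be a 20x20 matrix")
  chars <- strsplit(seq, "")[[1]]
  idx <- aa_index()[chars]
  M <- matrix(0, nrow = 20L, ncol = length(chars))
  ok <- !is.na(idx)
  if (any(ok)) M[, ok] <- S[, idx[ok]]
  rownames(M) <- aa_order()
  M
}

#' Graph energy of a window matrix
#'
#' A window matrix M is read as the biadjacency matrix of a bipartite graph
#' (residue types x window positions). The graph energy — the sum of the
#' absolute eigenvalues of the full symmetric adjacency
#' \eqn{[[0, M], [M^T, 0]]} — equals twice the sum of the singular values
#' of M, which is how it is computed here.
#'
#' @param M Numeric matrix (finite entries; any shape, typically 20x20).
#' @return Non-negative scalar energy.
#' @export
#' @examples
#' window_energy(matrix(0, 20, 20))           # empty graph: 0
#' M <- matrix(0, 20, 20); M[1:3, 1:2] <- 1
#' window_energy(M)                           # K_{3,2}: 2*sqrt(6)
window_energy <- function(M) {
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix")
  if (any(!is.finite(M))) stop("M has non-finite entries")
  2 * sum(svd(M, nu = 0, nv = 0)$d)
}

#' Sliding-window graph-energy profile
#'
#' Slides a window of `window` residues (default 20) along the adjacency
#' profile one position at a time, starting at the first residue, and
#' records the graph energy of each window sub-matrix. The profile is
#' zero-padded to a fixed length of `n_windows` entries (default 200);
#' sequences shorter than `window` residues yield the all-zero vector with
#' a warning, and sequences with more than `n_windows` windows are
#' truncated to the first `n_windows` (left-anchored).
#'
#' @inheritParams encode_adjacency
#' @param n_windows Fixed profile length (default 200).
#' @param window Window length in residues (default 20).
#' @return Numeric vector of length `n_windows`, entries >= 0.
#' @export
energy_profile <- function(seq, S, n_windows = 200L, window = 20L) {
  stopifnot(n_windows >= 1L, window >= 1L)
  n <- nchar(seq)
  e <- numeric(n_windows)
  if (n < window) {
    warning("sequence of length ", n, " has no length-", window,
            " window; returning all-zero profile")
    return(e)
  }
  M <- encode_adjacency(seq, S)
  k_max <- min(n - window + 1L, n_windows)
  for (k in seq_len(k_max)) {
    e[k] <- window_energy(M[, k:(k + window - 1L), drop = FALSE])
  }
  e
}

# Names for the 400 ordered dipeptides, ordering-major: index of (m, n)
# is (m - 1) * 20 + n over positions in aa_order().
.dipeptide_names <- function() {
  paste0(rep(aa_order(), each = 20L), rep(aa_order(), times = 20L))
}

#' Dipeptide composition
#'
#' Frequencies of all 400 ordered adjacent residue pairs: entry (m, n) is
#' \eqn{f_{mn} = N_{mn} / (L - 1)}, where \eqn{N_{mn}} counts occurrences
#' of the m-th residue type immediately followed by the n-th (positions in
#' [aa_order()]) and L is the sequence length. Entries sum to 1 whenever
#' L >= 2 and all residues are canonical; pairs involving a non-canonical
#' residue kept under the `"zero"` policy are skipped. A single-residue
#' sequence yields the all-zero vector with a warning.
#'
#' @inheritParams encode_adjacency
#' @return Named numeric vector of length 400 (ordering-major layout).
#' @export
#' @examples
#' dipeptide_composition("ACAC")[c("AC", "CA")]  # 2/3 and 1/3
dipeptide_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  f <- stats::setNames(numeric(400L), .dipeptide_names())
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 2L) {
    warning("sequence of length ", L, " has no dipeptides; all-zero vector")
    return(f)
  }
  idx <- aa_index()[chars]
  a <- idx[-L]
  b <- idx[-1L]
  keep <- !is.na(a) & !is.na(b)
  if (any(keep)) {
    counts <- tabulate((a[keep] - 1L) * 20L + b[keep], nbins = 400L)
    f[] <- counts / (L - 1L)
  }
  f
}

#' Fused per-protein descriptor
#'
#' Concatenates the physicochemical graph-energy profile (unit matrix `A`),
#' the contact graph-energy profile (contact matrix `B`) and the dipeptide
#' composition into one vector of length `2 * n_windows + 400` (800 at the
#' defaults).
#'
#' @inheritParams encode_adjacency
#' @param A Unit substitution matrix (default [unit_matrix()]); pluggable
#'   so alternative 0/1 substitution patterns can be tested.
#' @param B Contact-energy matrix (default [default_contact_matrix()]).
#' @inheritParams energy_profile
#' @return Named numeric vector (`pge_*`, `cge_*`, `dp_*` blocks).
#' @export
fuse_features <- function(seq, A = unit_matrix(), B = default_contact_matrix(),
                          n_windows = 200L, window = 20L) {
  pge <- energy_profile(seq, A, n_windows = n_windows, window = window)
  cge <- energy_profile(seq, B, n_windows = n_windows, window = window)
  dp <- dipeptide_composition(seq)
  wn <- formatC(seq_len(n_windows), width = 3L, flag = "0")
  stats::setNames(c(pge, cge, dp),
                  c(paste0("pge_", wn), paste0("cge_", wn),
                    paste0("dp_", names(dp))))
}

#' Fused feature matrix for a protein set
#'
#' Applies [fuse_features()] to every protein; one protein per row.
#'
#' @param proteins Named character vector of sequences (see [read_fasta()]).
#' @inheritParams fuse_features
#' @return Numeric matrix, rows named by protein id.
#' @export
feature_matrix <- function(proteins, A = unit_matrix(),
                           B = default_contact_matrix(),
                           n_windows = 200L, window = 20L) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  p <- 2L * n_windows + 400L
  X <- matrix(0, nrow = length(proteins), ncol = p)
  for (i in seq_along(proteins)) {
    v <- fuse_features(proteins[[i]], A = A, B = B,
                       n_windows = n_windows, window = window)
    if (i == 1L) colnames(X) <- names(v)
    X[i, ] <- v
  }
  rownames(X) <- names(proteins)
  X
}
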