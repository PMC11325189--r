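# Pairwise global alignment and profile-profile alignment. Starting-cluster
# members are near-identical (>= 90% id) so a deterministic progressive
# aligner with length-descending insertion order is used instead of a guide
# tree; internal-node MSAs come from profile-profile alignment of child MSAs.

#' Construct an alignment scoring scheme
#'
#' @param substitution 26x26 numeric matrix indexed by uppercase letters
#'   (rows/cols `LETTERS`); must be symmetric on the 20-residue alphabet.
#' @param gap_open non-negative gap opening penalty (affine mode: a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @param gap_extend non-negative per-residue gap penalty (linear mode: a
#'   gap of length L costs `L * gap_extend`).
#' @param mode `"affine"` or `"linear"`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution, gap_open, gap_extend,
                           mode = c("affine", "linear")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(substitution), nrow(substitution) == 26,
            ncol(substitution) == 26)
  if (!isTRUE(all.equal(substitution, t(substitution)))) {
    stop("substitution matrix must be symmetric")
  }
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  dimnames(substitution) <- list(LETTERS, LETTERS)
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "scoring_scheme")
}

#' BLOSUM62 scheme with affine gaps (open 11, extend 1)
#'
#' The community-standard default for protein global alignment.
#' @return A `scoring_scheme`.
#' @export
blosum62_scheme <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  S <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  common <- intersect(rownames(B), LETTERS)
  S[common, common] <- B[common, common]
  scoring_scheme(S, gap_open = 11, gap_extend = 1, mode = "affine")
}

#' Flat identity scheme (match 1, mismatch -1, linear gap 1)
#'
#' Exact-arithmetic scheme for tests and identity computations. `X` never
#' scores as a match, even against itself.
#'
#' @param match match score (default 1).
#' @param mismatch mismatch score (default -1).
#' @param gap per-residue linear gap penalty (default 1).
#' @return A `scoring_scheme`.
#' @export
identity_scheme <- function(match = 1, mismatch = -1, gap = 1) {
  S <- matrix(mismatch, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(S) <- match
  S["X", "X"] <- mismatch
  scoring_scheme(S, gap_open = gap, gap_extend = gap, mode = "linear")
}

#' Optimal global alignment of two residue strings
#'
#' Needleman-Wunsch (Gotoh for affine gaps) with a deterministic traceback:
#' at score ties the diagonal move is preferred over up (gap in `b`), which
#' is preferred over left (gap in `a`).
#'
#' @param a,b non-empty residue strings.
#' @param scheme a [scoring_scheme] (default [blosum62_scheme()]).
#' @return List with gapped strings `a`, `b` and the optimal `score`.
#' @export
global_align <- function(a, b, scheme = blosum62_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  .nw_align_cpp(toupper(a), toupper(b), scheme$substitution,
                scheme$gap_open, scheme$gap_extend,
                scheme$mode == "affine")
}

# per-column letter counts (26 x n_cols) and gap counts for a row matrix
profile_counts <- function(m) {
  codes <- matrix(match(m, LETTERS, nomatch = 0L), nrow = nrow(m))
  counts <- apply(codes, 2, tabulate, nbins = 26L)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 26L)
  gaps <- colSums(m == GAP)
  list(counts = counts, gaps = gaps, n = nrow(m))
}

#' Profile-profile alignment of two multiple sequence alignments
#'
#' Columns of each input alignment are never reordered; both sides acquire
#' the same inserted gap columns. The score of aligning column i of A with
#' column j of B is the mean over all row pairs of the substitution score
#' (gap-vs-residue pairs charged `gap_extend`, gap-vs-gap pairs zero). The
#' two profiles are oriented canonically (by smallest row id) before the
#' dynamic program so the result is symmetric in its arguments.
#'
#' @param A,B [alignment] objects with disjoint seq_id sets.
#' @param scheme a [scoring_scheme].
#' @return An [alignment] containing all rows of `A` and `B`.
#' @export
profile_align <- function(A, B, scheme = blosum62_scheme()) {
  if (length(intersect(names(A$rows), names(B$rows)))) {
    stop("alignments share seq_ids; profile_align requires disjoint sets")
  }
  swap <- min(names(B$rows)) < min(names(A$rows))
  P <- if (swap) B else A
  Q <- if (swap) A else B
  mp <- aln_matrix(P); mq <- aln_matrix(Q)
  cp <- profile_counts(mp); cq <- profile_counts(mq)
  S <- scheme$substitution
  ge <- scheme$gap_extend
  npairs <- cp$n * cq$n
  res_p <- cp$n - cp$gaps   # residue count per column of P
  res_q <- cq$n - cq$gaps
  # numerator: residue-residue substitution + gap-vs-residue charges
  num <- t(cp$counts) %*% S %*% cq$counts -
    ge * (outer(cp$gaps, res_q) + outer(res_p, cq$gaps))
  colscore <- num / npairs
  gap_p <- -ge * res_p / cp$n   # column of P vs inserted all-gap column
  gap_q <- -ge * res_q / cq$n
  open_pen <- if (scheme$mode == "affine") scheme$gap_open else 0
  dp <- .profile_dp_cpp(colscore, gap_p, gap_q, open_pen)
  L <- length(dp$take_a)
  expand <- function(m, take) {
    out <- matrix(GAP, nrow = nrow(m), ncol = L)
    out[, take] <- m
    out
  }
  mp2 <- expand(mp, dp$take_a)
  mq2 <- expand(mq, dp$take_b)
  rows_p <- setNames(apply(mp2, 1, paste, collapse = ""), rownames(mp))
  rows_q <- setNames(apply(mq2, 1, paste, collapse = ""), rownames(mq))
  rows <- if (swap) c(rows_q, rows_p) else c(rows_p, rows_q)
  # restore caller's A-then-B row order
  rows <- rows[c(names(A$rows), names(B$rows))]
  alignment(rows)
}

#' Progressive alignment of a starting cluster's members
#'
#' Members are sorted by sequence length descending (ties broken by
#' lexicographic seq_id); the first seeds the profile and each subsequent
#' sequence is profile-aligned in.
#'
#' @param cluster a [starting_cluster].
#' @param seqs a [domain_seqs] data frame containing all members.
#' @param scheme a [scoring_scheme].
#' @return An [alignment] with one row per member.
#' @export
align_members <- function(cluster, seqs, scheme = blosum62_scheme()) {
  ids <- cluster$member_ids
  missing <- setdiff(ids, seqs$seq_id)
  if (length(missing)) stop("no sequence for member: ", missing[1])
  res <- setNames(seqs$residues, seqs$seq_id)[ids]
  ord <- order(-nchar(res), ids)
  ids <- ids[ord]; res <- res[ord]
  msa <- alignment(res[1])
  for (i in seq_along(ids)[-1]) {
    msa <- profile_align(msa, alignment(res[i]), scheme)
  }
  # keep rows in representative-first cluster order? keep insertion order
  msa
}
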