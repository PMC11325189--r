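# Per-column conservation scoring, alignment diversity (DOPS), and
# detection of differentially conserved positions (DCPs) between two
# alignments. The conservation score is an entropy-based measure with a
# gap penalty: score(j) = (1 - H_j / ln 20) * (1 - gap_fraction_j), where
# H_j is the Shannon entropy of the non-gap residue frequencies in column
# j. Fully conserved gap-free columns score 1; a column holding all 20
# residues equally scores 0.

#' Conservation and cut thresholds
#'
#' @param c_high score at or above which a column counts as conserved when
#'   looking for differential conservation (default 0.8).
#' @param c_cons score threshold for the "conserved positions" counted by
#'   DOPS (default 0.9, so a fully conserved alignment scores exactly 0).
#' @param g_max maximum gap fraction for a column to be comparable between
#'   two alignments (default 0.5).
#' @param d_max maximum number of DCPs tolerated when accepting a merge
#'   (default 0: any differential conservation splits).
#' @param min_support minimum number of non-gap residues a column needs on
#'   each side before it can count as differentially conserved (default 2:
#'   conservation asserted from a single sequence carries no evidence, so
#'   stray singleton clusters are absorbed by distance rather than split
#'   off by their own point mutations).
#' @return An object of class `conservation_params`.
#' @export
conservation_params <- function(c_high = 0.8, c_cons = 0.9, g_max = 0.5,
                                d_max = 0, min_support = 2) {
  stopifnot(c_high >= 0, c_high <= 1, c_cons >= 0, c_cons <= 1,
            g_max >= 0, g_max <= 1, d_max >= 0, min_support >= 1)
  structure(list(c_high = c_high, c_cons = c_cons, g_max = g_max,
                 d_max = d_max, min_support = min_support),
            class = "conservation_params")
}

# X is an unknown residue: it participates in the entropy as its own
# symbol but is never eligible as the modal residue.
conservation_from_matrix <- function(m) {
  nc <- ncol(m); nr <- nrow(m)
  scores <- numeric(nc); gapf <- numeric(nc); nres <- integer(nc)
  modal <- character(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    res <- col[col != GAP]
    nres[j] <- length(res)
    gapf[j] <- 1 - length(res) / nr
    if (!length(res)) { scores[j] <- 0; modal[j] <- NA_character_; next }
    p <- table(res) / length(res)
    H <- -sum(p * log(p))
    scores[j] <- max(0, 1 - H / log(20)) * (1 - gapf[j])
    cand <- p[names(p) != "X"]
    modal[j] <- if (length(cand)) {
      nm <- names(cand)[cand == max(cand)]
      sort(nm)[1]  # ties: alphabetical
    } else NA_character_
  }
  list(scores = scores, gap_fractions = gapf, modal_residues = modal,
       n_residues = nres)
}

#' Per-column conservation profile of an alignment
#'
#' @param msa an [alignment].
#' @return An object of class `conservation_profile`: list with `scores`
#'   (in `[0,1]`), `gap_fractions`, and `modal_residues` (most frequent
#'   non-gap residue, ties broken alphabetically).
#' @export
column_conservation <- function(msa) {
  out <- conservation_from_matrix(aln_matrix(msa))
  structure(out, class = "conservation_profile")
}

#' Diversity of positions score (DOPS) of an alignment
#'
#' Measures alignment diversity from the proportion of conserved columns:
#' `100 * (1 - n_conserved / n_cols)`, where a column is conserved when its
#' conservation score is at least `c_cons`. 0 means no variability (an
#' uninformative alignment), 100 a highly diverse, information-rich one.
#'
#' @param msa an [alignment].
#' @param params [conservation_params] (supplies `c_cons`).
#' @return A value in `[0, 100]`.
#' @export
dops <- function(msa, params = conservation_params()) {
  prof <- column_conservation(msa)
  100 * (1 - sum(prof$scores >= params$c_cons) / msa$n_cols)
}

# DCP scan on an already-merged alignment, given which rows came from each
# side. A merged column is a DCP iff both sides are conserved (>= c_high)
# with at least min_support non-gap residues, both sides have gap fraction
# < g_max, and the modal residues differ.
dcp_on_merged <- function(merged, ids_a, ids_b, params) {
  m <- aln_matrix(merged)
  pa <- conservation_from_matrix(m[ids_a, , drop = FALSE])
  pb <- conservation_from_matrix(m[ids_b, , drop = FALSE])
  hit <- pa$scores >= params$c_high & pb$scores >= params$c_high &
    pa$gap_fractions < params$g_max & pb$gap_fractions < params$g_max &
    pa$n_residues >= params$min_support & pb$n_residues >= params$min_support &
    !is.na(pa$modal_residues) & !is.na(pb$modal_residues) &
    pa$modal_residues != pb$modal_residues
  which(hit) - 1L  # 0-based merged-alignment columns
}

#' Differentially conserved positions between two alignments
#'
#' The two alignments are put on a common coordinate system with
#' [profile_align()]; a merged column is differentially conserved when it
#' is conserved on both sides (score >= `c_high`), has gap fraction below
#' `g_max` on both sides, and the two modal residues differ. Such columns
#' are the operational signature of a functional boundary.
#'
#' @param A,B [alignment] objects with disjoint seq_id sets.
#' @param params [conservation_params].
#' @param scheme [scoring_scheme] for the profile alignment.
#' @return Ascending 0-based column indices in the merged alignment.
#' @export
differentially_conserved_positions <- function(A, B,
                                               params = conservation_params(),
                                               scheme = blosum62_scheme()) {
  merged <- profile_align(A, B, scheme)
  dcp_on_merged(merged, names(A$rows), names(B$rows), params)
}

#' Write a per-column conservation profile TSV
#' @param msa an [alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_profile <- function(msa, path) {
  prof <- column_conservation(msa)
  d <- data.frame(column = seq_along(prof$scores) - 1L,
                  score = prof$scores,
                  gap_fraction = prof$gap_fractions,
                  modal_residue = prof$modal_residues)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
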