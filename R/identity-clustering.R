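# Greedy incremental clustering at an identity threshold (S90 generation)
# and GO-evidence filtering of the resulting starting clusters.

#' Clustering parameters
#'
#' @param identity_threshold fraction in (0, 1]; default 0.90, the
#'   starting-cluster convention.
#' @param evidence_whitelist GO evidence codes accepted as experimental;
#'   default the six classic experimental codes.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(identity_threshold = 0.90,
                              evidence_whitelist = go_experimental_codes) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  if (!length(evidence_whitelist)) stop("evidence_whitelist must be non-empty")
  structure(list(identity_threshold = identity_threshold,
                 evidence_whitelist = as.character(evidence_whitelist)),
            class = "clustering_params")
}

#' Pairwise sequence identity
#'
#' Identity is the number of identical aligned residue pairs in the optimal
#' global alignment divided by the length of the shorter sequence (the
#' convention of greedy incremental clustering tools). `X` never counts as
#' a match.
#'
#' @param a,b non-empty residue strings.
#' @param scheme [scoring_scheme] used for the alignment.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b, scheme = blosum62_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  al <- global_align(a, b, scheme)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  n_id <- sum(ca == cb & ca != GAP & ca != "X")
  min(1, n_id / min(nchar(a), nchar(b)))
}

#' Greedy incremental clustering of sequences
#'
#' Sequences are processed in length-descending order (ties broken by
#' lexicographic seq_id). Each sequence joins the first existing cluster
#' (in creation order) whose representative has identity at or above the
#' threshold; otherwise it founds a new cluster with itself as
#' representative. The sort canonicalizes the result, so clustering is
#' invariant to input order.
#'
#' @param seqs a [domain_seqs] data frame.
#' @param params [clustering_params].
#' @param scheme [scoring_scheme] for identity computation.
#' @return List of [starting_cluster] objects, ids `"SC1"`, `"SC2"`, ...
#' @export
greedy_cluster <- function(seqs, params = clustering_params(),
                           scheme = blosum62_scheme()) {
  if (anyDuplicated(seqs$seq_id)) stop("seq_ids must be unique")
  ord <- order(-nchar(seqs$residues), seqs$seq_id)
  ids <- seqs$seq_id[ord]
  res <- seqs$residues[ord]
  reps <- character()       # representative residues, creation order
  rep_ids <- character()
  members <- list()
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(res[i], reps[k], scheme) >=
          params$identity_threshold) {
        members[[k]] <- c(members[[k]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, res[i])
      rep_ids <- c(rep_ids, ids[i])
      members <- c(members, list(ids[i]))
    }
  }
  lapply(seq_along(reps), function(k) {
    starting_cluster(paste0("SC", k), rep_ids[k], members[[k]])
  })
}

#' Filter starting clusters on experimental GO evidence
#'
#' A cluster is kept iff at least one member has at least one GO term with
#' an evidence code in the whitelist; clusters annotated only by
#' non-experimental evidence (e.g. IEA) or not at all are discarded.
#'
#' @param clusters list of [starting_cluster] objects.
#' @param annotations an `annotation_table`.
#' @param params [clustering_params] (supplies the evidence whitelist).
#' @return List with elements `kept` and `discarded`, both lists of
#'   clusters, input order preserved.
#' @export
filter_by_go <- function(clusters, annotations,
                         params = clustering_params()) {
  go <- annotations$go
  exp_ids <- unique(go$seq_id[go$evidence %in% params$evidence_whitelist])
  keep <- vapply(clusters, function(cl) {
    any(cl$member_ids %in% exp_ids)
  }, logical(1))
  list(kept = clusters[keep], discarded = clusters[!keep])
}

#' Write cluster membership as TSV (cluster_id, is_representative, seq_id)
#' @param clusters list of [starting_cluster] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_membership <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id,
               is_representative = as.integer(cl$member_ids == cl$representative_id),
               seq_id = cl$member_ids)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster membership from TSV in the same dialect
#'
#' Adapter hook for substituting an externally produced clustering: any
#' tool's membership can be injected through this format.
#'
#' @param path TSV with columns `cluster_id`, `is_representative`, `seq_id`.
#' @return List of [starting_cluster] objects.
#' @export
read_cluster_membership <- function(path) {
  d <- read.delim(path, colClasses = c("character", "integer", "character"))
  lapply(split(d, factor(d$cluster_id, levels = unique(d$cluster_id))),
         function(g) {
           rep_id <- g$seq_id[g$is_representative == 1][1]
           starting_cluster(g$cluster_id[1], rep_id, g$seq_id)
         }) |> unname()
}
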