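# Refilling the relationship tree with the full member sets of its
# starting clusters and cutting it into FunFams. A node is accepted when
# both children are accepted, the merge shows at most d_max differentially
# conserved positions between the child alignments, and (optionally) the
# merge height does not exceed a distance ceiling. FunFams are the member
# sets of the maximal accepted subtrees — the largest coherent subsets in
# which no functional boundary is detected.

#' Cut parameters
#'
#' @param conservation [conservation_params] for DCP detection.
#' @param distance_ceiling optional non-negative height above which merges
#'   are always rejected (`NULL`, the default, disables the gate: the cut
#'   is then driven by differential conservation alone).
#' @param min_funfam_size minimum reported FunFam size (default 1).
#' @return An object of class `cut_params`.
#' @export
cut_params <- function(conservation = conservation_params(),
                       distance_ceiling = NULL, min_funfam_size = 1) {
  if (!is.null(distance_ceiling) && distance_ceiling < 0) {
    stop("distance_ceiling must be NULL or >= 0")
  }
  stopifnot(min_funfam_size >= 1)
  structure(list(conservation = conservation,
                 distance_ceiling = distance_ceiling,
                 min_funfam_size = min_funfam_size),
            class = "cut_params")
}

#' Refill a relationship tree with full cluster member sets
#'
#' The tree was built over cluster representatives only; refilling restores
#' each leaf's complete membership and propagates unions up the tree.
#'
#' @param tree a `relationship_tree` whose leaves are cluster ids.
#' @param clusters list of [starting_cluster] objects covering all leaves.
#' @return The tree with a `members` element: named list node_id ->
#'   character vector of member seq_ids.
#' @export
refill <- function(tree, clusters) {
  names(clusters) <- vapply(clusters, `[[`, "", "cluster_id")
  missing <- setdiff(tree$leaves, names(clusters))
  if (length(missing)) stop("no cluster for leaf: ", missing[1])
  members <- lapply(clusters[tree$leaves], `[[`, "member_ids")
  for (k in seq_len(nrow(tree$merges))) {
    m <- tree$merges[k, ]
    members[[m$new]] <- c(members[[m$left]], members[[m$right]])
  }
  tree$members <- members
  tree
}

#' Compute per-node multiple sequence alignments
#'
#' Leaf alignments come from [align_members()]; each internal node's
#' alignment is the profile-profile alignment of its children's, computed
#' bottom-up in merge order.
#'
#' @param tree a refilled `relationship_tree`.
#' @param clusters list of [starting_cluster] objects.
#' @param seqs [domain_seqs] with all member sequences.
#' @param scheme [scoring_scheme].
#' @return The tree with a `node_msas` element: named list node_id ->
#'   [alignment].
#' @export
node_alignments <- function(tree, clusters, seqs,
                            scheme = blosum62_scheme()) {
  if (is.null(tree$members)) tree <- refill(tree, clusters)
  names(clusters) <- vapply(clusters, `[[`, "", "cluster_id")
  msas <- lapply(clusters[tree$leaves], function(cl) {
    if (!is.null(cl$msa)) cl$msa else align_members(cl, seqs, scheme)
  })
  for (k in seq_len(nrow(tree$merges))) {
    m <- tree$merges[k, ]
    msas[[m$new]] <- profile_align(msas[[m$left]], msas[[m$right]], scheme)
  }
  tree$node_msas <- msas
  tree
}

#' Cut a relationship tree into functional families
#'
#' Post-order evaluation: a leaf is always accepted; an internal node is
#' accepted iff both children are accepted, the number of differentially
#' conserved positions between the child alignments is at most `d_max`,
#' and (when a `distance_ceiling` is set) the merge height does not exceed
#' it. FunFams are the member sets of maximal accepted subtrees.
#'
#' @param tree a `relationship_tree` (refilled and aligned as needed).
#' @param clusters list of [starting_cluster] objects.
#' @param seqs [domain_seqs] with all member sequences.
#' @param params [cut_params].
#' @param scheme [scoring_scheme].
#' @return An object of class `cut_result`: list with `funfams` (list of
#'   [funfam]), `accepted_nodes`, `rejected_nodes`, `report` (per-internal-
#'   node data frame: node, dcp_count, height, accepted), `params_used`.
#' @export
cut_tree <- function(tree, clusters, seqs, params = cut_params(),
                     scheme = blosum62_scheme()) {
  if (is.null(tree$members)) tree <- refill(tree, clusters)
  if (is.null(tree$node_msas)) tree <- node_alignments(tree, clusters, seqs,
                                                       scheme)
  cp <- params$conservation
  accepted <- setNames(rep(TRUE, length(tree$leaves)), tree$leaves)
  report <- vector("list", nrow(tree$merges))
  for (k in seq_len(nrow(tree$merges))) {
    m <- tree$merges[k, ]
    ok_children <- accepted[[m$left]] && accepted[[m$right]]
    ndcp <- NA_integer_
    ok <- FALSE
    if (ok_children) {
      ids_l <- names(tree$node_msas[[m$left]]$rows)
      ids_r <- names(tree$node_msas[[m$right]]$rows)
      ndcp <- length(dcp_on_merged(tree$node_msas[[m$new]], ids_l, ids_r, cp))
      ok <- ndcp <= cp$d_max &&
        (is.null(params$distance_ceiling) ||
           m$height <= params$distance_ceiling)
    }
    accepted[[m$new]] <- ok
    report[[k]] <- data.frame(node = m$new, dcp_count = ndcp,
                              height = m$height, accepted = ok)
  }
  # maximal accepted subtrees: accepted nodes whose parent is rejected
  # (or which are the root)
  parent <- character()
  for (k in seq_len(nrow(tree$merges))) {
    m <- tree$merges[k, ]
    parent[[m$left]] <- m$new
    parent[[m$right]] <- m$new
  }
  all_nodes <- names(accepted)
  maximal <- vapply(all_nodes, function(id) {
    accepted[[id]] &&
      (id == tree$root_id || !accepted[[parent[[id]]]])
  }, logical(1))
  roots <- all_nodes[maximal]
  funfams <- lapply(seq_along(roots), function(i) {
    id <- roots[i]
    funfam(sprintf("FF%03d", i), tree$members[[id]],
           msa = tree$node_msas[[id]])
  })
  check_partition(funfams, unlist(tree$members[tree$leaves],
                                  use.names = FALSE))
  structure(list(funfams = funfams,
                 accepted_nodes = all_nodes[accepted[all_nodes]],
                 rejected_nodes = all_nodes[!accepted[all_nodes]],
                 report = do.call(rbind, report),
                 params_used = params),
            class = "cut_result")
}

#' Write the per-node cut report TSV
#' @param result a `cut_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cut_report <- function(result, path) {
  write.table(result$report, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
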