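# Agglomerative construction of the relationship tree over starting
# clusters: repeatedly merge the closest pair of nodes in the distance
# half-matrix, updating inter-node distances with the Lance-Williams rule
# for the chosen linkage. Deterministic: ties are broken by the
# lexicographically smallest (left_id, right_id) pair.

#' Build a relationship tree by agglomerative clustering
#'
#' @param hm a [half_matrix] over the starting-cluster ids (n >= 2).
#' @param linkage `"average"` (unweighted average, the default), `"single"`,
#'   `"complete"`, or `"centroid"` (Lance-Williams on squared distances;
#'   merge heights may then be non-monotone).
#' @return An object of class `relationship_tree`: list with `leaves`
#'   (ordered cluster ids), `merges` (data frame `step`, `left`, `right`,
#'   `new`, `height`) and `root_id`.
#' @export
agglomerate <- function(hm, linkage = c("average", "single", "complete",
                                        "centroid")) {
  linkage <- match.arg(linkage)
  n <- length(hm$ids)
  if (n < 2) stop("need at least 2 items to build a tree")
  D <- as.matrix(as_dist(hm))
  sq <- linkage == "centroid"
  if (sq) D <- D^2
  ids <- hm$ids
  size <- rep(1, n)
  active <- rep(TRUE, n)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    # minimum current distance among active pairs
    sub <- D[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    w <- which(sub == mn, arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest ordered (left, right) id pair
    lid <- pmin(ids[idx[w[, 1]]], ids[idx[w[, 2]]])
    rid <- pmax(ids[idx[w[, 1]]], ids[idx[w[, 2]]])
    pick <- order(lid, rid)[1]
    i <- idx[w[pick, 1]]; j <- idx[w[pick, 2]]
    left <- min(ids[i], ids[j]); right <- max(ids[i], ids[j])
    new_id <- paste0("N", step)
    while (new_id %in% ids) new_id <- paste0("_", new_id)
    h <- if (sq) sqrt(mn) else mn
    merges[[step]] <- data.frame(step = step, left = left, right = right,
                                 new = new_id, height = h)
    # Lance-Williams update into slot i; deactivate j
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      a <- size[i]; b <- size[j]
      dnew <- switch(linkage,
        average  = (a * D[i, others] + b * D[j, others]) / (a + b),
        single   = pmin(D[i, others], D[j, others]),
        complete = pmax(D[i, others], D[j, others]),
        centroid = (a * D[i, others] + b * D[j, others]) / (a + b) -
                   (a * b) / (a + b)^2 * D[i, j])
      D[i, others] <- dnew; D[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    ids[i] <- new_id
  }
  merges <- do.call(rbind, merges)
  structure(list(leaves = hm$ids, merges = merges,
                 root_id = merges$new[n - 1], linkage = linkage),
            class = "relationship_tree")
}

# children of each internal node: named list new_id -> c(left, right)
tree_children <- function(tree) {
  setNames(Map(c, tree$merges$left, tree$merges$right), tree$merges$new)
}

# heights of all nodes (leaves 0)
tree_heights <- function(tree) {
  c(setNames(rep(0, length(tree$leaves)), tree$leaves),
    setNames(tree$merges$height, tree$merges$new))
}

#' Serialize a relationship tree to Newick
#'
#' Branch lengths (when requested) are ultrametric: a node merged at height
#' h sits at h/2, and a branch length is the difference between parent and
#' child node heights.
#'
#' @param tree a `relationship_tree`.
#' @param heights include branch lengths (default `TRUE`).
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, heights = TRUE) {
  ch <- tree_children(tree)
  hts <- tree_heights(tree) / 2
  rec <- function(id) {
    if (is.null(ch[[id]])) return(id)
    paste0("(", rec(ch[[id]][1]), subtree_len(ch[[id]][1], id), ",",
                rec(ch[[id]][2]), subtree_len(ch[[id]][2], id), ")")
  }
  subtree_len <- function(child, parent) {
    if (!heights) return("")
    paste0(":", format(max(0, hts[[parent]] - hts[[child]]), digits = 10))
  }
  paste0(rec(tree$root_id), ";")
}

#' Convert a relationship tree to an `ape` phylo object
#' @param tree a `relationship_tree`.
#' @param heights include branch lengths.
#' @return An [ape] `phylo` object.
#' @export
as_phylo <- function(tree, heights = TRUE) {
  ape::read.tree(text = to_newick(tree, heights))
}

#' Write the merge trace as TSV (step, left, right, new, height)
#' @param tree a `relationship_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merge_trace <- function(tree, path) {
  m <- tree$merges
  m$height <- format(m$height, digits = 17, scientific = FALSE, trim = TRUE)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reconstruct a relationship tree from a merge-trace TSV
#' @param path path written by [write_merge_trace()].
#' @return A `relationship_tree`.
#' @export
read_merge_trace <- function(path) {
  m <- read.delim(path, colClasses = c("integer", "character", "character",
                                       "character", "numeric"))
  children <- as.vector(rbind(m$left, m$right)) # first-appearance order
  leaves <- setdiff(children, m$new)
  structure(list(leaves = leaves, merges = m,
                 root_id = m$new[nrow(m)], linkage = NA_character_),
            class = "relationship_tree")
}
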