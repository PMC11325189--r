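# Source-agnostic condensed distance half-matrices over cluster
# representatives, built either from embedding vectors (cosine / Euclidean /
# Manhattan) or from precomputed pairwise structural scores (1/bitscore,
# RMSD). The half-matrix is the only thing downstream tree building sees,
# so any distance source can be plugged in.

#' Construct a distance half-matrix
#'
#' Stores the n(n-1)/2 pairwise distances in row-major upper-triangle
#' (condensed) order — the same layout as [stats::dist].
#'
#' @param ids ordered character vector of n item ids.
#' @param condensed numeric vector of length n(n-1)/2, non-negative, finite.
#' @return An object of class `half_matrix`.
#' @export
half_matrix <- function(ids, condensed) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(condensed) != n * (n - 1) / 2) {
    stop("condensed length must be n(n-1)/2 = ", n * (n - 1) / 2)
  }
  if (any(!is.finite(condensed)) || any(condensed < 0)) {
    stop("distances must be finite and non-negative")
  }
  structure(list(ids = ids, condensed = as.numeric(condensed)),
            class = "half_matrix")
}

# condensed rank of pair (i, j), 1-based, i < j, matching stats::dist order
condensed_index <- function(i, j, n) {
  if (i > j) { t <- i; i <- j; j <- t }
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

#' Look up a pairwise distance by id
#' @param hm a [half_matrix].
#' @param a,b item ids.
#' @return The stored distance (`0` when `a == b`).
#' @export
hm_lookup <- function(hm, a, b) {
  i <- match(a, hm$ids); j <- match(b, hm$ids)
  if (is.na(i) || is.na(j)) stop("unknown id: ", if (is.na(i)) a else b)
  if (i == j) return(0)
  hm$condensed[condensed_index(i, j, length(hm$ids))]
}

#' Convert a half-matrix to a base `dist` object
#' @param hm a [half_matrix].
#' @return A [stats::dist] with labels.
#' @export
as_dist <- function(hm) {
  structure(hm$condensed, Size = length(hm$ids), Labels = hm$ids,
            Diag = FALSE, Upper = FALSE, method = "user", class = "dist")
}

#' Cosine distance between two vectors
#' @param u,v numeric vectors of equal length; neither all-zero.
#' @return `1 - cos(u, v)`, in `[0, 2]`.
#' @export
cosine_distance <- function(u, v) {
  check_pair(u, v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for a zero vector")
  max(0, 1 - sum(u * v) / (nu * nv))
}

#' Euclidean distance between two vectors
#' @inheritParams cosine_distance
#' @return Non-negative real.
#' @export
euclidean_distance <- function(u, v) {
  check_pair(u, v)
  sqrt(sum((u - v)^2))
}

#' Manhattan distance between two vectors
#' @inheritParams cosine_distance
#' @return Non-negative real.
#' @export
manhattan_distance <- function(u, v) {
  check_pair(u, v)
  sum(abs(u - v))
}

check_pair <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("vectors must be finite")
  invisible(TRUE)
}

metric_choices <- c("cosine", "euclidean", "manhattan", "inv_bitscore", "rmsd")

#' Build a distance half-matrix from embedding vectors
#'
#' @param vectors numeric matrix, one row per item, rownames = ids.
#' @param metric `"cosine"` (default), `"euclidean"` or `"manhattan"`.
#' @return A [half_matrix] with ids in input (row) order.
#' @export
build_half_matrix <- function(vectors, metric = "cosine") {
  metric <- match.arg(metric, c("cosine", "euclidean", "manhattan"))
  if (!is.matrix(vectors) || is.null(rownames(vectors))) {
    stop("vectors must be a numeric matrix with rownames as ids")
  }
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 vectors")
  d <- switch(metric,
    euclidean = stats::dist(vectors, method = "euclidean"),
    manhattan = stats::dist(vectors, method = "manhattan"),
    cosine = {
      nrm <- sqrt(rowSums(vectors^2))
      if (any(nrm == 0)) {
        stop("cosine distance undefined for zero vector: ",
             rownames(vectors)[nrm == 0][1])
      }
      cs <- tcrossprod(vectors / nrm)
      full <- pmax(1 - cs, 0)
      stats::as.dist(full)
    })
  half_matrix(rownames(vectors), pmax(0, as.numeric(d)))
}

#' Convert a pairwise score table to a distance half-matrix
#'
#' Structural-aligner output (query, target, bitscore and/or rmsd) is turned
#' into distances: `inv_bitscore` maps score s to 1/s, `rmsd` is used
#' unchanged. When both directions of a pair are present they are
#' symmetrized by the arithmetic mean of the two distances. Pairs absent
#' from the table get `d_max_fill` (default 10 x the largest observed
#' distance), so sparse input never silently creates zero distances.
#'
#' @param pairs data frame with columns `query`, `target` and `bitscore`
#'   (for `inv_bitscore`) or `rmsd` (for `rmsd`); extra columns ignored.
#' @param kind `"inv_bitscore"` or `"rmsd"`.
#' @param ids optional ordered id vector; default: ids in order of first
#'   appearance in the table.
#' @param d_max_fill distance assigned to missing pairs; default
#'   `10 * max(observed)`.
#' @return A [half_matrix].
#' @export
score_to_distance <- function(pairs, kind = c("inv_bitscore", "rmsd"),
                              ids = NULL, d_max_fill = NULL) {
  kind <- match.arg(kind)
  col <- if (kind == "inv_bitscore") "bitscore" else "rmsd"
  if (!all(c("query", "target", col) %in% names(pairs))) {
    stop("pair table must have columns query, target, ", col)
  }
  val <- as.numeric(pairs[[col]])
  if (kind == "inv_bitscore") {
    if (any(val <= 0)) stop("bitscore must be positive")
    dval <- 1 / val
  } else {
    if (any(val < 0)) stop("rmsd must be non-negative")
    dval <- val
  }
  if (is.null(ids)) {
    ids <- unique(c(rbind(as.character(pairs$query), as.character(pairs$target))))
  } else {
    unknown <- setdiff(unique(c(pairs$query, pairs$target)), ids)
    if (length(unknown)) stop("pair with unknown id: ", unknown[1])
  }
  n <- length(ids)
  if (n < 2) stop("need at least 2 ids")
  qi <- match(pairs$query, ids); ti <- match(pairs$target, ids)
  if (anyNA(qi) || anyNA(ti)) {
    bad <- c(pairs$query[is.na(qi)], pairs$target[is.na(ti)])[1]
    stop("pair with unknown id: ", bad)
  }
  off <- qi != ti
  sums <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (r in which(off)) {
    i <- min(qi[r], ti[r]); j <- max(qi[r], ti[r])
    sums[i, j] <- sums[i, j] + dval[r]
    cnt[i, j] <- cnt[i, j] + 1L
  }
  observed <- cnt > 0
  mean_d <- ifelse(observed, sums / pmax(cnt, 1L), NA_real_)
  if (is.null(d_max_fill)) {
    mx <- suppressWarnings(max(mean_d[observed]))
    d_max_fill <- if (is.finite(mx)) 10 * mx else 1
  }
  cond <- numeric(n * (n - 1) / 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cond[condensed_index(i, j, n)] <-
      if (observed[i, j]) mean_d[i, j] else d_max_fill
  }
  half_matrix(ids, cond)
}

#' Toy k-mer frequency embedding of sequences
#'
#' A deterministic stand-in for language-model embeddings: each sequence is
#' mapped to its normalized k-mer frequency profile over the 20-residue
#' alphabet (dimension 20^k). K-mers containing `X` are skipped.
#'
#' @param seqs a [domain_seqs] data frame.
#' @param k k-mer size, 1..3.
#' @return Numeric matrix (rows = sequences, rownames = seq_ids).
#' @export
kmer_embed <- function(seqs, k = 1) {
  if (!(k %in% 1:3)) stop("k must be in 1..3")
  kmers <- AA20
  if (k >= 2) for (i in 2:k) {
    kmers <- as.vector(outer(kmers, AA20, paste0))
  }
  kmers <- sort(kmers)
  mat <- t(vapply(seq_len(nrow(seqs)), function(r) {
    s <- seqs$residues[r]
    L <- nchar(s)
    if (L < k) stop("sequence ", seqs$seq_id[r], " shorter than k")
    subs <- substring(s, 1:(L - k + 1), k:L)
    subs <- subs[!grepl("X", subs, fixed = TRUE)]
    if (!length(subs)) stop("sequence ", seqs$seq_id[r], " has no countable k-mers")
    tab <- table(factor(subs, levels = kmers))
    as.numeric(tab) / length(subs)
  }, numeric(length(kmers))))
  rownames(mat) <- seqs$seq_id
  colnames(mat) <- kmers
  mat
}

#' Write / read an embedding TSV (id + one column per dimension, no header)
#' @param vectors numeric matrix with rownames.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_embeddings <- function(vectors, path) {
  d <- data.frame(id = rownames(vectors), vectors, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  d <- read.delim(path, header = FALSE, colClasses = "character")
  ids <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m))) stop("non-finite embedding value in ", path)
  rownames(m) <- ids
  colnames(m) <- NULL
  m
}

#' Write / read a half-matrix (header line of ids, one value per line)
#' @param hm a [half_matrix].
#' @param path file path.
#' @return `path` / the [half_matrix].
#' @export
write_half_matrix <- function(hm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hm$ids, collapse = "\t"), con)
  writeLines(format(hm$condensed, digits = 17, scientific = FALSE, trim = TRUE),
             con)
  invisible(path)
}

#' @rdname write_half_matrix
#' @export
read_half_matrix <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  half_matrix(ids, as.numeric(lines[-1]))
}
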