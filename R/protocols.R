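# Orchestration of the three clustering protocols over the stage modules:
#   single : greedy identity clustering -> GO filter -> representative
#            distance half-matrix -> tree -> refill -> cut, one pass.
#   marc   : prepartition by multi-domain architecture, run the single-pass
#            stages per partition, then pool the resulting FunFams as
#            starting clusters (medoid representatives) for a final pass.
#   fran   : deal starting clusters at random into fixed-size projects,
#            cut each, then pool FunFams for a merging second iteration.

#' Protocol configuration
#'
#' @param mode `"single"`, `"marc"` or `"fran"`.
#' @param mda_min_size minimum number of sequences for an MDA to form its
#'   own partition in MARC (default 1: every architecture separates). The
#'   production-scale analogue of this threshold is on the order of a
#'   million sequences; it is a scale parameter, not an algorithmic
#'   constant.
#' @param fran_project_size maximum starting clusters per FRAN project
#'   (default 10).
#' @param seed integer seed for the FRAN shuffle.
#' @param metric distance metric over embedding vectors (default
#'   `"cosine"`).
#' @param linkage tree linkage (default `"average"`).
#' @param clustering [clustering_params].
#' @param cut [cut_params].
#' @param scheme [scoring_scheme] for alignment stages.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(mode = c("single", "marc", "fran"),
                            mda_min_size = 1,
                            fran_project_size = 10,
                            seed = 1,
                            metric = "cosine",
                            linkage = "average",
                            clustering = clustering_params(),
                            cut = cut_params(),
                            scheme = blosum62_scheme()) {
  mode <- match.arg(mode)
  stopifnot(mda_min_size >= 1, fran_project_size >= 1)
  structure(list(mode = mode, mda_min_size = mda_min_size,
                 fran_project_size = fran_project_size,
                 seed = as.integer(seed), metric = metric,
                 linkage = linkage, clustering = clustering, cut = cut,
                 scheme = scheme),
            class = "protocol_config")
}

#' Load a protocol configuration from a YAML file
#'
#' Recognized keys mirror the [protocol_config()] arguments (scalar fields
#' only; nested `clustering:` and `cut:` blocks set the corresponding
#' parameter objects).
#'
#' @param path YAML file.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- do.call(clustering_params, y$clustering %||% list())
  cons <- do.call(conservation_params, y$cut$conservation %||% list())
  cut <- cut_params(conservation = cons,
                    distance_ceiling = y$cut$distance_ceiling,
                    min_funfam_size = y$cut$min_funfam_size %||% 1)
  protocol_config(mode = y$mode %||% "single",
                  mda_min_size = y$mda_min_size %||% 1,
                  fran_project_size = y$fran_project_size %||% 10,
                  seed = y$seed %||% 1,
                  metric = y$metric %||% "cosine",
                  linkage = y$linkage %||% "average",
                  clustering = cl, cut = cut)
}

rep_vectors <- function(clusters, vectors) {
  reps <- vapply(clusters, `[[`, "", "representative_id")
  missing <- setdiff(reps, rownames(vectors))
  if (length(missing)) {
    stop("no embedding vector for representative: ", missing[1])
  }
  vm <- vectors[reps, , drop = FALSE]
  rownames(vm) <- vapply(clusters, `[[`, "", "cluster_id")
  vm
}

# one tree-build-and-cut pass over a set of starting clusters
run_core <- function(clusters, seqs, vectors, config, label = "") {
  if (length(clusters) == 0) return(list())
  if (length(clusters) == 1) {
    cl <- clusters[[1]]
    msa <- if (!is.null(cl$msa)) cl$msa else
      align_members(cl, seqs, config$scheme)
    return(list(funfam(paste0(label, "FF001"), cl$member_ids, msa = msa)))
  }
  hm <- build_half_matrix(rep_vectors(clusters, vectors), config$metric)
  tree <- agglomerate(hm, config$linkage)
  res <- cut_tree(tree, clusters, seqs, config$cut, config$scheme)
  lapply(res$funfams, function(ff) {
    ff$funfam_id <- paste0(label, ff$funfam_id)
    ff
  })
}

#' Medoid member of a sequence set in embedding space
#'
#' The member minimizing the summed distance to its co-members (ties broken
#' by lexicographic seq_id); used to represent a pooled FunFam when it
#' becomes a starting cluster of a subsequent iteration.
#'
#' @param member_ids character vector of seq_ids.
#' @param vectors embedding matrix covering the members.
#' @param metric distance metric name.
#' @return A single seq_id.
#' @export
medoid_member <- function(member_ids, vectors, metric = "cosine") {
  member_ids <- sort(member_ids)
  if (length(member_ids) == 1) return(member_ids)
  missing <- setdiff(member_ids, rownames(vectors))
  if (length(missing)) stop("no embedding vector for member: ", missing[1])
  hm <- build_half_matrix(vectors[member_ids, , drop = FALSE], metric)
  D <- as.matrix(as_dist(hm))
  member_ids[which.min(rowSums(D))]
}

pool_funfams <- function(funfams, vectors, metric) {
  lapply(seq_along(funfams), function(i) {
    ff <- funfams[[i]]
    starting_cluster(sprintf("P%04d", i),
                     medoid_member(ff$member_ids, vectors, metric),
                     ff$member_ids, msa = ff$msa)
  })
}

run_result <- function(mode, iter1, final, partitions, config, extra = NULL) {
  structure(c(list(mode = mode, funfams_iter1 = iter1,
                   funfams_final = final, partitions = partitions,
                   provenance = list(metric = config$metric,
                                     linkage = config$linkage,
                                     seed = config$seed,
                                     identity_threshold =
                                       config$clustering$identity_threshold,
                                     d_max = config$cut$conservation$d_max,
                                     distance_ceiling =
                                       config$cut$distance_ceiling,
                                     mode = mode)),
              extra),
            class = "run_result")
}

#' Single-pass protocol: cluster, filter, tree, cut
#'
#' @param seqs [domain_seqs].
#' @param annotations `annotation_table` (GO evidence drives the starting-
#'   cluster filter).
#' @param vectors embedding matrix (rownames = seq_ids) covering at least
#'   every kept cluster representative.
#' @param config [protocol_config].
#' @return A `run_result`; for this mode `funfams_final` equals
#'   `funfams_iter1`.
#' @export
run_single <- function(seqs, annotations, vectors,
                       config = protocol_config("single")) {
  clusters <- greedy_cluster(seqs, config$clustering, config$scheme)
  flt <- filter_by_go(clusters, annotations, config$clustering)
  ff <- run_core(flt$kept, seqs, vectors, config)
  run_result("single", ff, ff,
             list(all = vapply(flt$kept, `[[`, "", "cluster_id")),
             config,
             extra = list(clusters = flt$kept, discarded = flt$discarded))
}

#' Partition sequences by multi-domain architecture
#'
#' Each MDA whose sequence count reaches `mda_min_size` becomes its own
#' partition labeled by the MDA string; all remaining sequences (small
#' MDAs and sequences without an MDA) form one residual partition labeled
#' `"pooled"`.
#'
#' @param seqs [domain_seqs] (uses the `mda` column).
#' @param mda_min_size partition threshold.
#' @return Named list of [domain_seqs] subsets; disjoint, covering the
#'   input.
#' @export
partition_by_mda <- function(seqs, mda_min_size = 1) {
  mda <- ifelse(is.na(seqs$mda), "", seqs$mda)
  counts <- table(mda[nzchar(mda)])
  own <- names(counts)[counts >= mda_min_size]
  labels <- ifelse(mda %in% own, mda, "pooled")
  out <- lapply(split(seq_len(nrow(seqs)), labels), function(i) {
    s <- seqs[i, , drop = FALSE]
    class(s) <- c("domain_seqs", "data.frame")
    s
  })
  # stable order: MDA partitions sorted, residual last
  nm <- sort(setdiff(names(out), "pooled"))
  out[c(nm, intersect("pooled", names(out)))]
}

#' MDA-prepartitioned protocol (MARC)
#'
#' Sequences are grouped by multi-domain architecture; the single-pass
#' stages run independently in each partition (iteration 1); the pooled
#' FunFams, each represented by its embedding-space medoid member, become
#' the starting clusters of a final tree-build-and-cut iteration.
#'
#' @inheritParams run_single
#' @return A `run_result` with `funfams_iter1` (pooled over partitions) and
#'   `funfams_final`.
#' @export
run_marc <- function(seqs, annotations, vectors,
                     config = protocol_config("marc")) {
  parts <- partition_by_mda(seqs, config$mda_min_size)
  iter1 <- list()
  kept_ids <- list()
  for (pname in names(parts)) {
    clusters <- greedy_cluster(parts[[pname]], config$clustering,
                               config$scheme)
    flt <- filter_by_go(clusters, annotations, config$clustering)
    ff <- run_core(flt$kept, parts[[pname]], vectors, config,
                   label = paste0(pname, "/"))
    iter1 <- c(iter1, ff)
    kept_ids[[pname]] <- vapply(flt$kept, `[[`, "", "cluster_id")
  }
  pooled <- pool_funfams(iter1, vectors, config$metric)
  final <- run_core(pooled, seqs, vectors, config)
  run_result("marc", iter1, final, kept_ids, config)
}

#' Random-splitting protocol (FRAN)
#'
#' Starting clusters are shuffled by a seeded pseudo-random permutation and
#' dealt into consecutive projects of at most `fran_project_size` clusters.
#' Each project is tree-built and cut independently (iteration 1); the
#' pooled FunFams feed a merging second iteration that reunites families
#' split across projects.
#'
#' @inheritParams run_single
#' @return A `run_result` with `funfams_iter1` and `funfams_final`.
#' @export
run_fran <- function(seqs, annotations, vectors,
                     config = protocol_config("fran")) {
  clusters <- greedy_cluster(seqs, config$clustering, config$scheme)
  flt <- filter_by_go(clusters, annotations, config$clustering)
  kept <- flt$kept
  k <- length(kept)
  if (k == 0) return(run_result("fran", list(), list(), list(), config))
  perm <- withr::with_seed(config$seed, sample.int(k))
  P <- config$fran_project_size
  proj_of <- ceiling(seq_len(k) / P)
  iter1 <- list()
  assignment <- list()
  for (p in unique(proj_of)) {
    idx <- perm[proj_of == p]
    label <- sprintf("proj%02d/", p)
    iter1 <- c(iter1, run_core(kept[idx], seqs, vectors, config, label))
    assignment[[sprintf("proj%02d", p)]] <-
      vapply(kept[idx], `[[`, "", "cluster_id")
  }
  pooled <- pool_funfams(iter1, vectors, config$metric)
  final <- run_core(pooled, seqs, vectors, config)
  run_result("fran", iter1, final, assignment, config)
}

#' Extract the sequence partition induced by a list of FunFams
#' @param funfams list of [funfam] objects.
#' @return Named character vector: seq_id -> funfam_id.
#' @export
funfam_partition <- function(funfams) {
  out <- unlist(lapply(funfams, function(ff) {
    setNames(rep(ff$funfam_id, length(ff$member_ids)), ff$member_ids)
  }))
  out[sort(names(out))]
}
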