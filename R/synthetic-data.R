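# Seeded generator of synthetic superfamilies: K planted functional
# families, each with its own random ancestor, family-specific conserved
# residues at shared specificity-determining-position (SDP) columns,
# per-site substitution noise elsewhere, planted embedding clusters, and
# EC / GO / MDA labels. The substrate for end-to-end validation of every
# pipeline stage.

#' Simulation configuration
#'
#' @param n_families number of planted families K.
#' @param seqs_per_family members per family n.
#' @param seq_length sequence length L (must exceed `n_sdp`).
#' @param n_sdp number of shared SDP columns; every family carries its own
#'   fixed residue there, differing between any two families.
#' @param mutation_rate per-site substitution probability at non-SDP sites
#'   (uniform over the 19 alternative residues).
#' @param embed_dim embedding dimension D.
#' @param within_sd embedding noise s.d. around the family center.
#' @param between_sd s.d. of the family-center coordinates.
#' @param mda_assignment optional character vector of MDA strings, one per
#'   family (recycled); default: one shared single-domain MDA.
#' @param shared_ec3 if `TRUE` (default) families get ECs `1.1.1.<i>`, so
#'   EC4 separates families while EC3 unifies them.
#' @param shared_ancestor if `TRUE`, all families derive from one common
#'   ancestor and differ only at the SDP columns (plus mutation noise) —
#'   the fixture for testing that differential-conservation detection
#'   recovers exactly the planted columns. Default `FALSE`: independent
#'   ancestors, so families are separable by overall sequence identity.
#' @param seed integer seed; the whole generation is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 6, seqs_per_family = 40,
                       seq_length = 80, n_sdp = 3, mutation_rate = 0.03,
                       embed_dim = 16, within_sd = 1, between_sd = 6,
                       mda_assignment = NULL, shared_ec3 = TRUE,
                       shared_ancestor = FALSE, seed = 1) {
  stopifnot(n_families >= 1, seqs_per_family >= 1,
            seq_length > n_sdp, n_sdp >= 0,
            mutation_rate >= 0, mutation_rate < 1,
            embed_dim >= 1, within_sd >= 0, between_sd > 0)
  if (n_sdp > 0 && n_families > 20) {
    stop("at most 20 families can carry distinct SDP residues")
  }
  if (is.null(mda_assignment)) mda_assignment <- "3.40.50.620"
  mda_assignment <- rep_len(mda_assignment, n_families)
  structure(list(n_families = n_families, seqs_per_family = seqs_per_family,
                 seq_length = seq_length, n_sdp = n_sdp,
                 mutation_rate = mutation_rate, embed_dim = embed_dim,
                 within_sd = within_sd, between_sd = between_sd,
                 mda_assignment = mda_assignment, shared_ec3 = shared_ec3,
                 shared_ancestor = shared_ancestor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic superfamily with planted functional families
#'
#' One random ancestor is drawn per family; members copy it with per-site
#' substitution probability `mutation_rate` at non-SDP sites, while the
#' shared SDP columns are held fixed at the family's planted residue
#' (residues differ between any two families at every SDP column). Family
#' `i` receives EC `1.1.1.i` (distinct EC4, shared EC3) and one
#' experimental GO term (`IDA`) on all members; members also carry the
#' family's MDA string.
#'
#' @param config a [sim_config].
#' @return List with `seqs` ([domain_seqs]), `annotations`
#'   (`annotation_table`), and `truth` (list: `family_of` named vector,
#'   `sdp_columns`, `ec_of_family`, `families`).
#' @export
generate_superfamily <- function(config) {
  withr::with_seed(config$seed, {
    K <- config$n_families; n <- config$seqs_per_family
    L <- config$seq_length
    sdp_cols <- if (config$n_sdp > 0) {
      sort(sample.int(L, config$n_sdp))
    } else integer()
    # distinct residue per family at every SDP column
    sdp_res <- matrix("", nrow = K, ncol = length(sdp_cols))
    for (j in seq_along(sdp_cols)) {
      sdp_res[, j] <- sample(AA20, K)
    }
    ids <- character(); res <- character(); mda <- character()
    fam_of <- character()
    common <- if (config$shared_ancestor) sample(AA20, L, replace = TRUE)
    for (f in seq_len(K)) {
      anc <- if (config$shared_ancestor) common
             else sample(AA20, L, replace = TRUE)
      anc[sdp_cols] <- sdp_res[f, ]
      for (m in seq_len(n)) {
        s <- anc
        mut <- runif(L) < config$mutation_rate
        mut[sdp_cols] <- FALSE
        for (p in which(mut)) {
          s[p] <- sample(setdiff(AA20, anc[p]), 1)
        }
        id <- sprintf("F%02dS%03d", f, m)
        ids <- c(ids, id)
        res <- c(res, paste(s, collapse = ""))
        mda <- c(mda, config$mda_assignment[f])
        fam_of[id] <- sprintf("fam%02d", f)
      }
    }
    seqs <- domain_seqs(ids, res, mda = mda)
    ec_of_family <- setNames(
      if (config$shared_ec3) sprintf("1.1.1.%d", seq_len(K))
      else sprintf("1.1.%d.%d", seq_len(K), seq_len(K)),
      sprintf("fam%02d", seq_len(K)))
    go <- data.frame(seq_id = ids,
                     value = sprintf("GO:%07d", match(fam_of, names(ec_of_family))),
                     evidence = "IDA")
    ec <- data.frame(seq_id = ids, value = unname(ec_of_family[fam_of]))
    ann <- annotation_table(go = go, ec = ec)
    truth <- list(
      family_of = fam_of,
      sdp_columns = lapply(seq_len(K), function(f) {
        list(columns = sdp_cols, residues = sdp_res[f, ])
      }) |> setNames(sprintf("fam%02d", seq_len(K))),
      ec_of_family = ec_of_family,
      families = sprintf("fam%02d", seq_len(K))
    )
    list(seqs = seqs, annotations = ann, truth = truth)
  })
}

#' Generate planted-cluster embedding vectors for a synthetic superfamily
#'
#' Family centers are drawn i.i.d. from N(0, between_sd^2) in each of the
#' `embed_dim` coordinates; each member vector is its family center plus
#' N(0, within_sd^2) noise. With `between_sd` well above `within_sd` the
#' families form well-separated clusters in embedding space.
#'
#' @param truth the `truth` element of [generate_superfamily()].
#' @param config the same [sim_config] (its `seed` is offset so sequence
#'   and embedding noise are independent streams).
#' @return Numeric matrix, one row per sequence (rownames = seq_ids).
#' @export
generate_embeddings <- function(truth, config) {
  withr::with_seed(config$seed + 1000003L, {
    fams <- truth$families
    D <- config$embed_dim
    centers <- matrix(rnorm(length(fams) * D, sd = config$between_sd),
                      nrow = length(fams), dimnames = list(fams, NULL))
    ids <- names(truth$family_of)
    noise <- matrix(if (config$within_sd > 0) {
      rnorm(length(ids) * D, sd = config$within_sd)
    } else 0, nrow = length(ids), ncol = D)
    m <- centers[truth$family_of[ids], , drop = FALSE] + noise
    rownames(m) <- ids
    m
  })
}

#' Write a synthetic superfamily to disk in the pipeline's input formats
#'
#' Produces `<dir>/sequences.fasta`, `<dir>/annotations.tsv`,
#' `<dir>/embeddings.tsv` and `<dir>/truth.tsv` (seq_id, family).
#'
#' @param sim output of [generate_superfamily()].
#' @param vectors output of [generate_embeddings()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_superfamily <- function(sim, vectors, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$seqs, file.path(dir, "sequences.fasta"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_embeddings(vectors, file.path(dir, "embeddings.tsv"))
  tr <- data.frame(seq_id = names(sim$truth$family_of),
                   family = unname(sim$truth$family_of))
  write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
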