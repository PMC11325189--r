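# FunFam quality benchmarking: EC purity at 4- and 3-field resolution,
# threshold-proportion summaries, DOPS summaries, and partition agreement
# (adjusted Rand index) against a reference labeling.

ec_keys_at_level <- function(ec_strings, level) {
  fields <- strsplit(ec_strings, ".", fixed = TRUE)
  keys <- vapply(fields, function(f) {
    head_f <- f[seq_len(level)]
    if (any(head_f == "-")) NA_character_ else paste(head_f, collapse = ".")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' EC purity of a functional family
#'
#' Each member contributes its EC numbers truncated to `level` fields,
#' excluding any EC whose truncation still contains the `-` wildcard. A
#' member with several valid keys splits a unit weight equally among them,
#' so promiscuously annotated members cannot dominate. Purity is the
#' largest total weight of any one key divided by the total weight;
#' `NA` (undefined) when no member contributes — never zero.
#'
#' @param ff a [funfam].
#' @param annotations an `annotation_table`.
#' @param level 3 or 4 (EC3 / EC4).
#' @return Purity fraction in `[0, 1]`, or `NA_real_` if undefined.
#' @export
ec_purity <- function(ff, annotations, level = 4) {
  stopifnot(level %in% c(3, 4))
  ec <- annotations$ec
  weights <- list()
  for (id in ff$member_ids) {
    keys <- ec_keys_at_level(unique(ec$ec[ec$seq_id == id]), level)
    if (!length(keys)) next
    w <- 1 / length(keys)
    for (k in keys) weights[[k]] <- (weights[[k]] %||% 0) + w
  }
  if (!length(weights)) return(NA_real_)
  tot <- sum(unlist(weights))
  max(unlist(weights)) / tot
}

#' Purity summary over a set of FunFams
#'
#' Proportions of FunFams with EC4 purity at or above 0.8, at or above 0.9,
#' and equal to 1.0, plus mean EC4 and EC3 purity. Two denominators are
#' reported: FunFams with defined purity (`prop_*`) and all FunFams
#' (`prop_*_all`), since undefined (EC-less) families are excluded from
#' averages rather than counted as zero.
#'
#' @param funfams list of [funfam] objects.
#' @param annotations an `annotation_table`.
#' @return An object of class `purity_summary`.
#' @export
purity_summary <- function(funfams, annotations) {
  p4 <- vapply(funfams, ec_purity, numeric(1), annotations = annotations,
               level = 4)
  p3 <- vapply(funfams, ec_purity, numeric(1), annotations = annotations,
               level = 3)
  defined <- !is.na(p4)
  nd <- sum(defined)
  total <- length(funfams)
  prop <- function(x) if (nd) sum(x, na.rm = TRUE) / nd else NA_real_
  structure(list(
    prop_ge_80 = prop(p4 >= 0.8),
    prop_ge_90 = prop(p4 >= 0.9),
    prop_eq_100 = prop(p4 == 1.0),
    prop_ge_80_all = if (total) sum(p4 >= 0.8, na.rm = TRUE) / total else NA_real_,
    prop_ge_90_all = if (total) sum(p4 >= 0.9, na.rm = TRUE) / total else NA_real_,
    prop_eq_100_all = if (total) sum(p4 == 1.0, na.rm = TRUE) / total else NA_real_,
    mean_ec4 = if (nd) mean(p4, na.rm = TRUE) else NA_real_,
    mean_ec3 = if (any(!is.na(p3))) mean(p3, na.rm = TRUE) else NA_real_,
    n_defined = nd,
    n_undefined = total - nd,
    purities_ec4 = p4,
    purities_ec3 = p3
  ), class = "purity_summary")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' around 0 for independent ones.
#'
#' @param a,b partition labelings: named vectors (names = elements) or
#'   plain vectors over the same element universe.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions are over different element universes")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions are over different element universes")
  }
  mclust::adjustedRandIndex(as.character(a), as.character(b))
}

#' DOPS summary over a set of FunFams
#'
#' @param funfams list of [funfam] objects carrying alignments.
#' @param params [conservation_params].
#' @return List with `table` (funfam_id, n_members, dops) and `mean_dops`.
#' @export
dops_summary <- function(funfams, params = conservation_params()) {
  rows <- do.call(rbind, lapply(funfams, function(ff) {
    data.frame(funfam_id = ff$funfam_id,
               n_members = length(ff$member_ids),
               dops = if (!is.null(ff$msa)) dops(ff$msa, params) else NA_real_)
  }))
  list(table = rows, mean_dops = mean(rows$dops, na.rm = TRUE))
}

#' Write a benchmark report for a protocol run
#'
#' Produces `<out>/benchmark.tsv` (one row per FunFam: id, size, ec4/ec3
#' purity, dops) and `<out>/benchmark_summary.tsv` (key-value block of
#' summary metrics).
#'
#' @param funfams list of [funfam] objects.
#' @param annotations an `annotation_table`.
#' @param out_dir output directory.
#' @return Named list of the summary values, invisibly.
#' @export
write_benchmark_report <- function(funfams, annotations, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps <- purity_summary(funfams, annotations)
  ds <- dops_summary(funfams)
  per <- data.frame(funfam_id = ds$table$funfam_id,
                    size = ds$table$n_members,
                    ec4_purity = ps$purities_ec4,
                    ec3_purity = ps$purities_ec3,
                    dops = ds$table$dops)
  write.table(per, file.path(out_dir, "benchmark.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  keys <- c(n_funfams = length(funfams),
            prop_ge_80 = ps$prop_ge_80, prop_ge_90 = ps$prop_ge_90,
            prop_eq_100 = ps$prop_eq_100,
            mean_ec4 = ps$mean_ec4, mean_ec3 = ps$mean_ec3,
            n_defined = ps$n_defined, n_undefined = ps$n_undefined,
            mean_dops = ds$mean_dops)
  kv <- data.frame(metric = names(keys), value = unname(keys))
  write.table(kv, file.path(out_dir, "benchmark_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(as.list(keys))
}
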