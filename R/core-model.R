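# Domain types and readers/writers for the formats the pipeline touches:
# domain sequences (FASTA, plain or aligned), MDA strings, the 4-column
# annotation TSV, and per-run FunFam output directories.

#' Construct a set of domain sequences
#'
#' The tabular container used throughout the pipeline: one row per protein
#' domain sequence, with optional multi-domain-architecture (MDA) and
#' organism columns.
#'
#' @param seq_id character vector of unique sequence identifiers.
#' @param residues character vector of amino-acid strings (20-letter
#'   alphabet plus `X`); stored uppercased.
#' @param mda optional character vector of MDA strings (`NA` allowed).
#' @param organism optional character vector.
#' @return A `data.frame` of class `domain_seqs` with columns `seq_id`,
#'   `residues`, `mda`, `organism`.
#' @export
domain_seqs <- function(seq_id, residues, mda = NA_character_,
                        organism = NA_character_) {
  seq_id <- as.character(seq_id)
  residues <- toupper(as.character(residues))
  if (length(seq_id) != length(residues)) {
    stop("seq_id and residues must have the same length")
  }
  if (anyDuplicated(seq_id)) {
    stop("duplicate seq_id: ", seq_id[duplicated(seq_id)][1])
  }
  if (length(seq_id) && any(!nzchar(residues))) {
    stop("empty residue string for ", seq_id[!nzchar(residues)][1])
  }
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X-]"), residues)
  if (any(bad)) {
    stop("invalid residue characters in ", seq_id[bad][1])
  }
  out <- data.frame(
    seq_id = seq_id,
    residues = residues,
    mda = rep_len(as.character(mda), length(seq_id)),
    organism = rep_len(as.character(organism), length(seq_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("domain_seqs", "data.frame")
  out
}

#' Read domain sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' sequence id. Residues are uppercased. Gap characters are accepted so the
#' same reader serves aligned FASTA.
#'
#' @param path path to a FASTA file.
#' @return A [domain_seqs] data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank)) {
    first <- nonblank[1]
    if (!startsWith(trimws(lines[first]), ">")) {
      stop("malformed FASTA: sequence data before first header at line ", first)
    }
  } else {
    return(domain_seqs(character(), character()))
  }
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate seq_id in ", path, ": ", ids[duplicated(ids)][1])
  }
  domain_seqs(ids, toupper(as.character(aa)))
}

#' Write domain sequences (or alignment rows) to FASTA
#'
#' Round-trip inverse of [read_fasta()].
#'
#' @param seqs a [domain_seqs] data frame, or a named character vector of
#'   (possibly gapped) sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    v <- setNames(seqs$residues, seqs$seq_id)
  } else {
    v <- seqs
  }
  set <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

cath_id_re <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

#' Parse a multi-domain architecture (MDA) string
#'
#' An MDA string is the ordered list of CATH superfamily ids along a protein
#' chain joined by hyphens, e.g. `"3.40.50.300-2.40.60.10-3.40.50.620"`.
#' En-dashes (as typeset in journals) are normalized to ASCII hyphens.
#'
#' @param text a single MDA string.
#' @return Character vector of CATH ids, class `mda`.
#' @export
parse_mda <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("MDA string must be a single non-empty string")
  }
  text <- gsub("–", "-", text)  # en-dash -> hyphen
  if (grepl("^-|-$|--", text)) stop("malformed MDA token: ''")
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  bad <- !grepl(cath_id_re, parts)
  if (length(parts) == 0L || any(bad)) {
    tok <- if (length(parts)) parts[bad][1] else ""
    stop("malformed MDA token: '", tok, "'")
  }
  structure(parts, class = "mda")
}

#' Format an MDA back to its hyphen-joined string
#' @param mda an `mda` object or character vector of CATH ids.
#' @return A single string.
#' @export
format_mda <- function(mda) paste(unclass(mda), collapse = "-")

go_experimental_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
go_all_codes <- c(go_experimental_codes,
                  "HTP", "HDA", "HMP", "HGI", "HEP",
                  "IBA", "IBD", "IKR", "IRD",
                  "ISS", "ISO", "ISA", "ISM", "IGC", "RCA",
                  "TAS", "NAS", "IC", "ND", "IEA")

#' Read a sequence annotation table
#'
#' Expects a tab-separated file with four columns and no header:
#' `seq_id`, `kind` (`GO` or `EC`), `value`, `evidence` (empty for EC rows).
#' EC values must have exactly four dot-separated fields; `-` is the
#' wildcard for an unknown field (e.g. `3.4.12.-`).
#'
#' @param path path to the TSV.
#' @return An object of class `annotation_table`: a list with data frames
#'   `go` (`seq_id`, `term`, `evidence`) and `ec` (`seq_id`, `ec`).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "",
                    blank.lines.skip = TRUE)
  if (nrow(raw) == 0) return(annotation_table())
  if (ncol(raw) < 3) stop("annotation table needs >= 3 tab-separated columns")
  if (ncol(raw) == 3) raw$V4 <- ""
  names(raw)[1:4] <- c("seq_id", "kind", "value", "evidence")
  annotation_table(
    go = raw[raw$kind == "GO", c("seq_id", "value", "evidence")],
    ec = raw[raw$kind == "EC", c("seq_id", "value")]
  )
}

#' Construct an annotation table in memory
#'
#' @param go data frame with columns `seq_id`, `value` (GO term),
#'   `evidence` (GO evidence code).
#' @param ec data frame with columns `seq_id`, `value` (4-field EC string).
#' @return An `annotation_table` object.
#' @export
annotation_table <- function(go = NULL, ec = NULL) {
  empty_go <- data.frame(seq_id = character(), term = character(),
                         evidence = character(), stringsAsFactors = FALSE)
  empty_ec <- data.frame(seq_id = character(), ec = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(go) && nrow(go)) {
    go <- data.frame(seq_id = as.character(go[[1]]),
                     term = as.character(go[[2]]),
                     evidence = as.character(go[[3]]),
                     stringsAsFactors = FALSE)
    bad <- !(go$evidence %in% go_all_codes)
    if (any(bad)) stop("unknown GO evidence code: ", go$evidence[bad][1])
  } else go <- empty_go
  if (!is.null(ec) && nrow(ec)) {
    ec <- data.frame(seq_id = as.character(ec[[1]]),
                     ec = as.character(ec[[2]]),
                     stringsAsFactors = FALSE)
    nfield <- lengths(strsplit(ec$ec, ".", fixed = TRUE))
    bad <- nfield != 4L | !grepl("^[^.]+\\.[^.]+\\.[^.]+\\.[^.]+$", ec$ec)
    if (any(bad)) stop("EC string must have exactly 4 fields: '",
                       ec$ec[bad][1], "'")
  } else ec <- empty_ec
  structure(list(go = go, ec = ec), class = "annotation_table")
}

#' Write an annotation table to its 4-column TSV form
#' @param ann an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_table"))
  rows <- rbind(
    if (nrow(ann$go)) data.frame(seq_id = ann$go$seq_id, kind = "GO",
                                 value = ann$go$term,
                                 evidence = ann$go$evidence),
    if (nrow(ann$ec)) data.frame(seq_id = ann$ec$seq_id, kind = "EC",
                                 value = ann$ec$ec, evidence = "")
  )
  if (is.null(rows)) rows <- data.frame(seq_id = character(), kind = character(),
                                        value = character(), evidence = character())
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a starting cluster
#'
#' A starting cluster is a set of sequences clustered at high identity
#' (typically >= 90%), represented by one member; the leaf unit of
#' relationship-tree building.
#'
#' @param cluster_id cluster identifier.
#' @param representative_id seq_id of the representative (must be a member).
#' @param member_ids character vector of member seq_ids.
#' @param msa optional [alignment] of the members.
#' @return An object of class `starting_cluster`.
#' @export
starting_cluster <- function(cluster_id, representative_id, member_ids,
                             msa = NULL) {
  member_ids <- unique(as.character(member_ids))
  if (!length(member_ids)) stop("cluster must have at least one member")
  if (!representative_id %in% member_ids) {
    stop("representative_id must be a member of the cluster")
  }
  structure(list(cluster_id = as.character(cluster_id),
                 representative_id = as.character(representative_id),
                 member_ids = member_ids,
                 msa = msa),
            class = "starting_cluster")
}

#' Construct a multiple sequence alignment
#'
#' @param rows named character vector of equal-length gapped rows
#'   (names are seq_ids).
#' @return An object of class `alignment`.
#' @export
alignment <- function(rows) {
  if (!length(rows)) stop("alignment must have at least one row")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named by seq_id")
  }
  if (anyDuplicated(names(rows))) stop("duplicate seq_id in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows must all have equal length")
  rows <- toupper(rows)
  m <- aln_matrix_raw(rows)
  if (any(colSums(m != GAP) == 0)) stop("alignment contains an all-gap column")
  structure(list(rows = rows, n_cols = unname(w)), class = "alignment")
}

aln_matrix_raw <- function(rows) {
  do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
}

#' Character matrix view of an alignment (rows x columns)
#' @param msa an [alignment].
#' @return A character matrix with rownames = seq_ids.
#' @export
aln_matrix <- function(msa) {
  m <- aln_matrix_raw(msa$rows)
  rownames(m) <- names(msa$rows)
  m
}

#' Remove gaps from an alignment row
#' @param x gapped string(s).
#' @return Ungapped string(s).
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Construct a functional family (FunFam)
#'
#' @param funfam_id identifier.
#' @param member_ids character vector of member seq_ids.
#' @param msa an [alignment] of the members (optional until computed).
#' @param metrics optional named list (purity, dops, size).
#' @return An object of class `funfam`.
#' @export
funfam <- function(funfam_id, member_ids, msa = NULL, metrics = NULL) {
  member_ids <- unique(as.character(member_ids))
  if (!length(member_ids)) stop("FunFam must have at least one member")
  structure(list(funfam_id = as.character(funfam_id),
                 member_ids = member_ids, msa = msa,
                 metrics = metrics),
            class = "funfam")
}

check_partition <- function(funfams, universe = NULL) {
  members <- unlist(lapply(funfams, `[[`, "member_ids"), use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("FunFams are not disjoint: ", members[duplicated(members)][1])
  }
  if (!is.null(universe) && !setequal(members, universe)) {
    stop("FunFams do not cover the input sequence set")
  }
  invisible(TRUE)
}

#' Write a set of FunFams to a run directory
#'
#' Creates `<out_dir>/funfams/<id>.aln.fasta` (one aligned FASTA per
#' FunFam) and `<out_dir>/summary.tsv` with columns `funfam_id`, `size`,
#' `ec4_purity`, `ec3_purity`, `dops`. Purity of a FunFam with no
#' EC-annotated member is left empty (undefined), never written as zero.
#' The member sets must form a partition (pairwise disjoint).
#'
#' @param funfams list of [funfam] objects with alignments.
#' @param out_dir output directory (created if needed).
#' @param annotations optional `annotation_table` used to fill purity
#'   columns.
#' @return Path to the summary TSV, invisibly.
#' @export
write_funfam_set <- function(funfams, out_dir, annotations = NULL) {
  check_partition(funfams)
  ffdir <- file.path(out_dir, "funfams")
  dir.create(ffdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(funfams, function(ff) {
    if (!is.null(ff$msa)) {
      write_fasta(ff$msa$rows, file.path(ffdir, paste0(ff$funfam_id, ".aln.fasta")))
    }
    p4 <- p3 <- NA_real_
    if (!is.null(annotations)) {
      p4 <- ec_purity(ff, annotations, level = 4)
      p3 <- ec_purity(ff, annotations, level = 3)
    }
    dps <- if (!is.null(ff$msa)) dops(ff$msa) else NA_real_
    data.frame(funfam_id = ff$funfam_id, size = length(ff$member_ids),
               ec4_purity = p4, ec3_purity = p3, dops = dps)
  })
  summary <- do.call(rbind, rows)
  path <- file.path(out_dir, "summary.tsv")
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
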