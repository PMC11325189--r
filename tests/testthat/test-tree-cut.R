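id_scheme <- identity_scheme()

# two-family fixture with a planted specificity column: clusters c1/c2 are
# family "A...", c3/c4 family "S..." at position 2, all else identical
two_family_fixture <- function() {
  base <- "ACDEFGHIKL"
  sub2 <- function(s, r) `substr<-`(s, 3, 3, r)
  seqs <- domain_seqs(
    paste0("s", 1:8),
    c(rep(sub2(base, "A"), 4), rep(sub2(base, "S"), 4)))
  clusters <- list(
    starting_cluster("c1", "s1", c("s1", "s2")),
    starting_cluster("c2", "s3", c("s3", "s4")),
    starting_cluster("c3", "s5", c("s5", "s6")),
    starting_cluster("c4", "s7", c("s7", "s8")))
  hm <- half_matrix(c("c1", "c2", "c3", "c4"),
                    # c1-c2 close, c3-c4 close, families far apart
                    c(0.1, 0.9, 1.0, 0.8, 0.95, 0.2))
  list(seqs = seqs, clusters = clusters, hm = hm)
}

test_that("refill restores full member sets bottom-up", {
  fx <- two_family_fixture()
  tr <- agglomerate(fx$hm)
  tr <- refill(tr, fx$clusters)
  expect_setequal(tr$members[[tr$root_id]], fx$seqs$seq_id)
  expect_equal(length(tr$members[["c1"]]), 2)
  # every internal node's members = union of its children's
  for (k in seq_len(nrow(tr$merges))) {
    m <- tr$merges[k, ]
    expect_setequal(tr$members[[m$new]],
                    union(tr$members[[m$left]], tr$members[[m$right]]))
  }
  expect_error(refill(agglomerate(fx$hm), fx$clusters[1:3]), "no cluster")
})

test_that("node alignments carry one row per member", {
  fx <- two_family_fixture()
  tr <- node_alignments(agglomerate(fx$hm), fx$clusters, fx$seqs, id_scheme)
  for (id in names(tr$node_msas)) {
    expect_setequal(names(tr$node_msas[[id]]$rows), tr$members[[id]])
  }
  # identical sequences within each family: family-level nodes gap-free
  expect_false(any(grepl("-", tr$node_msas[[tr$merges$new[1]]]$rows)))
})

test_that("cut splits at the planted specificity boundary and nowhere else", {
  fx <- two_family_fixture()
  tr <- agglomerate(fx$hm)
  res <- cut_tree(tr, fx$clusters, fx$seqs, cut_params(), id_scheme)
  expect_length(res$funfams, 2)
  sets <- lapply(res$funfams, `[[`, "member_ids")
  expect_true(any(vapply(sets, setequal, logical(1), paste0("s", 1:4))))
  expect_true(any(vapply(sets, setequal, logical(1), paste0("s", 5:8))))
  # the rejected merge carries exactly the one planted DCP
  expect_equal(res$report$dcp_count[res$report$node == tr$root_id], 1)
})

test_that("single starting cluster yields a single FunFam", {
  seqs <- domain_seqs(c("a", "b"), c("ACDE", "ACDE"))
  cl <- list(starting_cluster("c1", "a", c("a", "b")))
  # degenerate case is handled at the protocol level
  ann <- annotation_table(go = data.frame(seq_id = "a", value = "GO:1",
                                          evidence = "IDA"))
  vec <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  vec["a", 1] <- 1; vec["b", 1] <- 1
  res <- run_single(seqs, ann, vec, protocol_config("single", scheme = id_scheme))
  expect_length(res$funfams_final, 1)
  expect_setequal(res$funfams_final[[1]]$member_ids, c("a", "b"))
})

test_that("boundary laws: d_max infinite keeps one family, ceiling zero keeps leaves", {
  fx <- two_family_fixture()
  tr <- agglomerate(fx$hm)
  all_in <- cut_tree(tr, fx$clusters, fx$seqs,
                     cut_params(conservation_params(d_max = Inf)), id_scheme)
  expect_length(all_in$funfams, 1)
  expect_setequal(all_in$funfams[[1]]$member_ids, fx$seqs$seq_id)
  leaves_only <- cut_tree(tr, fx$clusters, fx$seqs,
                          cut_params(distance_ceiling = 0), id_scheme)
  expect_length(leaves_only$funfams, length(tr$leaves))
})

test_that("FunFam count is monotone non-increasing in d_max", {
  sm <- small_sim(seed = 5)
  cl <- greedy_cluster(sm$sim$seqs, scheme = id_scheme)
  hm <- build_half_matrix(funfamer:::rep_vectors(cl, sm$vec), "cosine")
  tr <- agglomerate(hm)
  counts <- vapply(c(0, 1, 2, 5, Inf), function(dm) {
    length(cut_tree(tr, cl, sm$sim$seqs,
                    cut_params(conservation_params(d_max = dm)),
                    id_scheme)$funfams)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1)
})

test_that("cut output is always a partition of the input", {
  sm <- small_sim(seed = 13)
  cl <- greedy_cluster(sm$sim$seqs, scheme = id_scheme)
  hm <- build_half_matrix(funfamer:::rep_vectors(cl, sm$vec), "cosine")
  res <- cut_tree(agglomerate(hm), cl, sm$sim$seqs, cut_params(), id_scheme)
  members <- unlist(lapply(res$funfams, `[[`, "member_ids"))
  expect_setequal(members, sm$sim$seqs$seq_id)
  expect_false(anyDuplicated(members) > 0)
  expect_gte(length(res$funfams), 1)
  expect_lte(length(res$funfams), length(cl))
})

test_that("cut report TSV round-trips", {
  fx <- two_family_fixture()
  res <- cut_tree(agglomerate(fx$hm), fx$clusters, fx$seqs, cut_params(),
                  id_scheme)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cut_report(res, f)
  d <- read.delim(f)
  expect_equal(nrow(d), 3)
  expect_equal(d$accepted, res$report$accepted)
})
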