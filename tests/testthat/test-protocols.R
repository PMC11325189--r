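id_scheme <- identity_scheme()
fast_cfg <- function(mode, ...) protocol_config(mode, ..., scheme = id_scheme)

test_that("MDA partitioning separates large architectures and pools the rest", {
  s <- domain_seqs(paste0("s", 1:12), rep("ACDEFGHIKL", 12),
                   mda = c(rep("1.10.10.10", 10), rep("2.20.20.20", 2)))
  p <- partition_by_mda(s, mda_min_size = 5)
  expect_setequal(names(p), c("1.10.10.10", "pooled"))
  expect_equal(nrow(p[["1.10.10.10"]]), 10)
  expect_equal(nrow(p[["pooled"]]), 2)
  # threshold above the total: everything pooled
  p2 <- partition_by_mda(s, mda_min_size = 100)
  expect_equal(names(p2), "pooled")
  # single shared MDA, threshold 1: one partition, no residual
  s3 <- domain_seqs(c("a", "b"), c("ACDE", "ACDF"), mda = "1.10.10.10")
  expect_equal(names(partition_by_mda(s3, 1)), "1.10.10.10")
  # disjoint cover
  expect_setequal(unlist(lapply(p, `[[`, "seq_id")), s$seq_id)
})

test_that("single-pass recovers planted families and records provenance", {
  sm <- small_sim(seed = 21)
  res <- run_single(sm$sim$seqs, sm$sim$annotations, sm$vec, fast_cfg("single"))
  part <- funfam_partition(res$funfams_final)
  expect_equal(adjusted_rand_index(part, sm$sim$truth$family_of[names(part)]), 1)
  expect_identical(res$funfams_iter1, res$funfams_final)
  expect_equal(res$provenance$metric, "cosine")
  expect_equal(res$provenance$d_max, 0)
  expect_equal(res$provenance$identity_threshold, 0.9)
})

test_that("missing representative vector fails loudly with the id", {
  sm <- small_sim(seed = 21)
  vec <- sm$vec[-1, ]
  missing_id <- setdiff(rownames(sm$vec), rownames(vec))
  cl <- greedy_cluster(sm$sim$seqs, scheme = id_scheme)
  if (missing_id %in% vapply(cl, `[[`, "", "representative_id")) {
    expect_error(run_single(sm$sim$seqs, sm$sim$annotations, vec,
                            fast_cfg("single")), missing_id)
  } else succeed()
})

test_that("MARC keeps architectures apart in iteration 1 and recovers families", {
  sm <- small_sim(seed = 31,
                  mda_assignment = c("1.10.10.10", "2.20.20.20", "2.20.20.20"))
  res <- run_marc(sm$sim$seqs, sm$sim$annotations, sm$vec, fast_cfg("marc"))
  # no iteration-1 FunFam mixes MDAs
  mda_of <- setNames(sm$sim$seqs$mda, sm$sim$seqs$seq_id)
  for (ff in res$funfams_iter1) {
    expect_length(unique(mda_of[ff$member_ids]), 1)
  }
  part <- funfam_partition(res$funfams_final)
  expect_gte(adjusted_rand_index(part, sm$sim$truth$family_of[names(part)]),
             0.95)
})

test_that("MARC with one shared MDA equals the single pass", {
  sm <- small_sim(seed = 8)
  r1 <- run_single(sm$sim$seqs, sm$sim$annotations, sm$vec, fast_cfg("single"))
  rm <- run_marc(sm$sim$seqs, sm$sim$annotations, sm$vec,
                 fast_cfg("marc", mda_min_size = 1))
  p1 <- funfam_partition(r1$funfams_final)
  pm <- funfam_partition(rm$funfams_final)
  expect_equal(adjusted_rand_index(p1, pm), 1)
})

test_that("a family split across small MDAs is reunited through the pool", {
  # families 1 and 2 both get rare MDAs below threshold -> residual set
  sm <- small_sim(seed = 55,
                  mda_assignment = c("1.10.10.10", "9.10.10.10", "8.10.10.10"))
  cfg <- fast_cfg("marc", mda_min_size = 10)
  res <- run_marc(sm$sim$seqs, sm$sim$annotations, sm$vec, cfg)
  part <- funfam_partition(res$funfams_final)
  expect_gte(adjusted_rand_index(part, sm$sim$truth$family_of[names(part)]),
             0.95)
})

test_that("FRAN: projects bounded, second iteration only merges, determinism", {
  sm <- small_sim(seed = 77)
  cfg <- fast_cfg("fran", fran_project_size = 2, seed = 5)
  res <- run_fran(sm$sim$seqs, sm$sim$annotations, sm$vec, cfg)
  expect_true(all(lengths(res$partitions) <= 2))
  expect_lte(length(res$funfams_final), length(res$funfams_iter1))
  res2 <- run_fran(sm$sim$seqs, sm$sim$annotations, sm$vec, cfg)
  expect_identical(res, res2)
  part <- funfam_partition(res$funfams_final)
  expect_setequal(names(part), sm$sim$seqs$seq_id)
})

test_that("FRAN with project size >= k reproduces the single-pass partition", {
  sm <- small_sim(seed = 4)
  r1 <- run_single(sm$sim$seqs, sm$sim$annotations, sm$vec, fast_cfg("single"))
  rf <- run_fran(sm$sim$seqs, sm$sim$annotations, sm$vec,
                 fast_cfg("fran", fran_project_size = 1000, seed = 3))
  p1 <- funfam_partition(r1$funfams_final)
  pf <- funfam_partition(rf$funfams_iter1)
  expect_equal(adjusted_rand_index(p1, pf), 1)
})

test_that("all protocols partition the same sequence universe", {
  sm <- small_sim(seed = 16)
  r1 <- run_single(sm$sim$seqs, sm$sim$annotations, sm$vec, fast_cfg("single"))
  rm <- run_marc(sm$sim$seqs, sm$sim$annotations, sm$vec, fast_cfg("marc"))
  rf <- run_fran(sm$sim$seqs, sm$sim$annotations, sm$vec,
                 fast_cfg("fran", fran_project_size = 3))
  u <- sm$sim$seqs$seq_id
  for (r in list(r1, rm, rf)) {
    expect_setequal(names(funfam_partition(r$funfams_final)), u)
  }
})

test_that("medoid representative minimizes summed distance", {
  vec <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  expect_equal(medoid_member(c("a", "b", "c"), vec, "euclidean"), "b")
  expect_equal(medoid_member("a", vec), "a")
  expect_error(medoid_member(c("a", "z"), vec, "euclidean"), "z")
})

test_that("protocol configuration loads from YAML", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("mode: fran", "fran_project_size: 7", "seed: 99",
               "metric: euclidean",
               "clustering:", "  identity_threshold: 0.85",
               "cut:", "  conservation:", "    d_max: 2"), f)
  cfg <- read_protocol_config(f)
  expect_equal(cfg$mode, "fran")
  expect_equal(cfg$fran_project_size, 7)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$clustering$identity_threshold, 0.85)
  expect_equal(cfg$cut$conservation$d_max, 2)
})
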