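test_that("scalar metrics match their closed forms", {
  expect_equal(cosine_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(manhattan_distance(c(1, 2), c(4, 6)), 7)
  expect_error(euclidean_distance(1, c(1, 2)), "dimension")
})

test_that("metric axioms hold on random vectors", {
  withr::with_seed(3, {
    for (i in 1:50) {
      u <- rnorm(5); v <- rnorm(5); w <- rnorm(5)
      for (f in list(euclidean_distance, manhattan_distance)) {
        expect_gte(f(u, v), 0)
        expect_equal(f(u, v), f(v, u))
        expect_equal(f(u, u), 0)
        expect_lte(f(u, w), f(u, v) + f(v, w) + 1e-12) # triangle inequality
      }
      expect_gte(manhattan_distance(u, v), euclidean_distance(u, v))
      expect_equal(cosine_distance(u, v), cosine_distance(v, u))
    }
  })
})

test_that("condensed index mapping is a bijection matching dist order", {
  n <- 7
  seen <- integer(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    seen <- c(seen, funfamer:::condensed_index(i, j, n))
  }
  expect_equal(sort(seen), seq_len(n * (n - 1) / 2))
  m <- matrix(rnorm(n * 3), n, dimnames = list(letters[1:n], NULL))
  hm <- build_half_matrix(m, "euclidean")
  d <- as.matrix(dist(m))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    expect_equal(hm_lookup(hm, letters[i], letters[j]), d[i, j])
    expect_equal(hm_lookup(hm, letters[j], letters[i]), d[i, j])
  }
  expect_equal(hm_lookup(hm, "a", "a"), 0)
})

test_that("half-matrix entries agree with scalar metric calls", {
  withr::with_seed(8, {
    m <- matrix(rnorm(12), 4, dimnames = list(c("a", "b", "c", "d"), NULL))
    for (metric in c("cosine", "euclidean", "manhattan")) {
      hm <- build_half_matrix(m, metric)
      f <- switch(metric, cosine = cosine_distance,
                  euclidean = euclidean_distance,
                  manhattan = manhattan_distance)
      for (i in 1:3) for (j in (i + 1):4) {
        expect_equal(hm_lookup(hm, rownames(m)[i], rownames(m)[j]),
                     f(m[i, ], m[j, ]), tolerance = 1e-12)
      }
    }
  })
  expect_error(build_half_matrix(matrix(1, 1, 1, dimnames = list("a", NULL))),
               "at least 2")
})

test_that("identical vectors give zero distance in the half-matrix", {
  m <- matrix(rep(c(1, 2, 3), 2), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(build_half_matrix(m, "cosine")$condensed, 0)
})

test_that("half-matrix disk round-trip preserves all values", {
  hm <- random_half_matrix(6, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_half_matrix(hm, f)
  hm2 <- read_half_matrix(f)
  expect_equal(hm2$ids, hm$ids)
  expect_equal(hm2$condensed, hm$condensed)
})

test_that("pairwise score tables convert to distances correctly", {
  # symmetric bitscores
  p <- data.frame(query = c("a", "b"), target = c("b", "a"),
                  bitscore = c(50, 50))
  hm <- score_to_distance(p, "inv_bitscore")
  expect_equal(hm_lookup(hm, "a", "b"), 0.02)
  # directed pair symmetrized by arithmetic mean of distances
  p2 <- data.frame(query = c("a", "b"), target = c("b", "a"),
                   bitscore = c(40, 60))
  expect_equal(hm_lookup(score_to_distance(p2, "inv_bitscore"), "a", "b"),
               (1 / 40 + 1 / 60) / 2)
  # rmsd passes through; zero allowed
  p3 <- data.frame(query = "a", target = "b", rmsd = 0)
  expect_equal(hm_lookup(score_to_distance(p3, "rmsd"), "a", "b"), 0)
  expect_error(score_to_distance(
    data.frame(query = "a", target = "b", bitscore = 0), "inv_bitscore"),
    "positive")
  expect_error(score_to_distance(p, "inv_bitscore", ids = c("a", "x")),
               "unknown id")
})

test_that("missing pairs are filled with 10x the largest observed distance", {
  p <- data.frame(query = c("a", "b"), target = c("b", "c"),
                  bitscore = c(50, 10))
  hm <- score_to_distance(p, "inv_bitscore", ids = c("a", "b", "c"))
  expect_equal(hm_lookup(hm, "b", "c"), 0.1)
  expect_equal(hm_lookup(hm, "a", "c"), 1.0) # 10 * 0.1
})

test_that("k-mer embedding produces normalized profiles with planted geometry", {
  s <- domain_seqs(c("a", "b", "c"), c("AAAA", "AAAA", "CCCC"))
  m <- kmer_embed(s, k = 1)
  expect_equal(unname(m["a", "A"]), 1)
  expect_equal(sum(m["a", ]), 1)
  expect_equal(cosine_distance(m["a", ], m["b", ]), 0)
  expect_equal(cosine_distance(m["a", ], m["c", ]), 1)
  expect_equal(ncol(kmer_embed(s, k = 2)), 400)
  expect_error(kmer_embed(s, k = 5), "1..3")
  expect_error(kmer_embed(domain_seqs("z", "AC"), k = 3), "shorter than k")
})

test_that("embedding TSV round-trips", {
  withr::with_seed(2, {
    m <- matrix(rnorm(8), 2, dimnames = list(c("a", "b"), NULL))
    f <- withr::local_tempfile(fileext = ".tsv")
    write_embeddings(m, f)
    m2 <- read_embeddings(f)
    expect_equal(m2, m, tolerance = 1e-12)
  })
})
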