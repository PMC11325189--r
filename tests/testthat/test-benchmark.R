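ann_of <- function(...) {
  # ann_of(s1 = "1.1.1.1", s2 = c("1.1.1.2", "2.7.11.1"))
  pairs <- list(...)
  annotation_table(ec = data.frame(
    seq_id = rep(names(pairs), lengths(pairs)),
    value = unlist(pairs, use.names = FALSE)))
}

test_that("EC purity follows the max-weight definition", {
  ids <- paste0("m", 1:10)
  ann <- do.call(ann_of, setNames(as.list(c(rep("1.1.1.1", 9), "2.7.11.1")), ids))
  ff <- funfam("f", ids)
  expect_equal(ec_purity(ff, ann, 4), 0.9)
  # EC3 truncation unifies sibling EC4s
  ann2 <- ann_of(a = "1.1.1.1", b = "1.1.1.2")
  ff2 <- funfam("f2", c("a", "b"))
  expect_equal(ec_purity(ff2, ann2, 4), 0.5)
  expect_equal(ec_purity(ff2, ann2, 3), 1.0)
})

test_that("wildcard ECs are excluded at the wildcard level only", {
  ann <- ann_of(a = "3.4.12.-")
  ff <- funfam("f", "a")
  expect_true(is.na(ec_purity(ff, ann, 4)))
  expect_equal(ec_purity(ff, ann, 3), 1.0)
})

test_that("multi-EC members are weighted fractionally", {
  # member b carries two ECs: each key gets weight 1/2
  ann <- ann_of(a = "1.1.1.1", b = c("1.1.1.1", "2.7.11.1"))
  ff <- funfam("f", c("a", "b"))
  expect_equal(ec_purity(ff, ann, 4), 1.5 / 2)
})

test_that("purity summary applies inclusive thresholds over defined purities", {
  ann <- ann_of(a = "1.1.1.1", b = "1.1.1.1",
                c = "1.1.1.1", d = "1.1.1.2", e = "1.1.1.2",          # 0.6? no
                f = "2.7.11.1")
  ffs <- list(funfam("p100", c("a", "b")),          # purity 1.0
              funfam("p50", c("c", "d")),           # purity 0.5
              funfam("undef", "zz"))                # undefined
  s <- purity_summary(ffs, ann)
  expect_equal(s$n_defined, 2)
  expect_equal(s$n_undefined, 1)
  expect_equal(s$prop_ge_80, 0.5)
  expect_equal(s$prop_eq_100, 0.5)
  expect_equal(s$mean_ec4, 0.75)
  # derived case {1.0, 0.85, 0.5}
  ann2 <- ann_of(a = "1.1.1.1", b = "1.1.1.1",
                 g1 = "4.1.1.1", g2 = "4.1.1.1", g3 = "4.1.1.1",
                 g4 = "4.1.1.1", g5 = "4.1.1.1", g6 = "4.1.1.1",
                 g7 = "5.1.1.1",
                 h1 = "6.1.1.1", h2 = "7.1.1.1")
  ffs2 <- list(funfam("x", c("a", "b")),
               funfam("y", paste0("g", 1:7)),
               funfam("z", c("h1", "h2")))
  s2 <- purity_summary(ffs2, ann2)
  expect_equal(s2$purities_ec4, c(1.0, 6 / 7, 0.5))
  expect_equal(s2$prop_ge_80, 2 / 3)
  expect_equal(s2$prop_ge_90, 1 / 3)
  expect_equal(s2$prop_eq_100, 1 / 3)
})

test_that("threshold proportions are monotone and EC3 >= EC4 on random sets", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 12
      ids <- sprintf("q%02d", 1:n)
      ecs <- sprintf("%d.%d.%d.%d", sample(2, n, TRUE), sample(2, n, TRUE),
                     sample(2, n, TRUE), sample(3, n, TRUE))
      ann <- annotation_table(ec = data.frame(seq_id = ids, value = ecs))
      split_at <- sort(sample(2:(n - 1), 2))
      ffs <- list(funfam("f1", ids[1:split_at[1]]),
                  funfam("f2", ids[(split_at[1] + 1):split_at[2]]),
                  funfam("f3", ids[(split_at[2] + 1):n]))
      s <- purity_summary(ffs, ann)
      expect_lte(s$prop_eq_100, s$prop_ge_90)
      expect_lte(s$prop_ge_90, s$prop_ge_80)
      for (ff in ffs) {
        expect_gte(ec_purity(ff, ann, 3), ec_purity(ff, ann, 4) - 1e-12)
      }
    }
  })
})

test_that("no EC anywhere yields undefined, never zero", {
  s <- purity_summary(list(funfam("f", "a")), annotation_table())
  expect_equal(s$n_defined, 0)
  expect_true(is.na(s$prop_ge_80))
  expect_true(is.na(s$mean_ec4))
})

test_that("adjusted Rand index matches pair counting and its axioms", {
  a <- c(x1 = "A", x2 = "A", x3 = "B", x4 = "B")
  expect_equal(adjusted_rand_index(a, a), 1)
  singletons <- setNames(paste0("s", 1:4), names(a))
  lump <- setNames(rep("L", 4), names(a))
  expect_equal(adjusted_rand_index(singletons, lump), 0)
  expect_equal(adjusted_rand_index(a, lump), adjusted_rand_index(lump, a))
  # relabeling invariance
  b <- setNames(c("Q", "Q", "R", "R"), names(a))
  expect_equal(adjusted_rand_index(a, b), 1)
  withr::with_seed(12, {
    for (i in 1:10) {
      u <- sample(3, 8, TRUE); v <- sample(3, 8, TRUE)
      expect_equal(adjusted_rand_index(u, v), oracle_ari(u, v),
                   tolerance = 1e-12)
    }
  })
  expect_error(adjusted_rand_index(a, setNames(1:3, c("x1", "x2", "zz"))),
               "universe")
})

test_that("DOPS summary rows and mean are consistent", {
  ffs <- list(
    funfam("f1", c("a", "b"), msa = alignment(c(a = "ACDE", b = "ACDE"))),
    funfam("f2", c("c", "d"), msa = alignment(c(c = "ACDE", d = "WYKR"))))
  ds <- dops_summary(ffs)
  expect_equal(nrow(ds$table), 2)
  expect_equal(ds$table$dops[1], 0)
  expect_equal(ds$mean_dops, mean(ds$table$dops))
})

test_that("benchmark report files are written with consistent values", {
  d <- withr::local_tempdir()
  ann <- ann_of(a = "1.1.1.1", b = "1.1.1.1")
  ffs <- list(funfam("f1", c("a", "b"),
                     msa = alignment(c(a = "ACDE", b = "ACDE"))))
  out <- write_benchmark_report(ffs, ann, d)
  expect_equal(out$n_funfams, 1)
  expect_equal(out$mean_ec4, 1)
  tab <- read.delim(file.path(d, "benchmark.tsv"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$dops, 0)
})
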