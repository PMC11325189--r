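# Independent oracles used to validate the implementation: exhaustive
# alignment enumeration, a naive rebuild-everything linkage oracle, and
# pair-counting ARI. These deliberately share no code with the package.

# Exhaustive global-alignment score: depth-first over every monotone path
# (diagonal / up / left), accumulating the score move by move. `last`
# tracks the previous move so affine gap openings are charged correctly.
oracle_align_score <- function(a, b, scheme) {
  S <- scheme$substitution
  open <- if (scheme$mode == "affine") scheme$gap_open + scheme$gap_extend
          else scheme$gap_extend
  ext <- scheme$gap_extend
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  rec <- function(i, j, acc, last) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < n && j < m) {
      rec(i + 1, j + 1, acc + S[ca[i + 1], cb[j + 1]], 0L)
    }
    if (i < n) rec(i + 1, j, acc - if (last == 1L) ext else open, 1L)
    if (j < m) rec(i, j + 1, acc - if (last == 2L) ext else open, 2L)
  }
  rec(0L, 0L, 0, 0L)
  best
}

# Naive agglomeration: after every merge, recompute every inter-cluster
# distance from the original leaf matrix and the full member sets.
oracle_agglomerate <- function(hm, linkage = "average") {
  n <- length(hm$ids)
  D0 <- as.matrix(funfamer::as_dist(hm))
  members <- setNames(as.list(hm$ids), hm$ids)
  cluster_dist <- function(A, B) {
    d <- D0[members[[A]], members[[B]], drop = FALSE]
    switch(linkage, average = mean(d), single = min(d), complete = max(d))
  }
  merges <- NULL
  for (step in seq_len(n - 1)) {
    ids <- names(members)
    best <- NULL
    for (x in seq_along(ids)) for (y in seq_along(ids)) {
      if (x >= y) next
      l <- min(ids[x], ids[y]); r <- max(ids[x], ids[y])
      d <- cluster_dist(ids[x], ids[y])
      if (is.null(best) || d < best$d ||
          (d == best$d && (l < best$l || (l == best$l && r < best$r)))) {
        best <- list(l = l, r = r, d = d)
      }
    }
    new_id <- paste0("N", step)
    merges <- rbind(merges,
                    data.frame(step = step, left = best$l, right = best$r,
                               new = new_id, height = best$d))
    members[[new_id]] <- c(members[[best$l]], members[[best$r]])
    members[[best$l]] <- NULL
    members[[best$r]] <- NULL
  }
  merges
}

# Pair-counting adjusted Rand index, straight from the contingency table.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  N <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / N
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

random_half_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("L%02d", seq_len(n))
    funfamer::half_matrix(ids, round(runif(n * (n - 1) / 2, 0.01, 1), 6))
  })
}

random_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small planted-family fixture shared across tests
small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(n_families = 3, seqs_per_family = 8, seq_length = 40,
                    n_sdp = 2, mutation_rate = 0.02, embed_dim = 8,
                    within_sd = 1, between_sd = 6, seed = seed, ...)
  sim <- generate_superfamily(cfg)
  list(cfg = cfg, sim = sim, vec = generate_embeddings(sim$truth, cfg))
}
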