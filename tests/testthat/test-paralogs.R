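test_that("pairwise identity handles the elementary cases", {
  expect_equal(pairwise_identity("MKVLITAG", "MKVLITAG"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_error(pairwise_identity("", "MKV"), "empty")
  # symmetry
  set.seed(1)
  for (i in 1:5) {
    a <- rand_prot(30); b <- rand_prot(25)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identity agrees with an exhaustive alignment-enumeration oracle", {
  cases <- list(c("MKVLIT", "MKVT"), c("MKWWA", "MKA"), c("ACDEF", "ACF"),
                c("MKVLH", "MKVLH"))
  for (cs in cases) {
    oracle <- align_enum_oracle(cs[1], cs[2])
    impl <- pairwise_identity(cs[1], cs[2])
    denom <- min(nchar(cs[1]), nchar(cs[2]))
    expect_true(impl %in% (oracle$identities / denom),
                label = paste(cs, collapse = " vs "))
  }
})

test_that("cluster_paralogs matches elementary expectations", {
  set.seed(2)
  s <- rand_prot(40)
  trio <- Biostrings::AAStringSet(c(a = s, b = s, c = s))
  cl <- cluster_paralogs(trio)
  expect_length(cl$clusters, 1L)
  expect_equal(cl$clusters[[1]], c("a", "b", "c"))

  pair <- Biostrings::AAStringSet(c(x = rand_prot(50), y = rand_prot(50)))
  cl2 <- cluster_paralogs(pair)
  expect_length(cl2$clusters, 2L)

  expect_error(cluster_paralogs(trio, threshold = 0), "threshold")
  expect_error(cluster_paralogs(trio, threshold = 1.2), "threshold")
})

test_that("single-linkage clustering equals the brute-force component oracle", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:8) {
    ps <- planted_protein_set(3, sample(2:5, 3, replace = TRUE),
                              n_singletons = sample(0:3, 1))
    m <- identity_matrix(ps$seqs)
    impl <- cluster_paralogs(m, 0.5)
    oracle <- single_linkage_oracle(m, 0.5)
    expect_equal(impl$clusters, oracle)
  }
})

test_that("clustering is invariant to input order and refines with threshold", {
  set.seed(4)
  ps <- planted_protein_set(3, c(4, 3, 2), n_singletons = 2)
  m <- identity_matrix(ps$seqs)
  base <- cluster_paralogs(m, 0.5)
  for (rep in 1:3) {
    perm <- sample(nrow(m))
    expect_equal(cluster_paralogs(m[perm, perm], 0.5)$clusters, base$clusters)
  }
  # refinement monotonicity: each cluster at a higher threshold is contained
  # in one cluster at the lower threshold
  for (t2 in c(0.7, 0.9)) {
    fine <- cluster_paralogs(m, t2)
    for (cl in fine$clusters) {
      holder <- vapply(base$clusters, function(b) all(cl %in% b), TRUE)
      expect_equal(sum(holder), 1L)
    }
  }
})

test_that("greedy representative mode yields a valid partition", {
  set.seed(5)
  ps <- planted_protein_set(2, c(3, 3), n_singletons = 1)
  cl <- cluster_paralogs(ps$seqs, 0.5, mode = "greedy")
  expect_setequal(unlist(cl$clusters), names(ps$seqs))
  expect_equal(anyDuplicated(unlist(cl$clusters)), 0L)
})

test_that("closest paralog reports the maximal off-diagonal identity", {
  set.seed(6)
  s <- rand_prot(45)
  seqs <- Biostrings::AAStringSet(c(a = s, b = s, c = rand_prot(45),
                                    d = rand_prot(45), e = rand_prot(45)))
  m <- identity_matrix(seqs)
  cp <- closest_paralog_identity(m, "a")
  expect_equal(cp$closest_id, "b")
  expect_equal(cp$identity, 1.0)
  expect_equal(closest_paralog_identity(m, "b")$closest_id, "a")

  m1 <- identity_matrix(seqs[1])
  cp1 <- closest_paralog_identity(m1, "a")
  expect_true(is.na(cp1$closest_id))
  expect_equal(cp1$identity, 0)

  all_rows <- closest_paralog_identity(m)
  expect_equal(nrow(all_rows), 5L)
})

test_that("near-identical fraction tracks the generator's planted fraction", {
  sim <- simulate_genome(small_sim_config(seed = 8, divergence = 0.08))
  m <- identity_matrix(Biostrings::AAStringSet(sim$proteins))
  cp <- closest_paralog_identity(m)
  n_hi <- sum(cp$identity > 0.95)
  # a gene has a >95%-identical closest paralog iff it was planted as (or is
  # the source of) a zero-divergence copy: 8% per-copy cds divergence drops
  # protein identity well below 95%
  tr <- sim$truth
  twins <- tr$gene_id[tr$copy_divergence == 0 & !is.na(tr$parent_id)]
  planted <- length(unique(c(twins, tr$parent_id[tr$gene_id %in% twins])))
  expect_lte(abs(n_hi - planted), 1)
})

test_that("large_clusters selects by minimum size", {
  cl <- structure(list(threshold = 0.5, mode = "single",
                       clusters = list(sprintf("a%02d", 1:12),
                                       sprintf("b%02d", 1:9),
                                       sprintf("c%02d", 1:3)),
                       membership = NULL), class = "paralog_clusters")
  expect_length(large_clusters(cl, 10), 1L)
  expect_length(large_clusters(cl, 1), 3L)
})
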