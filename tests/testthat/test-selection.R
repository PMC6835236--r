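test_that("back-translation replaces residues by codons and checks consistency", {
  aln <- c(s1 = "M-K", s2 = "MAK")
  cds <- c(s1 = "ATGAAA", s2 = "ATGGCTAAA")
  ca <- backtranslate_alignment(aln, cds)
  expect_equal(unname(ca$codons["s1", ]), c("ATG", "---", "AAA"))
  expect_equal(unname(ca$codons["s2", ]), c("ATG", "GCT", "AAA"))
  # terminal stop on the CDS is tolerated
  ca2 <- backtranslate_alignment(aln, c(s1 = "ATGAAATAA", s2 = "ATGGCTAAA"))
  expect_equal(unname(ca2$codons["s1", ]), c("ATG", "---", "AAA"))
  # mismatching CDS reported at the first discordant codon
  expect_error(backtranslate_alignment(aln, c(s1 = "ATGCCC", s2 = "ATGGCTAAA")),
               "codon 2")
  expect_error(backtranslate_alignment(aln, c(s1 = "ATGAAAAAA", s2 = "ATGGCTAAA")),
               "length")
  # round trip: stripping gaps and translating reproduces the proteins
  for (id in rownames(ca$codons)) {
    cods <- ca$codons[id, ]
    cods <- cods[cods != "---"]
    expect_equal(paste(Biostrings::GENETIC_CODE[cods], collapse = ""),
                 gsub("-", "", aln[[id]]))
  }
})

test_that("trimming drops gapped columns and keeps a provenance map", {
  m <- rbind(s1 = c("ATG", "AAA", "CCC", "GGG"),
             s2 = c("ATG", "---", "CCC", "GGT"))
  ca <- codon_alignment(m)
  tr <- trim_alignment(ca)
  expect_equal(ncol(tr$codons), 3L)
  expect_equal(tr$provenance, c(1L, 3L, 4L))
  expect_true(all(diff(tr$provenance) > 0))
  # region restriction
  tr2 <- trim_alignment(ca, region = c(3, 4))
  expect_equal(tr2$provenance, c(3L, 4L))
  expect_error(trim_alignment(codon_alignment(
    rbind(s1 = c("---", "AAA"), s2 = c("ATG", "---"))), NULL),
    "no analyzable sites")
})

test_that("neighbor joining solves the three-point case and recovers additive trees", {
  d3 <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  expect_equal(ape::Ntip(tr3), 3L)
  # branch lengths solve the three-point equations: a=1, b=3, c=5
  bl <- stats::setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 3, c = 5))

  # additive 4-taxon matrix from tree ((a:1,b:2):1,(c:3,d:1)); the check is
  # by enumeration of the three possible unrooted topologies
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 3
  d4["a", "c"] <- d4["c", "a"] <- 5
  d4["a", "d"] <- d4["d", "a"] <- 3
  d4["b", "c"] <- d4["c", "b"] <- 6
  d4["b", "d"] <- d4["d", "b"] <- 4
  d4["c", "d"] <- d4["d", "c"] <- 4
  tr4 <- nj_tree(d4)
  split_ab <- ape::prop.part(ape::unroot(tr4))
  # the a|b vs c|d bipartition must be present
  tips <- tr4$tip.label
  bip <- vapply(split_ab, function(p) {
    s <- sort(tips[p])
    identical(s, c("a", "b")) || identical(s, c("c", "d"))
  }, TRUE)
  expect_true(any(bip))

  expect_warning(nj_tree(matrix(c(0, 2, 2, 0), 2,
                                dimnames = list(c("x", "y"), c("x", "y")))),
                 "trivial")
})

test_that("Fitch ancestral codons match forced cases and the enumeration oracle", {
  # all-identical column
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  ca <- codon_alignment(rbind(t1 = "ATG", t2 = "ATG", t3 = "ATG"))
  anc <- ancestral_codons(tr, ca)
  expect_true(all(anc$states == "ATG"))
  expect_equal(anc$score, 0L)

  # cherry AAA/AAG with outgroup AAA: root forced to AAA
  ca2 <- codon_alignment(rbind(t1 = "AAA", t2 = "AAG", t3 = "AAA"))
  anc2 <- ancestral_codons(tr, ca2)
  root_state <- anc2$states[length(tr$tip.label) + 1L, 1]
  expect_equal(root_state, "AAA")
  expect_equal(anc2$score, 1L)

  # random small columns: parsimony score equals brute-force minimum
  set.seed(7)
  tr5 <- ape::rtree(5)
  codons <- c("AAA", "AAG", "ACA", "ATA")
  for (rep in 1:5) {
    col <- sample(codons, 5, replace = TRUE)
    names(col) <- tr5$tip.label
    ca5 <- codon_alignment(matrix(col, ncol = 1,
                                  dimnames = list(tr5$tip.label, NULL)))
    anc5 <- ancestral_codons(tr5, ca5)
    expect_equal(anc5$score, parsimony_enum_oracle(tr5, col))
  }
})

test_that("potential synonymous sites follow from single-mutant enumeration", {
  # TTT: only the third-position change to TTC is synonymous
  s <- codon_syn_sites("TTT")
  expect_equal(s$per_position, c(0, 0, 1 / 3))
  expect_equal(s$syn_sites, 1 / 3)
  # third positions of 4-fold degenerate codons are fully synonymous
  expect_equal(codon_syn_sites("GGG")$per_position[3], 1)
  expect_error(codon_syn_sites("TAA"), "sense")
})

test_that("codon path counting splits synonymous and nonsynonymous steps", {
  expect_equal(count_codon_path("AAA", "AAG"), c(syn = 1, nonsyn = 0))
  expect_equal(count_codon_path("AAA", "AGA"), c(syn = 0, nonsyn = 1))
  expect_equal(count_codon_path("ATG", "ATG"), c(syn = 0, nonsyn = 0))
  # two-step difference: counts sum to the nucleotide difference
  p <- count_codon_path("TTT", "TTA")
  expect_equal(sum(p), 1)
  p2 <- count_codon_path("AAA", "AGG")
  expect_equal(sum(p2), 2)
  # Trp TGG -> Tyr TAC: the path through the TAG stop codon is excluded,
  # leaving only the TGC route (two nonsynonymous steps)
  p3 <- count_codon_path("TGG", "TAC")
  expect_equal(p3, c(syn = 0, nonsyn = 2))
})

test_that("site counts conserve the per-branch nucleotide changes", {
  sim <- simulate_selection_alignment(8, 30, 0.4, seed = 21)
  anc <- ancestral_codons(sim$tree, sim$alignment)
  calls <- site_selection(sim$tree, sim$alignment)
  # per site, syn + nonsyn equals the summed nucleotide difference between
  # parent and child states over all edges
  edge <- anc$tree$edge
  for (s in seq_len(ncol(sim$alignment$codons))) {
    nt_changes <- sum(vapply(seq_len(nrow(edge)), function(e) {
      a <- anc$states[edge[e, 1], s]; b <- anc$states[edge[e, 2], s]
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, 0))
    expect_equal(calls$observed_syn[s] + calls$observed_nonsyn[s], nt_changes,
                 tolerance = 1e-9)
  }
  # invariant sites are neutral with p = 1
  inv <- which(apply(sim$alignment$codons, 2,
                     function(x) length(unique(x)) == 1L))
  if (length(inv)) {
    expect_true(all(calls$selection_class[inv] == "NEUTRAL"))
    expect_true(all(calls$p_value[inv] == 1))
  }
})

test_that("parsimony score is bounded by distinct codon count", {
  sim <- simulate_selection_alignment(10, 40, 0.6, seed = 22)
  anc <- ancestral_codons(sim$tree, sim$alignment)
  n_distinct <- apply(sim$alignment$codons, 2, function(x) length(unique(x)))
  expect_true(all(anc$score <= (n_distinct - 1L) * 3L))
  expect_true(all(anc$score >= n_distinct - 1L))
})

test_that("consensus support follows the two-method rule", {
  methods <- list(counting = c(3L, 7L), fel = c(7L, 9L), meme = integer(0))
  sup <- consensus_support(methods, 10)
  expect_equal(sup[7], "STRONG")
  expect_equal(sup[3], "MODERATE")
  expect_equal(sup[9], "MODERATE")
  expect_equal(sup[1], "NONE")
  expect_equal(consensus_support(list(a = integer(), b = integer()), 5),
               rep("NONE", 5))
  expect_error(consensus_support(list(a = 11L), 10), "outside")
  # round trip through the external-list reader
  path <- tempfile(fileext = ".tsv")
  writeLines(c("method\tsite_index", "fel\t7", "fel\t9", "slac\t7"), path)
  ml <- read_method_sites(path)
  expect_equal(ml$fel, c(7L, 9L))
  expect_equal(consensus_support(ml, 10)[7], "STRONG")
})
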