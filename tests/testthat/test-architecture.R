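# feature bundles for each canonical architecture, built in code
arch_fixture <- function(case) {
  dom <- function(name, s, e)
    data.frame(protein_id = "p", domain_name = name, ali_start = s,
               ali_end = e, e_value = 1e-10, model_coverage = 0.95)
  sp <- data.frame(protein_id = "p", feature_type = "signal_peptide",
                   start = 1, end = 20, score = 0.99)
  coil <- function(s, e, pr)
    data.frame(protein_id = "p", feature_type = "coiled_coil",
               start = s, end = e, score = pr)
  switch(case,
    sgh = protein_features("p", 200, sp, dom("C1q", 35, 180)),
    type2 = protein_features("p", 260, rbind(sp, coil(40, 90, 0.9)),
                             dom("C1q", 110, 240)),
    smulti = protein_features("p", 450, sp,
                              rbind(dom("C1q", 30, 150), dom("C1q", 160, 280),
                                    dom("C1q", 300, 420))),
    no_signal = protein_features("p", 200, NULL, dom("C1q", 40, 180)),
    suel = protein_features("p", 300, sp,
                            rbind(dom("SUEL_lectin", 25, 120),
                                  dom("C1q", 140, 270))),
    collagen = protein_features("p", 300, sp,
                                rbind(dom("Collagen", 30, 100),
                                      dom("C1q", 140, 270))),
    tm = protein_features("p", 220,
                          rbind(sp, data.frame(protein_id = "p",
                                               feature_type = "transmembrane",
                                               start = 180, end = 205,
                                               score = 1)),
                          dom("C1q", 35, 170)),
    weak_coil = protein_features("p", 260, rbind(sp, coil(40, 90, 0.3)),
                                 dom("C1q", 110, 240)))
}

test_that("the architecture cascade assigns each canonical layout correctly", {
  cases <- list(sgh = "SGH_C1Q", type2 = "C1Q_LIKE_TYPE_II",
                smulti = "SMULTI_C1Q", no_signal = "OTHER_UNCERTAIN",
                suel = "SSUEL_C1Q", collagen = "C1Q_LIKE_TYPE_I",
                tm = "OTHER_UNCERTAIN",
                # coil below probability threshold, domain far from cleavage
                weak_coil = "OTHER_UNCERTAIN")
  for (nm in names(cases)) {
    call <- classify_architecture(arch_fixture(nm))
    expect_equal(call$category, cases[[nm]], label = nm)
  }
  expect_equal(classify_architecture(arch_fixture("smulti"))$n_c1q_domains, 3L)
})

test_that("a protein without a C1q hit is rejected as non-family", {
  pf <- protein_features("p", 200,
                         data.frame(protein_id = "p",
                                    feature_type = "signal_peptide",
                                    start = 1, end = 20, score = 0.99),
                         NULL)
  expect_error(classify_architecture(pf), "not a family member")
})

test_that("classification is deterministic and order-independent", {
  feats <- lapply(c("sgh", "type2", "suel", "smulti", "no_signal"), arch_fixture)
  calls <- classify_architectures(feats)
  for (perm in list(5:1, c(3, 1, 5, 2, 4))) {
    calls2 <- classify_architectures(feats[perm])
    expect_equal(calls2$category[order(perm)], calls$category)
  }
})

test_that("summarize_architectures balances totals and flags unmapped ids", {
  gene_tab <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chromosome_id = c("chr1", "chr1", "chr2"),
    start = c(1L, 100L, 1L), end = c(50L, 150L, 60L),
    strand = "+", is_family = TRUE)
  calls <- data.frame(protein_id = c("g1", "g2", "g3"),
                      category = c("SGH_C1Q", "SGH_C1Q", "C1Q_LIKE_TYPE_II"),
                      n_c1q_domains = 1L)
  m <- summarize_architectures(calls, gene_tab)
  expect_equal(m["SGH_C1Q", "chr1"], 2L)
  expect_equal(m["C1Q_LIKE_TYPE_II", "chr2"], 1L)
  expect_equal(m["Total", "Total"], 3L)
  expect_equal(sum(m[setdiff(rownames(m), "Total"), "Total"]), m["Total", "Total"])
  expect_equal(sum(m["Total", setdiff(colnames(m), "Total")]), m["Total", "Total"])

  # empty input: all-zero matrix
  m0 <- summarize_architectures(calls[0, ], gene_tab)
  expect_true(all(m0 == 0))

  calls$protein_id[2] <- "missing"
  expect_error(summarize_architectures(calls, gene_tab), "missing")
})

test_that("planted architecture categories are recovered exactly from a simulation", {
  sim <- simulate_genome(small_sim_config(seed = 3))
  fam_ids <- sim$truth$gene_id
  feats <- lapply(fam_ids, function(id)
    protein_features(id, nchar(sim$proteins[[id]]), sim$features, sim$domains))
  calls <- classify_architectures(feats)
  expect_equal(calls$category, sim$truth$category)
  m <- summarize_architectures(calls, sim$genes)
  truth_tab <- table(factor(sim$truth$category, levels = ARCHITECTURE_CATEGORIES))
  expect_equal(unname(m[names(truth_tab), "Total"]), as.integer(truth_tab))
})
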