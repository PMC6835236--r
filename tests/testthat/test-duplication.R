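# minimal hand-built genome: helper to make a gene table + cluster set
make_genome <- function(genes, clusters) {
  tab <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g[[1]], chromosome_id = g[[2]],
               start = as.integer(g[[3]]), end = as.integer(g[[4]]),
               strand = "+", is_family = isTRUE(g[[5]]))))
  tab <- sort_gene_table(tab)
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, `[`, "", 1L))
  clusters <- clusters[ord]
  membership <- integer(0)
  for (k in seq_along(clusters)) {
    m <- stats::setNames(rep(k, length(clusters[[k]])), clusters[[k]])
    membership <- c(membership, m)
  }
  cs <- structure(list(threshold = 0.5, mode = "single",
                       clusters = unname(clusters), membership = membership),
                  class = "paralog_clusters")
  list(tab = tab, cs = cs)
}

test_that("intergenic distance is the gap between nearer boundaries", {
  g <- function(chrom, s, e) list(chromosome_id = chrom, start = s, end = e)
  expect_equal(intergenic_distance(g("c", 100, 200), g("c", 301, 400)), 100L)
  expect_equal(intergenic_distance(g("c", 100, 300), g("c", 250, 400)), 0L)
  expect_equal(intergenic_distance(g("c", 100, 200), g("c", 201, 300)), 0L)
  # symmetric in argument order
  expect_equal(intergenic_distance(g("c", 301, 400), g("c", 100, 200)), 100L)
  expect_error(intergenic_distance(g("c1", 1, 10), g("c2", 1, 10)),
               "different chromosomes")
})

test_that("adjacent same-cluster paralogs are tandem", {
  gm <- make_genome(
    list(list("F1", "chr1", 1000, 2000, TRUE),
         list("F2", "chr1", 5000, 6000, TRUE)),
    list(c("F1", "F2")))
  calls <- classify_duplications(gm$tab, gm$cs)
  expect_equal(calls$mode, c("TANDEM", "TANDEM"))
  expect_equal(calls$nearest_paralog_id, c("F2", "F1"))
  expect_equal(calls$nearest_paralog_distance, c(2999L, 2999L))
})

test_that("an intervening gene with a close paralog gives proximal", {
  gm <- make_genome(
    list(list("F1", "chr1", 1000, 2000, TRUE),
         list("B", "chr1", 8000, 9000, FALSE),
         list("F2", "chr1", 22001, 23000, TRUE)),
    list(c("F1", "F2")))
  calls <- classify_duplications(gm$tab, gm$cs)
  expect_equal(calls$mode[calls$gene_id == "F1"], "PROXIMAL")
  expect_equal(calls$mode[calls$gene_id == "F2"], "PROXIMAL")
  expect_equal(calls$nearest_paralog_distance[calls$gene_id == "F1"], 20000L)
})

test_that("distant or trans-chromosomal paralogs are dispersed", {
  # same chromosome, gap over the limit, intervening background gene
  gm <- make_genome(
    list(list("F1", "chr1", 1000, 2000, TRUE),
         list("B", "chr1", 50000, 51000, FALSE),
         list("F2", "chr1", 152001, 153000, TRUE)),
    list(c("F1", "F2")))
  calls <- classify_duplications(gm$tab, gm$cs)
  expect_equal(calls$mode, c("DISPERSED", "DISPERSED"))
  expect_equal(calls$nearest_paralog_distance[1], 150000L)
  # exactly at the limit: proximal (inclusive threshold)
  gm2 <- make_genome(
    list(list("F1", "chr1", 1000, 2000, TRUE),
         list("B", "chr1", 50000, 51000, FALSE),
         list("F2", "chr1", 102001, 103000, TRUE)),
    list(c("F1", "F2")))
  expect_equal(classify_duplications(gm2$tab, gm2$cs)$mode,
               c("PROXIMAL", "PROXIMAL"))
  # different chromosomes only
  gm3 <- make_genome(
    list(list("F1", "chr1", 1000, 2000, TRUE),
         list("F2", "chr2", 1000, 2000, TRUE)),
    list(c("F1", "F2")))
  calls3 <- classify_duplications(gm3$tab, gm3$cs)
  expect_equal(calls3$mode, c("DISPERSED", "DISPERSED"))
  expect_true(all(is.na(calls3$nearest_paralog_distance)))
})

test_that("singletons and cross-cluster neighbors are handled", {
  # F1/F2 adjacent but in different clusters: not tandem
  gm <- make_genome(
    list(list("F1", "chr1", 1000, 2000, TRUE),
         list("F2", "chr1", 5000, 6000, TRUE),
         list("F3", "chr1", 500000, 501000, TRUE)),
    list(c("F1", "F3"), "F2"))
  calls <- classify_duplications(gm$tab, gm$cs)
  expect_equal(calls$mode[calls$gene_id == "F2"], "SINGLETON")
  expect_equal(calls$mode[calls$gene_id == "F1"], "DISPERSED")
})

test_that("tandem calls are invariant under coordinate mirror reversal", {
  sim <- simulate_genome(small_sim_config(seed = 5))
  m <- identity_matrix(Biostrings::AAStringSet(sim$proteins))
  cs <- cluster_paralogs(m, 0.5)
  fwd <- classify_duplications(sim$genes, cs)
  # mirror every chromosome
  rev_tab <- sim$genes
  for (ch in names(sim$chromosome_lengths)) {
    L <- sim$chromosome_lengths[[ch]]
    sel <- rev_tab$chromosome_id == ch
    s <- rev_tab$start[sel]; e <- rev_tab$end[sel]
    rev_tab$start[sel] <- as.integer(L - e + 1)
    rev_tab$end[sel] <- as.integer(L - s + 1)
  }
  bwd <- classify_duplications(sort_gene_table(rev_tab), cs)
  fwd_modes <- stats::setNames(fwd$mode, fwd$gene_id)
  bwd_modes <- stats::setNames(bwd$mode, bwd$gene_id)
  expect_equal(bwd_modes[names(fwd_modes)], fwd_modes)
})

test_that("modes partition the family and the summary balances", {
  sim <- simulate_genome(small_sim_config(seed = 6))
  m <- identity_matrix(Biostrings::AAStringSet(sim$proteins))
  cs <- cluster_paralogs(m, 0.5)
  calls <- classify_duplications(sim$genes, cs)
  expect_equal(nrow(calls), sum(sim$genes$is_family))
  expect_true(all(calls$mode %in% DUPLICATION_MODES))
  summ <- summarize_duplication(calls, sim$genes)
  expect_equal(sum(summ$totals), nrow(calls))
  expect_equal(unname(colSums(summ$per_chromosome)),
               unname(table(factor(
                 sim$genes$chromosome_id[sim$genes$is_family],
                 levels = colnames(summ$per_chromosome)))[
                   colnames(summ$per_chromosome)]),
               ignore_attr = TRUE)
})

test_that("genome-wide mode fractions use two-decimal half-away rounding", {
  tab <- data.frame(gene_id = sprintf("F%03d", 1:476),
                    chromosome_id = "chr1",
                    start = seq(1, by = 1000, length.out = 476),
                    end = seq(500, by = 1000, length.out = 476),
                    strand = "+", is_family = TRUE)
  calls <- data.frame(gene_id = tab$gene_id,
                      mode = rep(c("TANDEM", "PROXIMAL", "DISPERSED"),
                                 c(297, 84, 95)),
                      nearest_paralog_id = NA, nearest_paralog_distance = NA)
  summ <- summarize_duplication(calls, tab)
  expect_equal(unname(summ$fractions_pct[c("TANDEM", "PROXIMAL", "DISPERSED")]),
               c(62.39, 17.65, 19.96))
  # all singleton: no duplication fractions
  calls$mode <- "SINGLETON"
  s0 <- summarize_duplication(calls, tab)
  expect_equal(unname(s0$fractions_pct[c("TANDEM", "PROXIMAL", "DISPERSED")]),
               c(0, 0, 0))
})
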