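#' Configuration for the synthetic genome simulator
#'
#' Bundles all tunable parameters of [simulate_genome()]. The defaults
#' describe a compact three-chromosome genome carrying a focal secreted
#' lectin-like gene family expanded by tandem arrays, with a smaller
#' number of proximal and dispersed copies, against a background of
#' unrelated genes.
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Lengths in bp (recycled to `n_chromosomes`).
#' @param n_background_genes Total non-family genes (some are consumed as
#'   spacers between family units, the rest scattered).
#' @param n_tandem_arrays Number of tandem arrays, each grown from an
#'   independent template protein (one array = one paralog cluster).
#' @param array_size_range Inclusive range of copies per array.
#' @param n_proximal Number of proximal copies (each attached to an array
#'   with 1-3 intervening background genes, within 100 kb).
#' @param n_dispersed Number of dispersed copies (placed far from, and
#'   never gene-order-adjacent to, any same-cluster paralog).
#' @param divergence Expected substitutions per CDS site applied to each
#'   successive copy (transition:transversion 2:1; stop codons forbidden).
#' @param near_identical_fraction Fraction of copies created with zero
#'   divergence, emulating very recent duplication events.
#' @param intron_rate_multiplier Relative substitution rate of the single
#'   intron (default 3, echoing the relaxed constraint on non-coding
#'   sequence); introns also suffer occasional short indels.
#' @param tandem_gap_range Intergenic gap between adjacent array copies,
#'   bp.
#' @param category_weights Named sampling weights over
#'   [ARCHITECTURE_CATEGORIES] for array templates.
#' @param feature_noise Fraction of family proteins whose emitted
#'   signal-peptide flag is flipped (default 0; truth is then exact).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42,
                              n_chromosomes = 3,
                              chromosome_lengths = 2e7,
                              n_background_genes = 300,
                              n_tandem_arrays = 12,
                              array_size_range = c(3, 15),
                              n_proximal = 20,
                              n_dispersed = 15,
                              divergence = 0.05,
                              near_identical_fraction = 0.15,
                              intron_rate_multiplier = 3,
                              tandem_gap_range = c(1e3, 1e4),
                              category_weights = c(SGH_C1Q = 0.25,
                                                   C1Q_LIKE_TYPE_II = 0.50,
                                                   SMULTI_C1Q = 0.10,
                                                   SSUEL_C1Q = 0.10,
                                                   OTHER_UNCERTAIN = 0.05),
                              feature_noise = 0) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chromosome_lengths = rep_len(chromosome_lengths, n_chromosomes),
              n_background_genes = n_background_genes,
              n_tandem_arrays = n_tandem_arrays,
              array_size_range = array_size_range,
              n_proximal = n_proximal, n_dispersed = n_dispersed,
              divergence = divergence,
              near_identical_fraction = near_identical_fraction,
              intron_rate_multiplier = intron_rate_multiplier,
              tandem_gap_range = tandem_gap_range,
              category_weights = category_weights,
              feature_noise = feature_noise)
  stopifnot(cfg$n_chromosomes >= 1, cfg$n_tandem_arrays >= 1,
            all(cfg$array_size_range >= 2), cfg$divergence >= 0,
            cfg$near_identical_fraction >= 0, cfg$near_identical_fraction <= 1,
            cfg$n_proximal >= 0, cfg$n_dispersed >= 0,
            all(cfg$tandem_gap_range > 0))
  structure(cfg, class = "simulation_config")
}

.NTS <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# random CDS encoding a given protein (uniform synonymous codon choice)
.encode_protein <- function(aa) {
  gc <- .genetic_code()
  vapply(aa, function(a) {
    cands <- names(gc)[gc == a]
    cands[sample.int(length(cands), 1L)]
  }, "")
}

.random_protein <- function(len) {
  aas <- setdiff(unique(unname(.genetic_code())), "*")
  c("M", sample(aas, len - 1L, replace = TRUE))
}

# mutate a codon vector at per-site rate, ts:tv 2:1, never creating stops
.mutate_cds <- function(codons, rate) {
  if (rate <= 0) return(codons)
  nt <- strsplit(paste(codons, collapse = ""), "")[[1]]
  L <- length(nt)
  hit <- which(stats::runif(L) < rate)
  for (p in hit) {
    old <- nt[p]
    new <- if (stats::runif(1) < 0.5) .TRANSITION[[old]]
           else sample(setdiff(.NTS, c(old, .TRANSITION[[old]])), 1L)
    ci <- (p - 1L) %/% 3L + 1L
    cod <- codons[ci]
    within <- p - (ci - 1L) * 3L
    newcod <- cod
    substr(newcod, within, within) <- new
    if (!.is_stop(newcod)) {
      codons[ci] <- newcod
      nt[p] <- new
    }
  }
  codons
}

.mutate_intron <- function(intron, rate) {
  nt <- strsplit(intron, "")[[1]]
  hit <- which(stats::runif(length(nt)) < rate)
  for (p in hit) {
    old <- nt[p]
    nt[p] <- if (stats::runif(1) < 0.5) .TRANSITION[[old]]
             else sample(setdiff(.NTS, c(old, .TRANSITION[[old]])), 1L)
  }
  # occasional microsatellite-like short indel
  if (stats::runif(1) < 0.3 && length(nt) > 30L) {
    k <- sample(1:10, 1L)
    at <- sample(seq_len(length(nt) - k), 1L)
    if (stats::runif(1) < 0.5) nt <- nt[-(at:(at + k - 1L))]
    else nt <- append(nt, nt[at:(at + k - 1L)], after = at)
  }
  paste(nt, collapse = "")
}

# architecture templates: protein length + feature/domain layout per category
.template_layout <- function(category) {
  switch(category,
    SGH_C1Q = list(len = 180, signal = 20, coil = NULL,
                   domains = list(c1q = c(30, 165))),
    C1Q_LIKE_TYPE_II = list(len = 250, signal = 20, coil = c(40, 90),
                            domains = list(c1q = c(120, 245))),
    SMULTI_C1Q = list(len = 400, signal = 20, coil = NULL,
                      domains = list(c1q = c(30, 150), c1q = c(160, 280),
                                     c1q = c(290, 395))),
    SSUEL_C1Q = list(len = 280, signal = 20, coil = NULL,
                     domains = list(suel = c(30, 130), c1q = c(150, 275))),
    OTHER_UNCERTAIN = list(len = 200, signal = NULL, coil = NULL,
                           domains = list(c1q = c(40, 175))),
    .err("no template for category ", category))
}

#' Simulate a genome annotation with a planted duplication history
#'
#' Generates a multi-chromosome gene annotation containing a focal gene
#' family expanded by tandem arrays, proximal copies and dispersed copies,
#' with per-copy sequence divergence, plus the unrelated background genes
#' the duplication classifier must see. Each tandem array grows from an
#' independent random template protein by iterated adjacent copy-insertion
#' (gaps 1-10 kb); proximal copies attach to an array behind 1-3 background
#' genes within 100 kb; dispersed copies are placed with more than 100 kb
#' of intergenic distance to any same-cluster paralog and never
#' gene-order-adjacent to one. Every family protein carries the feature
#' and domain-hit annotations of its array's architecture template. Genes
#' have a single intron evolving at an elevated rate with occasional short
#' indels, so exon/intron divergence contrasts can be examined.
#'
#' @param config A [simulation_config()].
#' @return A list of class `genome_simulation` with elements `genes`
#'   (gene table), `proteins` / `cds` (named character vectors, family
#'   genes only), `features` / `domains` (annotation tables), `truth`
#'   (`data.frame`: `gene_id`, `cluster_id`, `mode`, `category`,
#'   `parent_id`, `copy_divergence` -- the copy's source gene and the
#'   divergence applied when it was created),
#'   `chromosome_lengths` and `config`. Deterministic given
#'   `config$seed`.
#' @seealso [write_simulation()] to emit the standard file formats.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_arr <- config$n_tandem_arrays
  n_chrom <- config$n_chromosomes
  chrom_ids <- sprintf("chr%d", seq_len(n_chrom))

  # --- templates, one per array -------------------------------------------
  categories <- sample(names(config$category_weights), n_arr, replace = TRUE,
                       prob = config$category_weights)
  templates <- lapply(categories, function(cat) {
    lay <- .template_layout(cat)
    aa <- .random_protein(lay$len)
    list(category = cat, layout = lay, codons = .encode_protein(aa),
         intron = paste(sample(.NTS, sample(200:800, 1L), replace = TRUE),
                        collapse = ""))
  })

  # --- plan events ---------------------------------------------------------
  size_vals <- seq(config$array_size_range[1], config$array_size_range[2])
  array_sizes <- size_vals[sample.int(length(size_vals), n_arr, replace = TRUE)]
  array_chrom <- ((seq_len(n_arr) - 1L) %% n_chrom) + 1L
  prox_of_array <- if (config$n_proximal > 0)
    ((seq_len(config$n_proximal) - 1L) %% n_arr) + 1L else integer(0)
  disp_of_array <- if (config$n_dispersed > 0)
    ((seq_len(config$n_dispersed) - 1L) %% n_arr) + 1L else integer(0)
  disp_chrom <- vapply(disp_of_array, function(a) {
    if (n_chrom == 1L) return(1L)
    others <- setdiff(seq_len(n_chrom), array_chrom[a])
    others[sample.int(length(others), 1L)]
  }, 0L)

  # --- grow sequences ------------------------------------------------------
  div <- config$divergence
  copy_of <- function(parent, parent_id) {
    d <- if (stats::runif(1) < config$near_identical_fraction) 0 else div
    list(codons = .mutate_cds(parent$codons, d),
         intron = if (d > 0)
           .mutate_intron(parent$intron, d * config$intron_rate_multiplier)
         else parent$intron,
         d = d, parent_id = parent_id)
  }
  fam_counter <- 0L
  new_fam_id <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("FAM%04d", fam_counter)
  }
  arrays <- vector("list", n_arr)
  array_ids <- vector("list", n_arr)
  for (a in seq_len(n_arr)) {
    copies <- vector("list", array_sizes[a])
    ids <- vapply(seq_len(array_sizes[a]), function(i) new_fam_id(), "")
    copies[[1]] <- copy_of(templates[[a]], NA_character_)
    for (k in seq_len(array_sizes[a] - 1L))
      copies[[k + 1L]] <- copy_of(copies[[k]], ids[k])
    arrays[[a]] <- copies
    array_ids[[a]] <- ids
  }
  prox_seqs <- lapply(prox_of_array, function(a) {
    src <- sample.int(length(arrays[[a]]), 1L)
    copy_of(arrays[[a]][[src]], array_ids[[a]][src])
  })
  prox_ids <- vapply(seq_along(prox_seqs), function(i) new_fam_id(), "")
  disp_seqs <- lapply(disp_of_array, function(a) {
    src <- sample.int(length(arrays[[a]]), 1L)
    copy_of(arrays[[a]][[src]], array_ids[[a]][src])
  })
  disp_ids <- vapply(seq_along(disp_seqs), function(i) new_fam_id(), "")

  # --- chromosome layout ---------------------------------------------------
  # special units: arrays (with their proximal tails) and dispersed genes,
  # separated by >= 110 kb and at least one background gene
  units_by_chrom <- vector("list", n_chrom)
  for (a in seq_len(n_arr)) {
    tail_idx <- which(prox_of_array == a)
    units_by_chrom[[array_chrom[a]]] <-
      c(units_by_chrom[[array_chrom[a]]],
        list(list(kind = "array", array = a, prox = tail_idx)))
  }
  for (d in seq_along(disp_of_array))
    units_by_chrom[[disp_chrom[d]]] <-
      c(units_by_chrom[[disp_chrom[d]]],
        list(list(kind = "dispersed", idx = d)))

  n_special <- sum(lengths(units_by_chrom))
  prox_n_int <- if (length(prox_of_array)) sample(1:3, length(prox_of_array),
                                                  replace = TRUE) else integer(0)
  n_sep_needed <- max(0L, n_special - n_chrom)  # one bg between consecutive units
  n_spare <- config$n_background_genes - sum(prox_n_int) - n_sep_needed
  if (n_spare < 0)
    .err("n_background_genes too small for the requested family events")

  bg_counter <- 0L
  new_bg <- function() {
    bg_counter <<- bg_counter + 1L
    list(gene_id = sprintf("BG%04d", bg_counter),
         len = sample(1000:5000, 1L))
  }
  # spread spare background genes over chromosomes
  spare_by_chrom <- tabulate(sample.int(n_chrom, n_spare, replace = TRUE),
                             nbins = n_chrom)

  genes <- list(); proteins <- character(); cds <- character()
  features <- list(); domains <- list(); truth <- list()
  gap <- function(lo, hi) floor(stats::runif(1, lo, hi))

  place_family_gene <- function(chrom, pos, id, seqrec, template, cluster,
                                mode, strand) {
    cds_nt <- paste(seqrec$codons, collapse = "")
    glen <- nchar(cds_nt) + nchar(seqrec$intron)
    genes[[length(genes) + 1L]] <<- list(
      gene_id = id, chromosome_id = chrom, start = pos, end = pos + glen - 1L,
      strand = strand, is_family = TRUE)
    proteins[[id]] <<- paste(.translate_codon(seqrec$codons), collapse = "")
    cds[[id]] <<- cds_nt
    lay <- template$layout
    flip <- config$feature_noise > 0 && stats::runif(1) < config$feature_noise
    has_signal <- xor(!is.null(lay$signal), flip)
    if (has_signal) {
      sp_end <- if (!is.null(lay$signal)) lay$signal else 20
      features[[length(features) + 1L]] <<- data.frame(
        protein_id = id, feature_type = "signal_peptide",
        start = 1L, end = sp_end, score = 0.99)
    }
    if (!is.null(lay$coil))
      features[[length(features) + 1L]] <<- data.frame(
        protein_id = id, feature_type = "coiled_coil",
        start = lay$coil[1], end = lay$coil[2], score = 0.9)
    for (k in seq_along(lay$domains)) {
      dom <- lay$domains[[k]]
      domains[[length(domains) + 1L]] <<- data.frame(
        protein_id = id,
        domain_name = if (names(lay$domains)[k] == "suel") "SUEL_lectin" else "C1q",
        ali_start = dom[1], ali_end = dom[2],
        e_value = 1e-20, model_coverage = 0.95)
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = id, cluster_id = sprintf("CL%02d", cluster),
      mode = mode, category = template$category,
      parent_id = seqrec$parent_id, copy_divergence = seqrec$d)
    pos + glen - 1L
  }
  place_bg_gene <- function(chrom, pos) {
    b <- new_bg()
    genes[[length(genes) + 1L]] <<- list(
      gene_id = b$gene_id, chromosome_id = chrom, start = pos,
      end = pos + b$len - 1L, strand = sample(c("+", "-"), 1L),
      is_family = FALSE)
    pos + b$len - 1L
  }

  prox_done <- 0L
  for (ch in seq_len(n_chrom)) {
    units <- units_by_chrom[[ch]]
    if (length(units) > 1L) units <- units[sample.int(length(units))]
    chrom <- chrom_ids[ch]
    # distribute spare background genes over slots around the special units
    n_slot <- length(units) + 1L
    slot_bg <- tabulate(sample.int(n_slot, spare_by_chrom[ch], replace = TRUE),
                        nbins = n_slot)
    pos <- 1L
    advance <- function(pos, lo, hi) pos + gap(lo, hi)
    for (u in seq_len(n_slot)) {
      n_bg <- slot_bg[u]
      if (u > 1L && u <= length(units)) n_bg <- n_bg + 1L  # separator
      for (b in seq_len(n_bg)) {
        pos <- advance(pos, 2e3, 3e4)
        pos <- place_bg_gene(chrom, pos) + 1L
      }
      if (u > length(units)) break
      unit <- units[[u]]
      pos <- pos + gap(1.2e5, 2.0e5)  # isolate unit from anything upstream
      if (unit$kind == "dispersed") {
        a <- disp_of_array[unit$idx]
        pos <- place_family_gene(chrom, pos, disp_ids[unit$idx],
                                 disp_seqs[[unit$idx]],
                                 templates[[a]], a, "DISPERSED",
                                 strand = sample(c("+", "-"), 1L)) + 1L
      } else {
        a <- unit$array
        strand <- sample(c("+", "-"), 1L, prob = c(0.8, 0.2))
        for (k in seq_along(arrays[[a]])) {
          if (k > 1L) pos <- pos + gap(config$tandem_gap_range[1],
                                       config$tandem_gap_range[2])
          pos <- place_family_gene(chrom, pos, array_ids[[a]][k],
                                   arrays[[a]][[k]],
                                   templates[[a]], a, "TANDEM", strand) + 1L
        }
        for (p in unit$prox) {
          prox_done <- prox_done + 1L
          n_int <- prox_n_int[prox_done]
          pos <- pos + gap(5e3, 1.5e4)
          for (b in seq_len(n_int)) {
            pos <- place_bg_gene(chrom, pos) + 1L
            pos <- pos + gap(2e3, 8e3)
          }
          pos <- place_family_gene(chrom, pos, prox_ids[p], prox_seqs[[p]],
                                   templates[[a]], a, "PROXIMAL", strand) + 1L
        }
      }
    }
    if (pos > config$chromosome_lengths[ch])
      .err("requested genes exceed placeable space on ", chrom,
           " (need ", pos, " bp, have ", config$chromosome_lengths[ch], ")")
  }

  gene_tab <- do.call(rbind, lapply(genes, as.data.frame))
  gene_tab <- sort_gene_table(gene_tab)
  structure(list(
    genes = gene_tab,
    proteins = unlist(proteins), cds = unlist(cds),
    features = do.call(rbind, features),
    domains = do.call(rbind, domains),
    truth = do.call(rbind, truth),
    chromosome_lengths = stats::setNames(config$chromosome_lengths, chrom_ids),
    config = config), class = "genome_simulation")
}

#' @export
print.genome_simulation <- function(x, ...) {
  cat(sprintf("genome_simulation: %d genes (%d family) on %d chromosomes\n",
              nrow(x$genes), sum(x$genes$is_family),
              length(x$chromosome_lengths)))
  cat("  planted modes:",
      paste(names(table(x$truth$mode)), table(x$truth$mode),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated genome to standard file formats
#'
#' Emits `genes.gff3`, `proteins.faa`, `cds.fna`, `features.tsv`,
#' `domains.tsv`, `truth.tsv` and `chromosomes.tsv` into a directory, in
#' the same formats the analysis pipeline consumes.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "genome_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gff = file.path(dir, "genes.gff3"),
             proteins = file.path(dir, "proteins.faa"),
             cds = file.path(dir, "cds.fna"),
             features = file.path(dir, "features.tsv"),
             domains = file.path(dir, "domains.tsv"),
             truth = file.path(dir, "truth.tsv"),
             chromosomes = file.path(dir, "chromosomes.tsv"))
  g <- sim$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chromosome_id,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$source <- "famdup_sim"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  GenomeInfoDb::seqlengths(gr) <-
    sim$chromosome_lengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, paths[["gff"]], format = "gff3")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$proteins),
                              paths[["proteins"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds),
                              paths[["cds"]])
  utils::write.table(sim$features, paths[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$domains, paths[["domains"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chromosome_id = names(sim$chromosome_lengths),
               length = unname(sim$chromosome_lengths)),
    paths[["chromosomes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a codon alignment under site-specific selection
#'
#' Evolves codon sequences along a random pure-birth (Yule) tree -- the
#' natural null model for a gene-duplication history -- by a
#' continuous-time Markov process in which each single-nucleotide codon
#' change has rate 1/3 when synonymous and omega/3 when nonsynonymous
#' (so one unit of branch length equals one expected substitution per
#' nucleotide site under neutrality); changes into stop codons are
#' forbidden. Per-site omega is given by `omega_map`, so positively
#' selected sites (omega > 1) can be planted among neutral or constrained
#' ones. The realized substitution history is recorded per site.
#'
#' @param n_seqs Number of sequences (tree tips).
#' @param n_sites Number of codon sites.
#' @param tree_depth Root-to-tip height in expected neutral substitutions
#'   per nucleotide site.
#' @param omega_map Numeric vector of per-site omega values (recycled to
#'   `n_sites`).
#' @param seed RNG seed; the simulation is deterministic given it.
#' @return List with `alignment` (a [codon_alignment()] of the tip
#'   sequences), `tree` ([ape::phylo], tips `t1..tn`), `truth`
#'   (`data.frame`: `site_index`, `omega`, `true_syn`, `true_nonsyn` --
#'   realized substitution counts summed over all branches) and
#'   `omega_map`.
#' @export
simulate_selection_alignment <- function(n_seqs = 20, n_sites = 200,
                                         tree_depth = 0.5,
                                         omega_map = rep(1, n_sites),
                                         seed = 1) {
  stopifnot(n_seqs >= 3, n_sites >= 1, tree_depth >= 0)
  omega_map <- rep_len(omega_map, n_sites)
  if (any(omega_map < 0)) .err("omega must be >= 0")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_seqs, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (tree_depth / depth)

  # neighbor tables for the 61 sense codons
  sense <- sense_codons()
  nb <- lapply(sense, function(c) {
    n <- .codon_neighbors(c)
    n <- n[!vapply(n, .is_stop, TRUE)]
    list(to = n, syn = .translate_codon(n) == .translate_codon(c))
  })
  names(nb) <- sense

  root_seq <- sample(sense, n_sites, replace = TRUE)
  true_syn <- numeric(n_sites); true_nonsyn <- numeric(n_sites)
  evolve_branch <- function(codons, t) {
    if (t <= 0) return(codons)
    for (s in seq_len(n_sites)) {
      w <- omega_map[s]
      time <- 0
      repeat {
        tab <- nb[[codons[s]]]
        rates <- ifelse(tab$syn, 1, w) / 3
        R <- sum(rates)
        if (R <= 0) break
        time <- time + stats::rexp(1, R)
        if (time > t) break
        k <- sample.int(length(tab$to), 1L, prob = rates)
        if (tab$syn[k]) true_syn[s] <<- true_syn[s] + 1
        else true_nonsyn[s] <<- true_nonsyn[s] + 1
        codons[s] <- tab$to[k]
      }
    }
    codons
  }
  n_tip <- n_seqs
  edge <- tree$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  root <- setdiff(edge[, 1], edge[, 2])[1]
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- root_seq
  # preorder over edges
  stack <- children[[as.character(root)]]
  while (length(stack)) {
    e <- stack[length(stack)]; stack <- stack[-length(stack)]
    pa <- edge[e, 1]; ch <- edge[e, 2]
    seqs[[ch]] <- evolve_branch(seqs[[pa]], tree$edge.length[e])
    kids <- children[[as.character(ch)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  tips <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(tips) <- tree$tip.label
  list(alignment = codon_alignment(tips), tree = tree,
       truth = data.frame(site_index = seq_len(n_sites), omega = omega_map,
                          true_syn = true_syn, true_nonsyn = true_nonsyn),
       omega_map = omega_map)
}
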