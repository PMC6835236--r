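# Shared fixtures and independent oracles used across the test files.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# random protein of a given length (first residue M, like a real ORF)
rand_prot <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

# point-mutate a protein at a given per-residue rate
mutate_prot <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

# --- exhaustive global-alignment oracle -------------------------------------
# Enumerates every global alignment of two short sequences under
# BLOSUM62 + affine gaps (cost = open + ext * len, matching the package's
# scoring), returning the optimal score and the set of identity counts
# attained by optimal alignments.
align_enum_oracle <- function(a, b, open = 10, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- new.env(); best$score <- -Inf; best$idents <- integer()
  # state: 0 = last step diagonal, 1 = gap in b (consume a), 2 = gap in a
  rec <- function(i, j, state, score, ident) {
    if (i > length(ca) && j > length(cb)) {
      if (score > best$score) { best$score <- score; best$idents <- ident }
      else if (score == best$score) best$idents <- union(best$idents, ident)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, 0L, score + S[ca[i], cb[j]],
          ident + (ca[i] == cb[j]))
    if (i <= length(ca))
      rec(i + 1, j, 1L, score - (if (state == 1L) ext else open + ext), ident)
    if (j <= length(cb))
      rec(i, j + 1, 2L, score - (if (state == 2L) ext else open + ext), ident)
  }
  rec(1L, 1L, 0L, 0, 0L)
  list(score = best$score, identities = best$idents)
}

# --- single-linkage clustering oracle ---------------------------------------
# Connected components of the identity graph via igraph, as an independent
# route to the package's union-find. Returns a canonical partition: list of
# sorted member vectors, sorted by size then first member.
single_linkage_oracle <- function(identity, threshold) {
  adj <- identity > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  canonical_partition(split(rownames(identity), comp))
}

canonical_partition <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  ord <- order(-lengths(clusters), vapply(clusters, `[`, "", 1L),
               method = "radix")
  unname(clusters[ord])
}

# a protein set with planted identity blocks: each block is a template plus
# near-copies; singletons are unrelated random proteins
planted_protein_set <- function(n_blocks, block_sizes, n_singletons,
                                len = 50, rate = 0.05) {
  seqs <- character(); truth <- integer()
  for (b in seq_len(n_blocks)) {
    tmpl <- rand_prot(len)
    for (k in seq_len(block_sizes[b])) {
      seqs <- c(seqs, mutate_prot(tmpl, rate))
      truth <- c(truth, b)
    }
  }
  for (s in seq_len(n_singletons)) {
    seqs <- c(seqs, rand_prot(len))
    truth <- c(truth, n_blocks + s)
  }
  names(seqs) <- sprintf("P%03d", seq_along(seqs))
  list(seqs = Biostrings::AAStringSet(seqs),
       truth = stats::setNames(truth, names(seqs)))
}

# --- brute-force codon parsimony oracle -------------------------------------
# Minimal number of codon changes on a rooted tree over all assignments of
# observed states to internal nodes (exhaustive enumeration).
parsimony_enum_oracle <- function(tree, tip_codons) {
  tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(edge[, 1]))
  states <- sort(unique(tip_codons))
  node_state <- character(n_tip + tree$Nnode)
  node_state[seq_len(n_tip)] <- tip_codons[tree$tip.label]
  grid <- do.call(expand.grid,
                  c(rep(list(states), length(internal)),
                    list(stringsAsFactors = FALSE)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    node_state[internal] <- unlist(grid[r, ])
    cost <- sum(node_state[edge[, 1]] != node_state[edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# tiny GFF3 writer for io tests
write_tiny_gff <- function(rows, path) {
  lines <- c("##gff-version 3",
             vapply(rows, function(r)
               paste(r$chrom, "test", "gene", r$start, r$end, ".", r$strand,
                     ".", paste0("ID=", r$id), sep = "\t"), ""))
  writeLines(lines, path)
  path
}

# small, fast simulation used by several tests
small_sim_config <- function(seed = 1, divergence = 0.03) {
  simulation_config(seed = seed, n_chromosomes = 2,
                    chromosome_lengths = 8e6, n_background_genes = 60,
                    n_tandem_arrays = 4, array_size_range = c(3, 5),
                    n_proximal = 4, n_dispersed = 3,
                    divergence = divergence)
}
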