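#' Codon alignment container
#'
#' A light container for an in-frame codon alignment: a character matrix of
#' codon triplets (gap columns as `"---"`), one row per sequence, plus a
#' provenance map from current to original codon columns (maintained by
#' [trim_alignment()]).
#'
#' @param codons Character matrix of codon triplets, rows named by
#'   sequence ID.
#' @param trimmed Logical, whether gap/region trimming has been applied.
#' @param provenance Integer vector mapping current columns to original
#'   column indices.
#' @return Object of class `codon_alignment` with elements `ids`,
#'   `codons`, `trimmed`, `provenance`.
#' @export
codon_alignment <- function(codons, trimmed = FALSE,
                            provenance = seq_len(ncol(codons))) {
  stopifnot(is.matrix(codons), is.character(codons))
  if (is.null(rownames(codons))) .err("codon matrix must have row names")
  if (any(nchar(codons) != 3L)) .err("all entries must be codon triplets")
  structure(list(ids = rownames(codons), codons = codons,
                 trimmed = trimmed, provenance = as.integer(provenance)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d codon columns%s\n",
              nrow(x$codons), ncol(x$codons),
              if (x$trimmed) " (trimmed)" else ""))
  invisible(x)
}

#' Build a codon alignment from aligned nucleotide rows
#'
#' @param aligned Named character vector (or `DNAStringSet`) of equal-length
#'   gapped nucleotide sequences whose length is divisible by 3 and whose
#'   gaps respect codon boundaries.
#' @return A [codon_alignment()].
#' @export
as_codon_alignment <- function(aligned) {
  s <- stats::setNames(toupper(as.character(aligned)), names(aligned))
  if (length(unique(nchar(s))) != 1L) .err("rows differ in length")
  L <- nchar(s[1])
  if (L %% 3L != 0L) .err("alignment length not divisible by 3")
  m <- t(vapply(s, function(x)
    substring(x, seq(1, L, 3), seq(3, L, 3)), character(L / 3)))
  if (L == 3L) { m <- matrix(m, ncol = 1L, dimnames = list(names(s), NULL)) }
  rownames(m) <- names(s)
  bad <- grepl("-", m) & m != "---"
  if (any(bad)) .err("gap not respecting codon boundaries")
  codon_alignment(m)
}

#' Back-translate a protein alignment to codons
#'
#' Replaces every aligned residue of a protein multiple alignment by the
#' corresponding codon of the sequence's CDS, preserving codon-triplet
#' integrity; alignment gaps become gap triplets. Each protein's ungapped
#' sequence must equal the translation of its CDS under the standard code
#' (a terminal stop codon on the CDS is tolerated and dropped).
#'
#' @param protein_msa Named [Biostrings::AAStringSet] (aligned, `-` gaps)
#'   or named character vector.
#' @param cds_set Named [Biostrings::DNAStringSet] of coding sequences.
#' @return A [codon_alignment()].
#' @export
backtranslate_alignment <- function(protein_msa, cds_set) {
  prots <- stats::setNames(toupper(as.character(protein_msa)),
                           names(protein_msa))
  cds <- stats::setNames(toupper(as.character(cds_set)), names(cds_set))
  if (is.null(names(prots))) .err("protein alignment must be named")
  miss <- setdiff(names(prots), names(cds))
  if (length(miss)) .err("no CDS for: ", paste(miss, collapse = ", "))
  L <- unique(nchar(prots))
  if (length(L) != 1L) .err("protein alignment rows differ in length")
  rows <- matrix("", nrow = length(prots), ncol = L,
                 dimnames = list(names(prots), NULL))
  for (id in names(prots)) {
    aa <- strsplit(prots[[id]], "")[[1]]
    s <- cds[[id]]
    n_res <- sum(aa != "-")
    if (nchar(s) == 3L * (n_res + 1L)) {
      last <- substr(s, nchar(s) - 2L, nchar(s))
      if (.is_stop(last)) s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) != 3L * n_res)
      .err("CDS length of ", id, " (", nchar(s),
           ") does not match ", n_res, " aligned residues")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    trans <- .translate_codon(codons)
    res_idx <- which(aa != "-")
    mism <- which(trans != aa[res_idx])
    if (length(mism))
      .err("CDS of ", id, " does not translate to its protein at codon ",
           mism[1], " (alignment column ", res_idx[mism[1]], ": ",
           trans[mism[1]], " vs ", aa[res_idx[mism[1]]], ")")
    rows[id, ] <- "---"
    rows[id, res_idx] <- codons
  }
  codon_alignment(rows)
}

#' Trim a codon alignment to gap-free columns of a region
#'
#' Retains only columns that contain no gap triplet and (optionally) lie
#' within a focal region, e.g. the globular domain shared by all family
#' members. A provenance map from retained to original columns is kept so
#' reported site positions can be traced back.
#'
#' @param codon_aln A [codon_alignment()].
#' @param region Optional `c(first, last)` codon-column interval (in the
#'   alignment's current coordinates) to which trimming is restricted.
#' @return A trimmed [codon_alignment()]; error if no column survives.
#' @export
trim_alignment <- function(codon_aln, region = NULL) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  m <- codon_aln$codons
  keep <- colSums(m == "---") == 0L
  if (!is.null(region)) {
    if (length(region) != 2L || region[1] > region[2])
      .err("region must be c(first, last) with first <= last")
    in_region <- seq_len(ncol(m)) >= region[1] & seq_len(ncol(m)) <= region[2]
    keep <- keep & in_region
  }
  if (!any(keep)) .err("no analyzable sites after trimming")
  codon_alignment(m[, keep, drop = FALSE], trimmed = TRUE,
                  provenance = codon_aln$provenance[keep])
}

#' Nucleotide distance matrix of a codon alignment
#'
#' Pairwise nucleotide p-distances over the aligned codon columns
#' (gap-containing columns skipped pairwise), with Jukes-Cantor correction
#' by default; saturated pairs are capped just below the correction's
#' domain boundary.
#'
#' @param codon_aln A [codon_alignment()].
#' @param correction `"JC"` (default) or `"none"`.
#' @return Symmetric distance matrix over sequence IDs.
#' @export
codon_distance_matrix <- function(codon_aln, correction = c("JC", "none")) {
  correction <- match.arg(correction)
  m <- codon_aln$codons
  n <- nrow(m)
  nt <- t(vapply(seq_len(n), function(i)
    strsplit(paste(m[i, ], collapse = ""), "")[[1]],
    character(3L * ncol(m))))
  d <- matrix(0, n, n, dimnames = list(codon_aln$ids, codon_aln$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- nt[i, ] != "-" & nt[j, ] != "-"
    p <- if (any(ok)) mean(nt[i, ok] != nt[j, ok]) else 0
    if (correction == "JC") {
      p <- min(p, 0.74)
      p <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}); provided as
#' plumbing for the ancestral-state reconstruction the counting selection
#' analysis conditions on. With fewer than three taxa a trivial star tree
#' is returned with a warning. Negative branch lengths (possible for
#' non-additive inputs) are clamped to zero.
#'
#' @param distance_matrix Symmetric non-negative matrix with dimnames.
#' @return An [ape::phylo] tree (unrooted for n >= 3).
#' @export
nj_tree <- function(distance_matrix) {
  if (!isSymmetric(unname(distance_matrix), tol = 1e-8))
    .err("distance matrix must be symmetric")
  if (any(distance_matrix < 0)) .err("distances must be non-negative")
  n <- nrow(distance_matrix)
  if (n < 3L) {
    warning("fewer than 3 taxa: returning trivial tree", call. = FALSE)
    ids <- rownames(distance_matrix)
    if (n == 1L)
      return(ape::read.tree(text = paste0("(", ids[1], ":0);")))
    d <- distance_matrix[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         ids[1], d / 2, ids[2], d / 2)))
  }
  tr <- ape::nj(distance_matrix)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# root an (unrooted) phylo at the first tip's attachment, resolving to binary
.rooted <- function(tree) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  tree
}

#' Ancestral codon states by Fitch parsimony
#'
#' Reconstructs codon states at the internal nodes of a tree for every
#' column of a codon alignment, by Fitch parsimony over the observed codon
#' states. In the top-down refinement, a node whose state set contains the
#' parent's state inherits it; otherwise the state requiring the fewest
#' nucleotide differences from the children's candidate sets (then the
#' lexicographically smallest codon) is chosen.
#'
#' @param tree [ape::phylo] whose tip labels equal the alignment IDs.
#' @param codon_aln A [codon_alignment()] (gap-free; trim first).
#' @return List with `tree` (the rooted working tree), `states` (character
#'   matrix `(n_tips + n_internal) x n_sites` of codons, rows ordered by
#'   the tree's node numbering) and `score` (integer vector of per-site
#'   parsimony scores, in codon changes).
#' @export
ancestral_codons <- function(tree, codon_aln) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  if (any(codon_aln$codons == "---"))
    .err("alignment contains gaps; trim_alignment first")
  tree <- .rooted(tree)
  if (!setequal(tree$tip.label, codon_aln$ids))
    .err("tree tip labels must match alignment IDs")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  n_site <- ncol(codon_aln$codons)
  edge <- tree$edge
  children <- split(edge[, 2], edge[, 1])
  root <- setdiff(edge[, 1], edge[, 2])[1]
  # postorder of internal nodes
  post <- rev(.preorder_nodes(root, children))
  states <- matrix(NA_character_, nrow = n_tip + n_node, ncol = n_site)
  scores <- integer(n_site)
  tipdat <- codon_aln$codons[match(tree$tip.label, codon_aln$ids), , drop = FALSE]
  for (s in seq_len(n_site)) {
    sets <- vector("list", n_tip + n_node)
    for (i in seq_len(n_tip)) sets[[i]] <- tipdat[i, s]
    score <- 0L
    for (v in post) {
      if (v <= n_tip) next
      kids <- children[[as.character(v)]]
      inter <- Reduce(intersect, lapply(kids, function(k) sets[[k]]))
      if (length(inter)) {
        sets[[v]] <- inter
      } else {
        sets[[v]] <- sort(unique(unlist(lapply(kids, function(k) sets[[k]]))))
        score <- score + 1L
      }
    }
    # top-down refinement
    for (v in .preorder_nodes(root, children)) {
      if (v <= n_tip) { states[v, s] <- sets[[v]][1L]; next }
      cand <- sets[[v]]
      parent <- edge[edge[, 2] == v, 1]
      if (length(parent) && states[parent, s] %in% cand) {
        states[v, s] <- states[parent, s]
        next
      }
      if (length(cand) == 1L) { states[v, s] <- cand; next }
      kids <- children[[as.character(v)]]
      cost <- vapply(cand, function(cs)
        sum(vapply(kids, function(k)
          min(vapply(sets[[k]], function(ks) .nt_diff(cs, ks), 0)), 0)),
        0)
      cand <- sort(cand[cost == min(cost)])
      states[v, s] <- cand[1L]
    }
    scores[s] <- score
  }
  list(tree = tree, states = states, score = scores)
}

.preorder_nodes <- function(root, children) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- children[[as.character(v)]]
    if (!is.null(kids)) stack <- c(stack, rev(kids))
  }
  out
}

# continuous two-sided binomial test (regularized incomplete beta tails),
# valid for non-integer counts arising from path averaging
.binom_test_cont <- function(successes, trials, p0) {
  if (trials <= 0) return(1)
  lower <- if (successes >= trials) 1 else stats::pbeta(1 - p0, trials - successes, successes + 1)
  upper <- if (successes <= 0) 1 else stats::pbeta(p0, successes, trials - successes + 1)
  min(1, 2 * min(lower, upper))
}

#' Counting-based per-site selection analysis
#'
#' SLAC-style counting analysis of a gap-free codon alignment: codon states
#' at internal nodes are reconstructed by parsimony, synonymous and
#' nonsynonymous substitutions are counted per site along every branch
#' (averaging over minimal mutational paths, excluding paths through stop
#' codons), and the observed synonymous count at each site is compared with
#' the neutral expectation (the mean potential-synonymous-site fraction of
#' the codons observed at the site) by a two-sided binomial test. A site
#' with a significant nonsynonymous excess is called `POSITIVE`, a
#' significant synonymous excess `NEGATIVE`, anything else `NEUTRAL`; a
#' site with zero inferred substitutions is `NEUTRAL` with p = 1.
#'
#' @param tree [ape::phylo] over the alignment IDs (e.g. from
#'   [nj_tree()]).
#' @param codon_aln Gap-free [codon_alignment()].
#' @param alpha Per-site significance threshold (default 0.05, applied to
#'   raw p-values, matching the per-method convention).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values before classification.
#' @return `data.frame` with one row per site: `site_index` (1-based in
#'   the trimmed alignment), `observed_syn`, `observed_nonsyn`,
#'   `expected_syn_fraction`, `p_value`, `selection_class`, `support`
#'   (`"NONE"`; filled by [consensus_support()]).
#' @export
site_selection <- function(tree, codon_aln, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  anc <- ancestral_codons(tree, codon_aln)
  tree <- anc$tree
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  n_site <- ncol(codon_aln$codons)
  syn <- numeric(n_site); nonsyn <- numeric(n_site)
  for (e in seq_len(nrow(edge))) {
    pa <- edge[e, 1]; ch <- edge[e, 2]
    for (s in seq_len(n_site)) {
      a <- anc$states[pa, s]; b <- anc$states[ch, s]
      if (a != b) {
        cnt <- count_codon_path(a, b)
        syn[s] <- syn[s] + cnt[["syn"]]
        nonsyn[s] <- nonsyn[s] + cnt[["nonsyn"]]
      }
    }
  }
  tipdat <- codon_aln$codons[match(tree$tip.label, codon_aln$ids), , drop = FALSE]
  exp_frac <- vapply(seq_len(n_site), function(s)
    mean(vapply(tipdat[, s], function(c) codon_syn_sites(c)$syn_sites / 3, 0)),
    0)
  total <- syn + nonsyn
  pval <- vapply(seq_len(n_site), function(s)
    if (total[s] == 0) 1 else .binom_test_cont(syn[s], total[s], exp_frac[s]),
    0)
  p_eff <- if (p_adjust == "BH") stats::p.adjust(pval, "BH") else pval
  class <- rep("NEUTRAL", n_site)
  obs_frac <- ifelse(total > 0, syn / total, exp_frac)
  class[p_eff < alpha & obs_frac < exp_frac] <- "POSITIVE"
  class[p_eff < alpha & obs_frac > exp_frac] <- "NEGATIVE"
  data.frame(site_index = seq_len(n_site),
             observed_syn = syn, observed_nonsyn = nonsyn,
             expected_syn_fraction = exp_frac,
             p_value = pval, selection_class = class,
             support = "NONE", stringsAsFactors = FALSE)
}

#' Multi-method consensus support for positively selected sites
#'
#' Merges positively selected site lists from several methods (the internal
#' counting method plus any externally computed lists) into per-site
#' support levels: `STRONG` for sites detected by at least two methods,
#' `MODERATE` for sites detected by exactly one, `NONE` otherwise.
#'
#' @param site_calls_by_method Named list; each element an integer vector
#'   of positively selected site indices from one method.
#' @param n_sites Number of sites in the (trimmed) alignment.
#' @return Character vector of length `n_sites` with support levels.
#' @export
consensus_support <- function(site_calls_by_method, n_sites) {
  votes <- integer(n_sites)
  for (sites in site_calls_by_method) {
    sites <- unique(as.integer(sites))
    if (length(sites) && (any(sites < 1L) || any(sites > n_sites)))
      .err("site index outside alignment (1..", n_sites, ")")
    votes[sites] <- votes[sites] + 1L
  }
  ifelse(votes >= 2L, "STRONG", ifelse(votes == 1L, "MODERATE", "NONE"))
}

#' Read external per-method positive-site lists
#'
#' Two-column TSV (`method`, `site_index`) as exported by external
#' selection-inference tools.
#'
#' @param path Path to the TSV.
#' @return Named list of integer vectors, one per method.
#' @export
read_method_sites <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("method", "site_index") %in% colnames(tab)))
    .err("expected columns method, site_index")
  lapply(split(tab$site_index, tab$method), as.integer)
}
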