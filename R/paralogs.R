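#' Global pairwise protein identity
#'
#' Aligns two amino-acid sequences globally (Needleman-Wunsch with affine
#' gap penalties, BLOSUM62 scores by default) and returns the fraction of
#' identical aligned positions. The denominator follows the
#' representative-clustering convention: the length of the shorter
#' sequence, so that a perfect sub-sequence match of a longer protein
#' scores 1. An `"alignment"` denominator (aligned length including gaps)
#' is available.
#'
#' @param seq_a,seq_b Amino-acid sequences (character scalars or
#'   [Biostrings::AAString]).
#' @param substitution_matrix Name of the scoring matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties, as positive
#'   costs (defaults 10 and 1).
#' @param denominator `"shorter"` (default) or `"alignment"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 1,
                              denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  a <- as.character(seq_a); b <- as.character(seq_b)
  if (!nzchar(a) || !nzchar(b)) .err("empty sequence in pairwise_identity")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension, type = "global")
  .aln_identity(as.character(Biostrings::pattern(aln)),
                as.character(Biostrings::subject(aln)),
                nchar(a), nchar(b), denominator)
}

.aln_identity <- function(row_a, row_b, len_a, len_b, denominator) {
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  n_id <- sum(ca == cb & ca != "-")
  denom <- if (denominator == "shorter") min(len_a, len_b) else length(ca)
  n_id / denom
}

#' All-against-all identity matrix
#'
#' Computes the symmetric matrix of global pairwise identities over a
#' protein set. Alignments against each subject are vectorized.
#'
#' @param seqs Named [Biostrings::AAStringSet] (or named character vector).
#' @inheritParams pairwise_identity
#' @return Symmetric numeric matrix with unit diagonal, dimnames = IDs.
#' @export
identity_matrix <- function(seqs, substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 1,
                            denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  seqs <- Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    .err("identity_matrix needs uniquely named sequences")
  n <- length(seqs)
  ids <- names(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  lens <- Biostrings::width(seqs)
  for (i in seq_len(n - 1L)) {
    alns <- Biostrings::pairwiseAlignment(
      seqs[(i + 1L):n], seqs[[i]],
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension, type = "global")
    pa <- as.character(Biostrings::pattern(alns))
    sa <- as.character(Biostrings::subject(alns))
    for (k in seq_along(pa)) {
      j <- i + k
      m[i, j] <- m[j, i] <-
        .aln_identity(pa[k], sa[k], lens[j], lens[i], denominator)
    }
  }
  m
}

#' Partition family proteins into paralog clusters
#'
#' Groups proteins whose pairwise identity exceeds `threshold` (strict
#' inequality) into paralog clusters. The default `"single"` mode takes
#' connected components of the identity graph (single linkage), which is
#' invariant to input order and admits an exact brute-force oracle. A
#' `"greedy"` representative mode is provided for parity with
#' representative-clustering tools: sequences are processed longest first,
#' each either joining the first representative it exceeds the threshold
#' against or founding a new cluster.
#'
#' @param seqs Named [Biostrings::AAStringSet], or a precomputed identity
#'   matrix from [identity_matrix()].
#' @param threshold Identity threshold in `(0, 1]` (default 0.5; an edge
#'   requires identity strictly greater than this).
#' @param mode `"single"` (default) or `"greedy"`.
#' @param ... Passed to [identity_matrix()] when `seqs` are sequences.
#' @return An object of class `paralog_clusters`: list with `threshold`,
#'   `mode`, `clusters` (list of character vectors of member IDs, sorted by
#'   descending size then by lexicographically smallest member; members
#'   sorted within each cluster) and `membership` (named integer vector of
#'   cluster indices).
#' @export
cluster_paralogs <- function(seqs, threshold = 0.5,
                             mode = c("single", "greedy"), ...) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    .err("threshold must lie in (0, 1]")
  if (is.matrix(seqs)) {
    m <- seqs
    if (mode == "greedy")
      .err("greedy mode needs sequences, not a precomputed matrix")
  } else {
    seqs <- Biostrings::AAStringSet(seqs)
    if (length(seqs) < 1L) .err("need at least one sequence")
    m <- NULL
  }
  if (mode == "single") {
    if (is.null(m)) m <- identity_matrix(seqs, ...)
    ids <- rownames(m)
    n <- length(ids)
    # union-find over the identity graph
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (m[i, j] > threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, 0L)
    clusters <- split(ids, comp)
  } else {
    ids <- names(seqs)
    ord <- order(-Biostrings::width(seqs), ids, method = "radix")
    reps <- integer() # indices of cluster representatives
    assignment <- integer(length(seqs))
    for (i in ord) {
      placed <- FALSE
      for (r in seq_along(reps)) {
        idt <- pairwise_identity(seqs[[i]], seqs[[reps[r]]], ...)
        if (idt > threshold) { assignment[i] <- r; placed <- TRUE; break }
      }
      if (!placed) { reps <- c(reps, i); assignment[i] <- length(reps) }
    }
    clusters <- split(ids, assignment)
  }
  clusters <- lapply(clusters, function(x) sort(unname(x)))
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, "", 1L), method = "radix")
  clusters <- unname(clusters[ord])
  membership <- integer(length(unlist(clusters)))
  names(membership) <- unlist(clusters)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  structure(list(threshold = threshold, mode = mode,
                 clusters = clusters, membership = membership),
            class = "paralog_clusters")
}

#' @export
print.paralog_clusters <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("paralog_clusters: %d proteins in %d clusters (threshold > %g, %s linkage)\n",
              sum(sizes), length(sizes), x$threshold, x$mode))
  cat("  cluster sizes:", paste(utils::head(sizes, 15), collapse = " "),
      if (length(sizes) > 15) "...", "\n")
  invisible(x)
}

#' Closest paralog and its identity
#'
#' For one protein (or all of them), finds the maximal off-diagonal
#' identity in the matrix; ties are broken by lexicographically smallest
#' partner ID. A singleton matrix yields `NA` partner and identity 0.
#'
#' @param matrix Identity matrix from [identity_matrix()].
#' @param protein_id One protein ID, or `NULL` (default) for all rows.
#' @return For one ID, a list `(closest_id, identity)`; for all rows a
#'   `data.frame` with columns `protein_id`, `closest_id`, `identity`.
#' @export
closest_paralog_identity <- function(matrix, protein_id = NULL) {
  ids <- rownames(matrix)
  one <- function(id) {
    i <- match(id, ids)
    if (is.na(i)) .err("protein not in matrix: ", id)
    if (length(ids) == 1L)
      return(list(closest_id = NA_character_, identity = 0))
    row <- matrix[i, -i]
    best <- max(row)
    cand <- sort(names(row)[row == best])
    list(closest_id = cand[1L], identity = unname(best))
  }
  if (!is.null(protein_id)) return(one(protein_id))
  res <- lapply(ids, one)
  data.frame(protein_id = ids,
             closest_id = vapply(res, `[[`, "", "closest_id"),
             identity = vapply(res, `[[`, 0, "identity"),
             stringsAsFactors = FALSE)
}

#' Select large paralog clusters
#'
#' @param cluster_set A [cluster_paralogs()] result.
#' @param min_size Minimum member count (default 10).
#' @return List of clusters (character vectors) with at least `min_size`
#'   members, in the cluster set's order.
#' @export
large_clusters <- function(cluster_set, min_size = 10) {
  stopifnot(inherits(cluster_set, "paralog_clusters"))
  cluster_set$clusters[lengths(cluster_set$clusters) >= min_size]
}

#' Write cluster membership as TSV
#'
#' @param cluster_set A [cluster_paralogs()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cluster_set, path) {
  rows <- do.call(rbind, lapply(seq_along(cluster_set$clusters), function(k) {
    mem <- cluster_set$clusters[[k]]
    data.frame(protein_id = mem, cluster_id = k, cluster_size = length(mem),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
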