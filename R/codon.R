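# Codon-level primitives shared by the counting selection caller and the
# sequence simulators. The standard genetic code is taken from Biostrings.

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() Biostrings::GENETIC_CODE

#' All sense codons of the standard genetic code
#' @return Character vector of the 61 non-stop codons, alphabetical.
#' @export
sense_codons <- function() {
  gc <- .genetic_code()
  sort(names(gc)[gc != "*"])
}

.is_stop <- function(codon) .genetic_code()[codon] == "*"

.translate_codon <- function(codon) unname(.genetic_code()[codon])

# number of differing nucleotide positions between two codons
.nt_diff <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# the 9 single-nucleotide neighbors of a codon (including stops)
.codon_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (n in setdiff(nts, ch[p])) {
    mut <- ch; mut[p] <- n
    out <- c(out, paste(mut, collapse = ""))
  }
  out
}

#' Potential synonymous sites of a codon
#'
#' For each codon position, enumerates the three single-nucleotide mutants;
#' mutants that create a stop codon are excluded, and the position
#' contributes the fraction of remaining mutants that are synonymous. The
#' per-codon number of synonymous sites is the sum over the three
#' positions (so the codon's total site count is 3). E.g. for TTT only the
#' third-position change to TTC is synonymous, giving 1/3 synonymous sites.
#'
#' @param codon A sense codon (3-letter DNA string).
#' @return List with `syn_sites` (in `[0, 3]`), `nonsyn_sites`
#'   (`3 - syn_sites`) and `per_position` (numeric length 3, synonymous
#'   fraction per position).
#' @export
codon_syn_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% sense_codons()) .err("not a sense codon: ", codon)
  key <- paste0("syn_", codon)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  aa <- .translate_codon(codon)
  ch <- strsplit(codon, "")[[1]]
  nts <- c("A", "C", "G", "T")
  per <- numeric(3)
  for (p in 1:3) {
    muts <- vapply(setdiff(nts, ch[p]), function(n) {
      m <- ch; m[p] <- n; paste(m, collapse = "")
    }, "")
    ok <- !vapply(muts, .is_stop, TRUE)
    per[p] <- if (any(ok)) mean(.translate_codon(muts[ok]) == aa) else 0
  }
  res <- list(syn_sites = sum(per), nonsyn_sites = 3 - sum(per),
              per_position = per)
  .codon_env[[key]] <- res
  res
}

#' Synonymous/nonsynonymous substitution counts between two codons
#'
#' Counts the synonymous and nonsynonymous single-nucleotide steps
#' separating two codons, averaged over all minimal mutational paths
#' (orderings of the differing positions). Paths passing through a stop
#' codon are excluded; the surviving shortest paths are weighted equally.
#' If every path hits a stop, the pair contributes nonsynonymous-only
#' minimal counts, with a warning.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(syn, nonsyn)`; `syn + nonsyn` equals the
#'   nucleotide difference count between the codons (also when the
#'   stop-only fallback applies).
#' @export
count_codon_path <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (codon_a == codon_b) return(c(syn = 0, nonsyn = 0))
  key <- paste0("path_", codon_a, codon_b)
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  ca <- strsplit(codon_a, "")[[1]]; cb <- strsplit(codon_b, "")[[1]]
  pos <- which(ca != cb)
  k <- length(pos)
  perms <- .permutations(pos)
  syn_tot <- 0; nonsyn_tot <- 0; n_valid <- 0L
  for (ord in perms) {
    cur <- ca; s <- 0; ns <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cb[p]
      ncod <- paste(nxt, collapse = "")
      if (.is_stop(ncod)) { valid <- FALSE; break }
      if (.translate_codon(paste(cur, collapse = "")) == .translate_codon(ncod))
        s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (valid) { syn_tot <- syn_tot + s; nonsyn_tot <- nonsyn_tot + ns
                 n_valid <- n_valid + 1L }
  }
  res <- if (n_valid > 0L) {
    c(syn = syn_tot / n_valid, nonsyn = nonsyn_tot / n_valid)
  } else {
    warning("all mutational paths between ", codon_a, " and ", codon_b,
            " pass through stop codons; counting all steps as nonsynonymous",
            call. = FALSE)
    c(syn = 0, nonsyn = k)
  }
  .codon_env[[key]] <- res
  res
}

# all permutations of a small vector (k <= 3 here)
.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}
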