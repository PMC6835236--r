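#' Windowed family-gene counts along a chromosome
#'
#' Counts family genes in non-overlapping tiling windows
#' `[k*w + 1, (k+1)*w]` (1-based inclusive). A gene is assigned to the
#' window containing its start coordinate; the last window may be partial.
#'
#' @param genes Gene table rows, all on one chromosome (typically the
#'   family genes of that chromosome).
#' @param chromosome_length Chromosome length in bp.
#' @param window_size Window length in bp (default 1 Mb).
#' @return Integer vector of length `ceiling(chromosome_length /
#'   window_size)`; sums to `nrow(genes)`.
#' @export
window_counts <- function(genes, chromosome_length, window_size = 1e6) {
  if (window_size <= 0) .err("window_size must be positive")
  if (chromosome_length <= 0) .err("chromosome_length must be positive")
  if (nrow(genes) && length(unique(genes$chromosome_id)) > 1L)
    .err("window_counts expects genes from a single chromosome")
  n_win <- as.integer(ceiling(chromosome_length / window_size))
  if (nrow(genes) == 0L) return(integer(n_win))
  if (any(genes$start > chromosome_length))
    .err("gene start beyond chromosome length: ",
         paste(genes$gene_id[genes$start > chromosome_length], collapse = ", "))
  w <- as.integer(ceiling(genes$start / window_size))
  tabulate(w, nbins = n_win)
}

#' Chromosome-level gene density
#'
#' @param n_genes Number of family genes on the chromosome.
#' @param chromosome_length Chromosome length in bp (or in Mb if
#'   `length_unit = "Mb"`, convenient when replicating printed summary
#'   tables).
#' @param length_unit `"bp"` (default) or `"Mb"`.
#' @return Genes per Mb, rounded to two decimals (half away from zero).
#' @export
chromosome_density <- function(n_genes, chromosome_length,
                               length_unit = c("bp", "Mb")) {
  length_unit <- match.arg(length_unit)
  if (chromosome_length <= 0) .err("chromosome_length must be positive")
  mb <- if (length_unit == "bp") chromosome_length / 1e6 else chromosome_length
  round_half_up(n_genes / mb, 2)
}

#' Family share of a chromosome's gene complement
#'
#' Percentage of all annotated genes on a chromosome (or in the genome)
#' that belong to the focal family.
#'
#' @param n_family_genes Family genes on the chromosome.
#' @param n_all_genes All annotated genes on the chromosome (> 0).
#' @return Percentage, two decimals (half away from zero).
#' @export
family_share <- function(n_family_genes, n_all_genes) {
  if (n_all_genes <= 0) .err("n_all_genes must be positive")
  round_half_up(100 * n_family_genes / n_all_genes, 2)
}

#' Per-chromosome density profiles
#'
#' Computes, for every chromosome, the windowed family-gene counts and the
#' chromosome-level density, i.e. the data behind a per-chromosome density
#' heat-map track.
#'
#' @param gene_table Gene table from [read_gff3()].
#' @param chromosome_lengths Named numeric vector of chromosome lengths in
#'   bp (names = chromosome IDs; must cover every chromosome bearing a
#'   family gene).
#' @param window_size Window length in bp (default 1 Mb).
#' @return List of per-chromosome lists with `chromosome_id`,
#'   `chromosome_length`, `window_size`, `window_counts`, `n_family_genes`
#'   and `density_per_mb`.
#' @export
density_profile <- function(gene_table, chromosome_lengths, window_size = 1e6) {
  fam <- gene_table[gene_table$is_family, , drop = FALSE]
  chroms <- names(chromosome_lengths)
  miss <- setdiff(unique(fam$chromosome_id), chroms)
  if (length(miss))
    .err("no length given for chromosome(s): ", paste(miss, collapse = ", "))
  lapply(stats::setNames(chroms, chroms), function(ch) {
    g <- fam[fam$chromosome_id == ch, , drop = FALSE]
    len <- chromosome_lengths[[ch]]
    list(chromosome_id = ch, chromosome_length = len,
         window_size = window_size,
         window_counts = window_counts(g, len, window_size),
         n_family_genes = nrow(g),
         density_per_mb = chromosome_density(nrow(g), len))
  })
}

#' Write window densities as a BED track
#'
#' One BED line per window (0-based half-open coordinates) with the family
#' gene count in the score column.
#'
#' @param profiles Result of [density_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_bed <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    k <- seq_along(p$window_counts)
    data.frame(chrom = p$chromosome_id,
               start = as.integer((k - 1L) * p$window_size),
               end = as.integer(pmin(k * p$window_size, p$chromosome_length)),
               count = p$window_counts)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
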