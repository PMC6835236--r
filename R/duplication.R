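#' Duplication modes
#' @format Character vector of mode labels.
#' @export
DUPLICATION_MODES <- c("SINGLETON", "TANDEM", "PROXIMAL", "DISPERSED")

#' Intergenic distance between two genes on one chromosome
#'
#' Gap in bp between the nearer boundaries of two genes: start of the
#' downstream gene minus end of the upstream gene minus 1. Overlapping or
#' immediately adjacent genes have distance 0. Coordinates are 1-based
#' inclusive.
#'
#' @param gene_a,gene_b Single-row slices of a gene table (lists or
#'   one-row data.frames with `chromosome_id`, `start`, `end`).
#' @return Non-negative integer gap in bp.
#' @export
intergenic_distance <- function(gene_a, gene_b) {
  if (gene_a$chromosome_id != gene_b$chromosome_id)
    .err("intergenic_distance: genes on different chromosomes")
  if (gene_a$start > gene_b$start) { tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp }
  max(0L, as.integer(gene_b$start) - as.integer(gene_a$end) - 1L)
}

#' Canonical gene order along chromosomes
#'
#' Splits the (canonically sorted) gene table into per-chromosome ordered
#' data frames; the within-chromosome position index defines flanking
#' neighbors for the tandem test.
#'
#' @param gene_table Gene table from [read_gff3()].
#' @param family_only If `TRUE`, restrict the order to family genes;
#'   default `FALSE` keeps all annotated genes, so that an intervening
#'   non-family gene breaks strict adjacency.
#' @return Named list of per-chromosome gene tables in coordinate order.
#' @export
gene_order <- function(gene_table, family_only = FALSE) {
  tab <- sort_gene_table(gene_table)
  if (family_only) tab <- tab[tab$is_family, , drop = FALSE]
  split(tab, tab$chromosome_id)
}

#' Classify duplication modes of family genes
#'
#' Classifies every family gene as `SINGLETON`, `TANDEM`, `PROXIMAL` or
#' `DISPERSED` from its paralog-cluster membership and genomic position:
#'
#' * `SINGLETON`: its cluster has size 1;
#' * `TANDEM`: flanked (immediately preceding or following position in the
#'   full gene order of its chromosome) by a same-cluster paralog;
#' * `PROXIMAL`: not tandem, but the nearest same-cluster paralog on the
#'   same chromosome lies within `proximal_limit` bp of intergenic gap
#'   (inclusive);
#' * `DISPERSED`: the nearest same-cluster paralog is farther than that, or
#'   on another chromosome.
#'
#' Strand is ignored; flanking neighbors are taken from the full gene
#' order, so any intervening annotated gene breaks tandem adjacency. Only
#' same-cluster family genes count as paralogs.
#'
#' @param gene_table Gene table from [read_gff3()] (all genes, with
#'   `is_family` flags).
#' @param cluster_set [cluster_paralogs()] result whose member IDs are the
#'   family gene IDs.
#' @param proximal_limit Maximum intergenic gap for a proximal call, in bp
#'   (default 100000, inclusive).
#' @return `data.frame` with one row per family gene: `gene_id`, `mode`,
#'   `nearest_paralog_id`, `nearest_paralog_distance` (bp; `NA` when no
#'   same-chromosome paralog exists).
#' @export
classify_duplications <- function(gene_table, cluster_set,
                                  proximal_limit = 100000) {
  stopifnot(inherits(cluster_set, "paralog_clusters"))
  fam <- gene_table[gene_table$is_family, , drop = FALSE]
  miss <- setdiff(fam$gene_id, names(cluster_set$membership))
  if (length(miss))
    .err("family genes absent from cluster set: ", paste(miss, collapse = ", "))
  order_by_chrom <- gene_order(gene_table, family_only = FALSE)
  membership <- cluster_set$membership
  cl_size <- lengths(cluster_set$clusters)

  res <- lapply(seq_len(nrow(fam)), function(r) {
    g <- fam[r, ]
    cl <- membership[[g$gene_id]]
    ord <- order_by_chrom[[g$chromosome_id]]
    pos <- match(g$gene_id, ord$gene_id)
    if (is.na(pos)) .err("gene absent from gene order: ", g$gene_id)
    # same-cluster paralogs on this chromosome, excluding the gene itself
    sib_ids <- setdiff(cluster_set$clusters[[cl]], g$gene_id)
    sib <- ord[ord$gene_id %in% sib_ids, , drop = FALSE]
    nearest_id <- NA_character_; nearest_d <- NA_integer_
    if (nrow(sib)) {
      d <- vapply(seq_len(nrow(sib)), function(i)
        intergenic_distance(g, sib[i, ]), 0L)
      best <- min(d)
      cand <- sort(sib$gene_id[d == best])
      nearest_id <- cand[1L]; nearest_d <- best
    }
    mode <- if (cl_size[cl] == 1L) {
      "SINGLETON"
    } else {
      flank <- ord$gene_id[c(pos - 1L, pos + 1L)]
      flank <- flank[!is.na(flank)]
      if (any(flank %in% sib_ids)) "TANDEM"
      else if (!is.na(nearest_d) && nearest_d <= proximal_limit) "PROXIMAL"
      else "DISPERSED"
    }
    list(gene_id = g$gene_id, mode = mode,
         nearest_paralog_id = nearest_id,
         nearest_paralog_distance = nearest_d)
  })
  data.frame(
    gene_id = vapply(res, `[[`, "", "gene_id"),
    mode = vapply(res, `[[`, "", "mode"),
    nearest_paralog_id = vapply(res, `[[`, "", "nearest_paralog_id"),
    nearest_paralog_distance = vapply(res, `[[`, 0L, "nearest_paralog_distance"),
    stringsAsFactors = FALSE
  )
}

#' Classify one gene's duplication mode
#'
#' Convenience wrapper over [classify_duplications()] for a single gene.
#'
#' @param gene_id Family gene ID.
#' @inheritParams classify_duplications
#' @return One-row `data.frame` as in [classify_duplications()].
#' @export
classify_duplication <- function(gene_id, gene_table, cluster_set,
                                 proximal_limit = 100000) {
  calls <- classify_duplications(gene_table, cluster_set, proximal_limit)
  row <- calls[calls$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0L) .err("not a family gene: ", gene_id)
  rownames(row) <- NULL
  row
}

#' Summarize duplication modes
#'
#' Counts duplication modes per chromosome and genome-wide, with
#' genome-wide mode fractions as percentages (two decimals, half away from
#' zero) and the per-chromosome tandem + proximal share.
#'
#' @param calls `data.frame` from [classify_duplications()].
#' @param gene_table Gene table (used to place genes on chromosomes).
#' @return List with `per_chromosome` (integer matrix modes x chromosomes),
#'   `totals` (named integer vector per mode), `fractions_pct` (named
#'   numeric, percent of family genes per mode) and
#'   `tandem_proximal_share_pct` (named numeric per chromosome).
#' @export
summarize_duplication <- function(calls, gene_table) {
  idx <- match(calls$gene_id, gene_table$gene_id)
  if (anyNA(idx))
    .err("calls refer to genes absent from the gene table: ",
         paste(calls$gene_id[is.na(idx)], collapse = ", "))
  chroms <- sort(unique(gene_table$chromosome_id))
  m <- table(factor(calls$mode, levels = DUPLICATION_MODES),
             factor(gene_table$chromosome_id[idx], levels = chroms))
  m <- matrix(as.integer(m), nrow = length(DUPLICATION_MODES),
              dimnames = list(DUPLICATION_MODES, chroms))
  totals <- rowSums(m)
  n <- sum(totals)
  fractions <- if (n > 0) round_half_up(100 * totals / n, 2) else totals * 0
  share <- apply(m, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) 0 else round_half_up(100 * (col["TANDEM"] + col["PROXIMAL"]) / tot, 2)
  })
  list(per_chromosome = m, totals = totals, fractions_pct = fractions,
       tandem_proximal_share_pct = share)
}
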