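#' Domain-architecture categories
#'
#' The five architecture categories used for secreted C1q-domain proteins,
#' plus a catch-all. `SGH_C1Q`: signal peptide immediately followed by the
#' globular C1q domain. `C1Q_LIKE_TYPE_I` / `C1Q_LIKE_TYPE_II`: secreted
#' proteins with, respectively, a collagen tail or a coiled-coil region
#' N-terminal to the C1q domain. `SMULTI_C1Q`: secreted proteins with
#' multiple C1q domains. `SSUEL_C1Q`: N-terminal SUEL rhamnose-binding
#' lectin domain plus a C1q domain. `OTHER_UNCERTAIN`: anything else,
#' including non-secreted or membrane-bound proteins and likely truncated
#' annotations.
#'
#' @format Character vector of category labels.
#' @export
ARCHITECTURE_CATEGORIES <- c("SGH_C1Q", "C1Q_LIKE_TYPE_I", "C1Q_LIKE_TYPE_II",
                             "SMULTI_C1Q", "SSUEL_C1Q", "OTHER_UNCERTAIN")

#' Classify the domain architecture of one family protein
#'
#' Assigns a family protein to one architecture category from its predicted
#' features and filtered domain hits. The decision cascade is total and
#' deterministic:
#'
#' 1. count C1q-domain hits; zero hits is an error (not a family member);
#' 2. no signal peptide, or any transmembrane segment, gives
#'    `OTHER_UNCERTAIN` (the protein is not plainly secreted);
#' 3. two or more C1q domains give `SMULTI_C1Q`;
#' 4. a SUEL-domain hit N-terminal to the C1q domain gives `SSUEL_C1Q`;
#' 5. a collagen-domain hit N-terminal to the C1q domain gives
#'    `C1Q_LIKE_TYPE_I`;
#' 6. a coiled-coil segment with probability > `coil_prob` lying between
#'    the cleavage site and the C1q domain start gives `C1Q_LIKE_TYPE_II`;
#' 7. a C1q domain starting within `linker_tolerance` residues after the
#'    cleavage site gives `SGH_C1Q`;
#' 8. otherwise `OTHER_UNCERTAIN`.
#'
#' SUEL/collagen checks take precedence over the coiled-coil check, and the
#' multi-domain check over all N-terminal checks (multi-C1q proteins may or
#' may not carry a coiled-coil region).
#'
#' @param features A [protein_features()] object.
#' @param c1q_name,suel_name,collagen_name Domain names (as they appear in
#'   the hit table) identifying the C1q, SUEL and collagen profiles.
#'   Matching is by substring, case-insensitive, so PFAM-style names such
#'   as `"C1q"` or `"PF00386_C1q"` both work.
#' @param linker_tolerance Maximum gap, in residues, between the
#'   signal-peptide cleavage site and the C1q domain start for the domain
#'   to count as "immediately following" (default 30).
#' @param coil_prob Minimum coiled-coil probability (default 0.5,
#'   exclusive).
#' @return A list of class `architecture_call` with `protein_id`,
#'   `category` and `n_c1q_domains`.
#' @export
classify_architecture <- function(features,
                                  c1q_name = "C1q",
                                  suel_name = "SUEL",
                                  collagen_name = "Collagen",
                                  linker_tolerance = 30,
                                  coil_prob = 0.5) {
  stopifnot(inherits(features, "protein_features"))
  hits <- features$domain_hits
  is_type <- function(name) grepl(name, hits$domain_name, ignore.case = TRUE)
  c1q <- hits[is_type(c1q_name), , drop = FALSE]
  n_c1q <- nrow(c1q)
  if (n_c1q == 0L)
    .err("protein ", features$protein_id,
         " has no C1q domain hit: not a family member")
  c1q_start <- min(c1q$ali_start)
  category <- NULL
  if (!features$has_signal_peptide || nrow(features$tm_segments) > 0L) {
    category <- "OTHER_UNCERTAIN"
  } else if (n_c1q >= 2L) {
    category <- "SMULTI_C1Q"
  } else {
    before_c1q <- function(name) {
      h <- hits[is_type(name), , drop = FALSE]
      nrow(h) > 0L && any(h$ali_end < c1q_start)
    }
    cleave <- features$cleavage_pos
    coils <- features$coiled_coil_segments
    coil_between <- nrow(coils) > 0L &&
      any(coils[, "prob"] > coil_prob &
            coils[, "start"] > cleave & coils[, "end"] < c1q_start)
    if (before_c1q(suel_name)) {
      category <- "SSUEL_C1Q"
    } else if (before_c1q(collagen_name)) {
      category <- "C1Q_LIKE_TYPE_I"
    } else if (coil_between) {
      category <- "C1Q_LIKE_TYPE_II"
    } else if (c1q_start - cleave - 1 <= linker_tolerance) {
      category <- "SGH_C1Q"
    } else {
      category <- "OTHER_UNCERTAIN"
    }
  }
  structure(list(protein_id = features$protein_id,
                 category = category,
                 n_c1q_domains = n_c1q),
            class = "architecture_call")
}

#' Classify many proteins at once
#'
#' @param feature_list List of [protein_features()] objects.
#' @param ... Passed to [classify_architecture()].
#' @return A `data.frame` with columns `protein_id`, `category`,
#'   `n_c1q_domains`, one row per protein, in input order.
#' @export
classify_architectures <- function(feature_list, ...) {
  calls <- lapply(feature_list, classify_architecture, ...)
  data.frame(
    protein_id = vapply(calls, `[[`, "", "protein_id"),
    category = vapply(calls, `[[`, "", "category"),
    n_c1q_domains = vapply(calls, `[[`, 0L, "n_c1q_domains"),
    stringsAsFactors = FALSE
  )
}

#' Per-chromosome architecture count matrix
#'
#' Tabulates architecture calls by chromosome, in the layout of a
#' family-census summary table: one row per category, one column per
#' chromosome, plus a `Total` row and column.
#'
#' @param calls `data.frame` from [classify_architectures()] (protein IDs
#'   must equal gene IDs, or supply a mapping via the `gene_id` column).
#' @param gene_table Gene table from [read_gff3()]; every classified
#'   protein must map to a gene.
#' @return Integer matrix `(categories + Total) x (chromosomes + Total)`.
#'   Row and column totals each sum to the number of classified genes.
#' @export
summarize_architectures <- function(calls, gene_table) {
  ids <- if ("gene_id" %in% colnames(calls)) calls$gene_id else calls$protein_id
  idx <- match(ids, gene_table$gene_id)
  if (anyNA(idx))
    .err("proteins not mapped to any gene: ",
         paste(ids[is.na(idx)], collapse = ", "))
  chroms <- sort(unique(gene_table$chromosome_id))
  m <- table(factor(calls$category, levels = ARCHITECTURE_CATEGORIES),
             factor(gene_table$chromosome_id[idx], levels = chroms))
  m <- matrix(as.integer(m), nrow = length(ARCHITECTURE_CATEGORIES),
              dimnames = list(ARCHITECTURE_CATEGORIES, chroms))
  m <- rbind(m, Total = colSums(m))
  cbind(m, Total = rowSums(m))
}
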