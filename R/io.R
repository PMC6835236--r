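#' Read gene coordinates from a GFF3 annotation
#'
#' Builds the unified gene table from a GFF3 file. Only features of type
#' `gene` are retained; each becomes one row with 1-based inclusive
#' coordinates, the strand, and a family-membership flag set from
#' `family_ids`.
#'
#' @param path Path to a GFF3 file.
#' @param family_ids Character vector of gene IDs belonging to the focal
#'   gene family. IDs in this list that are absent from the annotation are
#'   reported with a warning.
#' @return A `data.frame` with columns `gene_id`, `chromosome_id`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`) and `is_family` (logical), sorted by
#'   `(chromosome_id, start, end, gene_id)`.
#' @details Malformed lines (wrong column count, non-numeric or inverted
#'   coordinates) abort with the offending line number. Gene IDs are taken
#'   from the `ID` attribute.
#' @seealso [write_gene_table()], [gene_order()]
#' @export
read_gff3 <- function(path, family_ids = character()) {
  if (!file.exists(path)) .err("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      .err("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.numeric(f[4]))) ||
        is.na(suppressWarnings(as.numeric(f[5]))))
      .err("malformed GFF3 at line ", i, ": non-numeric coordinates")
    if (as.numeric(f[5]) < as.numeric(f[4]))
      .err("malformed GFF3 at line ", i, ": end < start")
  }
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  id <- as.character(genes$ID)
  if (anyNA(id) || any(!nzchar(id)))
    .err("gene feature without an ID attribute")
  if (anyDuplicated(id))
    .err("duplicate gene IDs in GFF3: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  tab <- data.frame(
    gene_id = id,
    chromosome_id = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    is_family = id %in% family_ids,
    stringsAsFactors = FALSE
  )
  missing <- setdiff(family_ids, id)
  if (length(missing))
    warning("family IDs not found in annotation: ",
            paste(missing, collapse = ", "), call. = FALSE)
  sort_gene_table(tab)
}

#' Sort a gene table into canonical order
#'
#' Orders genes by chromosome, then start, with ties broken by end and then
#' gene ID, giving a deterministic gene order for any input permutation.
#'
#' @param tab Gene table as returned by [read_gff3()].
#' @return The sorted gene table with fresh row names.
#' @export
sort_gene_table <- function(tab) {
  o <- order(tab$chromosome_id, tab$start, tab$end, tab$gene_id, method = "radix")
  out <- tab[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read the gene table as TSV
#'
#' Round-trip safe: `read_gene_table(write_gene_table(tab, f))` reproduces
#' an identical table.
#'
#' @param tab Gene table.
#' @param path Output path.
#' @return `write_gene_table` returns `path` invisibly; `read_gene_table`
#'   returns the gene table.
#' @export
write_gene_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "integer",
                                          "integer", "character", "logical"),
                           stringsAsFactors = FALSE)
  tab
}

#' Read a FASTA file into a sequence set
#'
#' Headers are tokenized to the first whitespace and sequences are
#' upper-cased. Duplicate IDs abort; an empty file yields an empty set with
#' a warning. Protein sets are checked for internal stop symbols.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"AA"` for protein or `"DNA"` for nucleotide sequences.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path, alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .err("FASTA file not found: ", path)
  set <- if (alphabet == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(set)
  }
  names(set) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  dup <- names(set)[duplicated(names(set))]
  if (length(dup))
    .err("duplicate sequence IDs in FASTA: ", paste(unique(dup), collapse = ", "))
  up <- toupper(as.character(set))
  set <- if (alphabet == "AA") Biostrings::AAStringSet(up)
         else Biostrings::DNAStringSet(up)
  if (alphabet == "AA") {
    has_stop <- vapply(as.character(set),
                       function(s) grepl("\\*", sub("\\*$", "", s)), TRUE)
    if (any(has_stop))
      .err("internal stop symbol in protein sequence(s): ",
           paste(names(set)[has_stop], collapse = ", "))
  }
  set
}

#' Read and filter profile-domain hits
#'
#' Reads per-protein domain hits either from a simplified 6-column TSV
#' (`protein_id`, `domain_name`, `ali_start`, `ali_end`, `e_value`,
#' `model_coverage`) or from an HMMER3 `--domtblout` table. Hits above the
#' e-value threshold or covering too little of the profile model (likely
#' partial domains from truncated annotations) are discarded.
#'
#' @param path Path to the hits file.
#' @param e_threshold Maximum e-value retained (default 0.05).
#' @param min_coverage Minimum fraction of the profile model covered for a
#'   hit to be treated as a complete domain (default 0.6).
#' @return A `data.frame` of retained hits sorted by
#'   `(protein_id, ali_start)`, with the six columns above.
#' @export
read_domain_table <- function(path, e_threshold = 0.05, min_coverage = 0.6) {
  if (!file.exists(path)) .err("domain table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    return(.empty_domain_table())
  first <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(first) == 6L) {
    hdr <- identical(tolower(first[1]), "protein_id")
    tab <- utils::read.table(text = body, sep = "\t", header = hdr,
                             stringsAsFactors = FALSE)
    colnames(tab) <- c("protein_id", "domain_name", "ali_start", "ali_end",
                       "e_value", "model_coverage")
  } else {
    # HMMER3 domtblout: whitespace table; target=col1, query(model)=col4,
    # model length=col6, i-Evalue=col13, hmm from/to=col16/17, ali from/to=col18/19
    f <- strsplit(trimws(body), "\\s+")
    if (any(lengths(f) < 19L)) .err("unrecognized domain table format")
    g <- function(k) vapply(f, `[`, "", k)
    tab <- data.frame(
      protein_id = g(1), domain_name = g(4),
      ali_start = suppressWarnings(as.integer(g(18))),
      ali_end = suppressWarnings(as.integer(g(19))),
      e_value = suppressWarnings(as.numeric(g(13))),
      model_coverage = (suppressWarnings(as.numeric(g(17))) -
                          suppressWarnings(as.numeric(g(16))) + 1) /
                       suppressWarnings(as.numeric(g(6))),
      stringsAsFactors = FALSE
    )
  }
  for (col in c("ali_start", "ali_end", "e_value", "model_coverage")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) .err("non-numeric value in domain table column '", col, "'")
    tab[[col]] <- v
  }
  if (any(tab$e_value < 0)) .err("negative e-value in domain table")
  if (any(tab$ali_start > tab$ali_end)) .err("domain hit with ali_start > ali_end")
  keep <- tab$e_value <= e_threshold & tab$model_coverage >= min_coverage
  tab <- tab[keep, , drop = FALSE]
  tab$ali_start <- as.integer(tab$ali_start)
  tab$ali_end <- as.integer(tab$ali_end)
  tab <- tab[order(tab$protein_id, tab$ali_start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.empty_domain_table <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             ali_start = integer(), ali_end = integer(),
             e_value = numeric(), model_coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' Read per-protein feature annotations
#'
#' Reads the TSV of externally predicted protein features (signal peptide,
#' transmembrane segments, coiled-coil segments) with columns
#' `protein_id`, `feature_type`, `start`, `end`, `score`. Recognized
#' feature types are `signal_peptide` (end = cleavage position),
#' `transmembrane` and `coiled_coil` (score = probability).
#'
#' @param path Path to the feature TSV.
#' @return A `data.frame` with the five columns above.
#' @seealso [protein_features()] which assembles these rows, the domain
#'   hits and the protein lengths into classifier input.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) .err("feature table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("protein_id", "feature_type", "start", "end", "score")
  if (!all(need %in% colnames(tab)))
    .err("feature table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$feature_type),
                 c("signal_peptide", "transmembrane", "coiled_coil"))
  if (length(bad))
    .err("unknown feature_type(s): ", paste(bad, collapse = ", "))
  tab[, need]
}

#' Assemble classifier input for one protein
#'
#' Bundles a protein's length, signal-peptide call, transmembrane and
#' coiled-coil segments and its filtered domain hits into the structure
#' consumed by [classify_architecture()].
#'
#' @param protein_id Protein identifier.
#' @param length Protein length in amino acids.
#' @param feature_table Feature rows (all proteins) from
#'   [read_feature_table()]; rows for other proteins are ignored.
#' @param domain_table Filtered hits from [read_domain_table()].
#' @return An object of class `protein_features`: a list with elements
#'   `protein_id`, `length`, `has_signal_peptide`, `cleavage_pos`,
#'   `tm_segments`, `coiled_coil_segments` (each a matrix with columns
#'   start, end and, for coils, prob) and `domain_hits`.
#' @export
protein_features <- function(protein_id, length, feature_table = NULL,
                             domain_table = NULL) {
  ft <- if (is.null(feature_table)) NULL
        else feature_table[feature_table$protein_id == protein_id, , drop = FALSE]
  seg <- function(type, with_prob = FALSE) {
    if (is.null(ft)) rows <- NULL
    else rows <- ft[ft$feature_type == type, , drop = FALSE]
    if (is.null(rows) || nrow(rows) == 0L)
      return(matrix(numeric(), ncol = if (with_prob) 3L else 2L,
                    dimnames = list(NULL, c("start", "end", if (with_prob) "prob"))))
    m <- cbind(start = rows$start, end = rows$end,
               if (with_prob) cbind(prob = rows$score))
    m
  }
  sp <- if (is.null(ft)) NULL
        else ft[ft$feature_type == "signal_peptide", , drop = FALSE]
  has_sp <- !is.null(sp) && nrow(sp) > 0L
  dom <- if (is.null(domain_table)) .empty_domain_table()
         else domain_table[domain_table$protein_id == protein_id, , drop = FALSE]
  out <- list(
    protein_id = protein_id,
    length = as.integer(length),
    has_signal_peptide = has_sp,
    cleavage_pos = if (has_sp) as.integer(sp$end[1]) else NA_integer_,
    tm_segments = seg("transmembrane"),
    coiled_coil_segments = seg("coiled_coil", with_prob = TRUE),
    domain_hits = dom
  )
  segs <- rbind(out$tm_segments[, 1:2, drop = FALSE],
                out$coiled_coil_segments[, 1:2, drop = FALSE])
  if (nrow(segs) && (any(segs < 1) || any(segs > out$length)))
    .err("feature interval outside [1, length] for protein ", protein_id)
  structure(out, class = "protein_features")
}

#' @export
print.protein_features <- function(x, ...) {
  cat("protein_features:", x$protein_id, sprintf("(%d aa)\n", x$length))
  cat("  signal peptide:",
      if (x$has_signal_peptide) sprintf("yes (cleavage %d)", x$cleavage_pos)
      else "no", "\n")
  cat("  TM segments:", nrow(x$tm_segments),
      " coiled-coil:", nrow(x$coiled_coil_segments),
      " domain hits:", nrow(x$domain_hits), "\n")
  invisible(x)
}
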