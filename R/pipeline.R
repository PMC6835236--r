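#' Pipeline configuration
#'
#' Collects input paths, thresholds and output settings for
#' [run_pipeline()]. All thresholds default to the values used throughout
#' the package's analyses; any of them can be overridden here.
#'
#' @param gff Path to the GFF3 annotation.
#' @param proteins Path to the family protein FASTA.
#' @param features Path to the protein feature TSV
#'   ([read_feature_table()]).
#' @param domains Path to the domain-hit table ([read_domain_table()]).
#' @param family_ids Character vector of family gene IDs, or a path to a
#'   one-column text file of IDs.
#' @param chromosome_lengths Named numeric vector of chromosome lengths in
#'   bp, or a path to a two-column TSV (`chromosome_id`, `length`).
#' @param out_dir Output directory (created if needed).
#' @param cds Optional path to the family CDS FASTA (required for the
#'   selection stage).
#' @param run_selection Run the per-site selection stage on large
#'   clusters (default `FALSE`).
#' @param method_sites Optional path to external per-method positive-site
#'   lists ([read_method_sites()]) merged into the consensus support.
#' @param identity_threshold Paralog-cluster identity threshold (default
#'   0.5, strict).
#' @param proximal_limit Proximal-duplication distance limit in bp
#'   (default 100000).
#' @param e_threshold,min_coverage Domain-hit filters (defaults 0.05,
#'   0.6).
#' @param large_cluster_size Minimum cluster size for the large-cluster
#'   report and the selection stage (default 10).
#' @param alpha Per-site selection significance threshold (default 0.05).
#' @param linker_tolerance Signal-peptide-to-domain linker tolerance in aa
#'   (default 30).
#' @param window_size Density window in bp (default 1 Mb).
#' @param seed RNG seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gff, proteins, features, domains, family_ids,
                            chromosome_lengths, out_dir,
                            cds = NULL, run_selection = FALSE,
                            method_sites = NULL,
                            identity_threshold = 0.5,
                            proximal_limit = 100000,
                            e_threshold = 0.05, min_coverage = 0.6,
                            large_cluster_size = 10, alpha = 0.05,
                            linker_tolerance = 30, window_size = 1e6,
                            seed = 1) {
  if (is.character(family_ids) && length(family_ids) == 1L &&
      file.exists(family_ids))
    family_ids <- readLines(family_ids, warn = FALSE)
  if (is.character(chromosome_lengths) && length(chromosome_lengths) == 1L) {
    tab <- utils::read.table(chromosome_lengths, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    chromosome_lengths <- stats::setNames(tab$length, tab$chromosome_id)
  }
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            proximal_limit > 0, e_threshold >= 0, min_coverage >= 0,
            min_coverage <= 1, large_cluster_size >= 1,
            alpha > 0, alpha < 1, linker_tolerance >= 0, window_size > 0)
  structure(list(gff = gff, proteins = proteins, features = features,
                 domains = domains, family_ids = family_ids,
                 chromosome_lengths = chromosome_lengths, out_dir = out_dir,
                 cds = cds, run_selection = run_selection,
                 method_sites = method_sites,
                 identity_threshold = identity_threshold,
                 proximal_limit = proximal_limit,
                 e_threshold = e_threshold, min_coverage = min_coverage,
                 large_cluster_size = large_cluster_size, alpha = alpha,
                 linker_tolerance = linker_tolerance,
                 window_size = window_size, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full family-expansion analysis pipeline
#'
#' Executes the stages in order -- input parsing, architecture
#' classification, paralog clustering, duplication-mode classification,
#' density profiling and (optionally) per-site selection analysis of large
#' clusters -- writing all tabular outputs plus a run log into
#' `config$out_dir`. Rerunning with the same configuration produces
#' identical files.
#'
#' The selection stage analyzes each cluster of at least
#' `large_cluster_size` members whose CDS are length-identical (an
#' in-frame alignment without indels); clusters with length variation
#' need an externally built codon-aware alignment and are skipped with a
#' log note. External positive-site lists, when supplied, enter the
#' consensus support merge.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `gene_table`, `architecture_calls`,
#'   `architecture_matrix`, `clusters`, `identity`,
#'   `duplication_calls`, `duplication_summary`, `density`, `selection`
#'   (named list per analyzed cluster, or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", sprintf(...))
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e)
      .err("pipeline aborted in stage '", name, "': ", conditionMessage(e)))
  }
  logf("famdup %s on R %s", as.character(utils::packageVersion("famdup")),
       paste(R.version$major, R.version$minor, sep = "."))
  logf("thresholds: identity>%g proximal<=%g bp e-value<=%g coverage>=%g cluster>=%d alpha=%g linker<=%d aa window=%g bp seed=%d",
       config$identity_threshold, config$proximal_limit, config$e_threshold,
       config$min_coverage, config$large_cluster_size, config$alpha,
       config$linker_tolerance, config$window_size, config$seed)
  set.seed(config$seed)

  out <- list()
  stage("io", {
    out$gene_table <- read_gff3(config$gff, config$family_ids)
    out$proteins <- read_fasta(config$proteins, "AA")
    domains <- read_domain_table(config$domains, config$e_threshold,
                                 config$min_coverage)
    features <- read_feature_table(config$features)
    out$domains <- domains; out$features <- features
    write_gene_table(out$gene_table, file.path(config$out_dir, "genes.tsv"))
    logf("io: %d genes (%d family), %d proteins, %d domain hits",
         nrow(out$gene_table), sum(out$gene_table$is_family),
         length(out$proteins), nrow(domains))
  })
  fam_ids <- out$gene_table$gene_id[out$gene_table$is_family]
  miss <- setdiff(fam_ids, names(out$proteins))
  if (length(miss))
    .err("family genes without protein sequence: ", paste(miss, collapse = ", "))
  fam_prot <- out$proteins[fam_ids]

  stage("architecture", {
    fl <- lapply(fam_ids, function(id)
      protein_features(id, Biostrings::width(fam_prot[id]),
                       out$features, out$domains))
    out$architecture_calls <- classify_architectures(
      fl, linker_tolerance = config$linker_tolerance)
    out$architecture_matrix <- summarize_architectures(
      out$architecture_calls, out$gene_table)
    utils::write.table(out$architecture_calls,
                       file.path(config$out_dir, "architecture.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$architecture_matrix,
                       file.path(config$out_dir, "architecture_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    logf("architecture: %s",
         paste(names(table(out$architecture_calls$category)),
               table(out$architecture_calls$category),
               sep = "=", collapse = " "))
  })

  stage("paralogs", {
    out$identity <- identity_matrix(fam_prot)
    out$clusters <- cluster_paralogs(out$identity,
                                     threshold = config$identity_threshold)
    write_cluster_table(out$clusters,
                        file.path(config$out_dir, "clusters.tsv"))
    logf("paralogs: %d clusters, %d large (>=%d members)",
         length(out$clusters$clusters),
         length(large_clusters(out$clusters, config$large_cluster_size)),
         config$large_cluster_size)
  })

  stage("duplication", {
    out$duplication_calls <- classify_duplications(
      out$gene_table, out$clusters, config$proximal_limit)
    out$duplication_summary <- summarize_duplication(
      out$duplication_calls, out$gene_table)
    utils::write.table(out$duplication_calls,
                       file.path(config$out_dir, "duplication.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$duplication_summary$per_chromosome,
                       file.path(config$out_dir, "duplication_summary.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    logf("duplication: %s",
         paste(names(out$duplication_summary$totals),
               out$duplication_summary$totals, sep = "=", collapse = " "))
  })

  stage("landscape", {
    out$density <- density_profile(out$gene_table, config$chromosome_lengths,
                                   config$window_size)
    write_density_bed(out$density,
                      file.path(config$out_dir, "density_windows.bed"))
    summ <- data.frame(
      chromosome_id = names(out$density),
      length_bp = vapply(out$density, `[[`, 0, "chromosome_length"),
      n_family_genes = vapply(out$density, `[[`, 0L, "n_family_genes"),
      density_per_mb = vapply(out$density, `[[`, 0, "density_per_mb"))
    utils::write.table(summ, file.path(config$out_dir, "density_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("landscape: genome density %.2f genes/Mb",
         chromosome_density(sum(summ$n_family_genes), sum(summ$length_bp)))
  })

  out$selection <- NULL
  if (isTRUE(config$run_selection)) stage("selection", {
    if (is.null(config$cds))
      .err("selection stage requires a CDS FASTA (config$cds)")
    cds <- read_fasta(config$cds, "DNA")
    ext <- if (!is.null(config$method_sites))
      read_method_sites(config$method_sites) else NULL
    big <- large_clusters(out$clusters, config$large_cluster_size)
    res <- list()
    for (k in seq_along(big)) {
      mem <- big[[k]]
      if (length(setdiff(mem, names(cds)))) {
        logf("selection: cluster %d skipped (missing CDS)", k); next
      }
      lens <- nchar(as.character(cds[mem]))
      if (length(unique(lens)) != 1L) {
        logf("selection: cluster %d skipped (CDS length variation; supply a codon-aware alignment)", k)
        next
      }
      aln <- as_codon_alignment(as.character(cds[mem]))
      aln <- trim_alignment(aln)
      tr <- nj_tree(codon_distance_matrix(aln))
      calls <- site_selection(tr, aln, alpha = config$alpha)
      methods <- c(list(counting = calls$site_index[
        calls$selection_class == "POSITIVE"]), ext)
      calls$support <- consensus_support(methods, nrow(calls))
      res[[paste0("cluster_", k)]] <- list(members = mem, tree = tr,
                                           calls = calls)
      ape::write.tree(tr, file.path(config$out_dir,
                                    sprintf("cluster_%d.nwk", k)))
      utils::write.table(calls,
                         file.path(config$out_dir,
                                   sprintf("cluster_%d_sites.tsv", k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("selection: cluster %d (%d genes): %d positive, %d negative sites",
           k, length(mem), sum(calls$selection_class == "POSITIVE"),
           sum(calls$selection_class == "NEGATIVE"))
    }
    out$selection <- res
  })
  logf("pipeline complete; outputs in %s", config$out_dir)
  invisible(out)
}
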