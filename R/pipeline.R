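#' Pipeline configuration
#'
#' Bundles every stage parameter. Two presets bind the alignment thresholds
#' exactly: `"salmonid-strict"` (strict thresholds, for closely related
#' species where paralogy must be resolved) and `"all-species-relaxed"`
#' (relaxed thresholds, for distant comparisons).
#'
#' @param preset `"salmonid-strict"` or `"all-species-relaxed"`.
#' @param trim_length common locus length in bp (default 60).
#' @param dust_window,dust_threshold low-complexity masking parameters
#'   (see [mask_low_complexity()]).
#' @param repeat_library optional repeat FASTA path or `DNAStringSet`.
#' @param merge a [merge_policy()] for within-species cross-study merging.
#' @param thresholds optional [alignment_thresholds()] override; defaults to
#'   the preset's thresholds.
#' @param seed_k exact-seed length for alignment (default 11).
#' @param score_floor minimum reported alignment score (default 20).
#' @param cluster_mode `"clique"` or `"component"`.
#' @param min_species minimum taxon coverage per cluster (default 2).
#' @param required_groups species-group constraints for [filter_coverage()].
#' @param gene_db optional gene FASTA path or `DNAStringSet` for genic
#'   annotation.
#' @param annotation an [annotation_config()].
#' @param tree_model `"p"` (default; variant-only sites are strongly
#'   ascertained, so the uncorrected proportion is the safer internal
#'   distance) or `"JC69"`.
#' @param n_bootstrap bootstrap replicates (default 1000; 0 skips
#'   bootstrapping and reports the point tree only).
#' @param seed master seed for the seeded stages (bootstrap).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("salmonid-strict", "all-species-relaxed"),
                            trim_length = 60L, dust_window = 12L,
                            dust_threshold = 2, repeat_library = NULL,
                            merge = merge_policy(), thresholds = NULL,
                            seed_k = 11L, score_floor = 20,
                            cluster_mode = c("clique", "component"),
                            min_species = 2L, required_groups = NULL,
                            gene_db = NULL, annotation = annotation_config(),
                            tree_model = c("p", "JC69"),
                            n_bootstrap = 1000L, seed = 1L) {
  preset <- match.arg(preset)
  cluster_mode <- match.arg(cluster_mode)
  tree_model <- match.arg(tree_model)
  th <- thresholds %||% alignment_thresholds(
    if (preset == "salmonid-strict") "strict" else "relaxed"
  )
  structure(list(
    preset = preset, trim_length = as.integer(trim_length),
    dust_window = as.integer(dust_window), dust_threshold = dust_threshold,
    repeat_library = repeat_library, merge = merge, thresholds = th,
    seed_k = as.integer(seed_k), score_floor = score_floor,
    cluster_mode = cluster_mode, min_species = as.integer(min_species),
    required_groups = required_groups, gene_db = gene_db,
    annotation = annotation, tree_model = tree_model,
    n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Lists every violation found: unreadable paths, out-of-range parameters,
#' and preset-threshold overrides (reported as warnings in the report,
#' prefixed `"warning:"`, since overriding a preset is legal but worth
#' flagging).
#'
#' @param config a [pipeline_config()].
#' @return Character vector of problems; empty when valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  if (!inherits(config, "pipeline_config")) {
    return("not a pipeline_config object")
  }
  if (config$trim_length < 1L) problems <- c(problems, "trim_length must be positive")
  if (config$min_species < 2L) problems <- c(problems, "min_species must be >= 2")
  if (config$seed_k < 4L) problems <- c(problems, "seed_k must be >= 4")
  if (config$n_bootstrap < 0L) problems <- c(problems, "n_bootstrap must be >= 0")
  for (p in c("repeat_library", "gene_db")) {
    v <- config[[p]]
    if (is.character(v) && !file.exists(v)) {
      problems <- c(problems, sprintf("%s path does not exist: %s", p, v))
    }
  }
  bound <- alignment_thresholds(
    if (config$preset == "salmonid-strict") "strict" else "relaxed"
  )
  for (f in c("identity_min", "aln_length_min", "mismatch_max")) {
    if (!isTRUE(all.equal(config$thresholds[[f]], bound[[f]]))) {
      problems <- c(problems, sprintf(
        "warning: preset %s binds %s = %s but config overrides it to %s",
        config$preset, f, bound[[f]], config$thresholds[[f]]
      ))
    }
  }
  problems
}

#' Run the full ortholog-clustering and phylogeny pipeline
#'
#' Stages run in fixed order: preprocess (trim, mask, within-species
#' cross-study merge) -> all-vs-all seeded alignment per species pair ->
#' best-hit, threshold and uniqueness filtering -> RBH graph -> cluster
#' inference and paralogy/multiplicity/coverage filters -> per-cluster
#' alignment and variant extraction -> supermatrix -> optional genic
#' annotation -> distance tree with bootstrap. Every stage's counts are
#' logged; identical input and config give identical output.
#'
#' @param loci a [rad_loci] table covering all species and studies (e.g.
#'   from [simulate_dataset()] or [read_loci_fasta()] row-bound over a
#'   manifest).
#' @param config a [pipeline_config()]. Hard validation failures abort.
#' @param out_dir optional directory; when given, intermediates (merged
#'   FASTA, unique hits, clusters, PHYLIP supermatrix, provenance, newick
#'   tree, summary table) are written there.
#' @return A list of class `rad_pipeline_result`: `loci` (merged), `hits`
#'   (unique best hits), `clusters`, `supermatrix`, `annotation` (or NULL),
#'   `tree` (or NULL, with `tree_error` explaining why), `summary` (one-row
#'   data frame mirroring the per-analysis report columns), `log`.
#' @export
run_pipeline <- function(loci, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(loci, "rad_loci"))
  problems <- validate_config(config)
  hard <- problems[!startsWith(problems, "warning:")]
  if (length(hard)) stop("invalid config: ", paste(hard, collapse = "; "))
  for (w in problems[startsWith(problems, "warning:")]) warning(w)
  log <- list()

  ## --- preprocess ---
  species <- sort(unique(loci$species))
  merged <- list()
  for (sp in species) {
    x <- loci[loci$species == sp, , drop = FALSE]
    class(x) <- c("rad_loci", "data.frame")
    x <- trim_loci(x, config$trim_length)
    log[[paste0("trim_", sp)]] <- attr(x, "trim_log")
    x <- mask_low_complexity(x, config$dust_window, config$dust_threshold)
    if (!is.null(config$repeat_library)) {
      x <- mask_repeat_library(x, config$repeat_library)
    }
    x <- merge_studies(x, config$merge, k = config$seed_k)
    log[[paste0("merge_", sp)]] <- attr(x, "merge_log")
    merged[[sp]] <- x
  }
  all_merged <- do.call(rbind, merged)
  class(all_merged) <- c("rad_loci", "data.frame")

  ## --- pairwise alignment, best hits, filtering, uniqueness ---
  kc_f <- lapply(merged, function(x) unmasked_kmers(x$seq, x$mask, config$seed_k))
  kc_r <- lapply(merged, function(x) {
    unmasked_kmers(reverse_complement(x$seq), lapply(x$mask, rev), config$seed_k)
  })
  unique_hits <- list()
  n_sp <- length(species)
  for (i in seq_len(max(0L, n_sp - 1L))) {
    for (j in (i + 1L):n_sp) {
      a <- merged[[species[i]]]; b <- merged[[species[j]]]
      if (nrow(a) == 0L || nrow(b) == 0L) next
      hits <- align_all_pairs(a, b, k = config$seed_k,
                              score_floor = config$score_floor,
                              query_kmers = kc_f[[species[i]]],
                              subject_kmers = kc_f[[species[j]]],
                              subject_kmers_rc = kc_r[[species[j]]])
      for (dir_hits in list(hits, swap_hits(hits))) {
        h <- extract_best_hits(dir_hits)
        h <- filter_hits(h, config$thresholds)
        h <- filter_unique(h)
        unique_hits[[length(unique_hits) + 1L]] <- h
      }
    }
  }
  unique_hits <- if (length(unique_hits)) {
    do.call(rbind, unique_hits)
  } else {
    empty_hits()
  }
  class(unique_hits) <- c("pairwise_hits", "data.frame")
  log$n_unique_hits <- nrow(unique_hits)

  ## --- clustering and filters ---
  graph <- build_rbh_graph(unique_hits)
  clusters <- infer_clusters(graph, config$cluster_mode)
  log$n_clusters_raw <- length(unique(clusters$cluster_id))
  clusters <- remove_multi_cluster_sequences(clusters)
  log$n_removed_multicluster <- attr(clusters, "n_removed")
  clusters <- remove_multi_species_duplicates(clusters)
  log$n_removed_multispecies <- attr(clusters, "n_removed")
  clusters <- filter_coverage(clusters, config$min_species,
                              config$required_groups, known_species = species)
  log$n_removed_coverage <- attr(clusters, "n_removed")
  log$n_clusters <- length(unique(clusters$cluster_id))

  ## --- supermatrix ---
  seqs <- setNames(all_merged$seq, all_merged$id)
  ids <- unique(clusters$cluster_id)
  variant_list <- lapply(ids, function(cid) {
    extract_variants(align_cluster(
      clusters[clusters$cluster_id == cid, , drop = FALSE], seqs
    ))
  })
  supermatrix <- concatenate_variants(variant_list, species)
  stats <- matrix_stats(supermatrix)

  ## --- genic annotation (optional) ---
  annotation <- NULL
  if (!is.null(config$gene_db)) {
    member_loci <- all_merged[all_merged$id %in% clusters$locus_id, , drop = FALSE]
    class(member_loci) <- c("rad_loci", "data.frame")
    locus_ann <- annotate_loci(member_loci, config$gene_db, config$annotation)
    annotation <- annotate_clusters(clusters, locus_ann)
    annotation$locus_annotation <- locus_ann
  }

  ## --- tree ---
  tree <- NULL; tree_error <- NULL
  if (length(species) >= 3L && ncol(supermatrix$matrix) >= 1L) {
    tree <- tryCatch({
      if (config$n_bootstrap >= 1L) {
        bootstrap_support(supermatrix, config$n_bootstrap,
                          seed = config$seed, model = config$tree_model)
      } else {
        nj_tree(variant_distances(supermatrix, config$tree_model))
      }
    }, error = function(e) {
      tree_error <<- conditionMessage(e)
      NULL
    })
  } else {
    tree_error <- "tree not estimated: need >= 3 species and >= 1 variant column"
  }

  summary <- data.frame(
    preset = config$preset,
    cluster_mode = config$cluster_mode,
    min_taxon_coverage = config$min_species,
    n_orthologous_loci = log$n_clusters,
    n_genic = if (is.null(annotation)) NA_integer_ else annotation$n_genic,
    pct_genic = if (is.null(annotation)) NA_real_ else annotation$pct_genic,
    n_variants = stats$n_variants,
    missing_min = stats$missing_range[1],
    missing_max = stats$missing_range[2],
    pct_missing = stats$pct_missing,
    stringsAsFactors = FALSE
  )

  result <- structure(list(
    loci = all_merged, hits = unique_hits, clusters = clusters,
    supermatrix = supermatrix, annotation = annotation,
    tree = tree, tree_error = tree_error, summary = summary, log = log,
    config = config
  ), class = "rad_pipeline_result")

  if (!is.null(out_dir)) write_pipeline_bundle(result, out_dir)
  result
}

write_pipeline_bundle <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_loci_fasta(result$loci, file.path(out_dir, "merged_loci.fasta"))
  write_hits(result$hits, file.path(out_dir, "unique_hits.tsv"))
  write_clusters(result$clusters, file.path(out_dir, "clusters.tsv"))
  sm <- result$supermatrix
  if (length(sm$species) >= 2L && ncol(sm$matrix) >= 1L) {
    write_phylip(sm, file.path(out_dir, "supermatrix.phy"))
    write.table(sm$provenance, file.path(out_dir, "provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$tree)) {
    ape::write.tree(result$tree, file.path(out_dir, "tree.nwk"))
  }
  write.table(result$summary, file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.rad_pipeline_result <- function(x, ...) {
  cat("radortho pipeline result\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tree_error)) cat("tree:", x$tree_error, "\n")
  invisible(x)
}
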