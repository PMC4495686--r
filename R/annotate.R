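#' Annotation search configuration
#'
#' Significance of a locus-vs-gene alignment is an E-value-like statistic
#' computed from the raw local alignment score S with a Karlin-Altschul-style
#' formula, `E = K * m * n * exp(-lambda * S)`, where m is the locus length
#' and n the summed database length. The constants are fixed, documented
#' defaults (nucleotide mode: lambda 1.33, K 0.621, the classical ungapped
#' +1/-2 values; translated mode: lambda 0.267, K 0.041, the classical
#' gapped BLOSUM62 values), so a given threshold is reproducible within this
#' tool; they are not a reimplementation of any external program's
#' statistics.
#'
#' @param evalue_threshold significance cut-off (> 0; default 1e-5).
#' @param search_mode `"nucleotide"` or `"translated"` (all 6 reading frames
#'   of the locus against all 6 frames of each gene).
#' @param min_seed exact seed length for the candidate prefilter (default 11
#'   nt; translated mode uses `max(3, min_seed %/% 3)` residues).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(evalue_threshold = 1e-5,
                              search_mode = c("nucleotide", "translated"),
                              min_seed = 11L) {
  search_mode <- match.arg(search_mode)
  stopifnot(evalue_threshold > 0, min_seed >= 4L)
  structure(list(evalue_threshold = evalue_threshold, search_mode = search_mode,
                 min_seed = as.integer(min_seed)),
            class = "annotation_config")
}

karlin_evalue <- function(score, m, n, lambda, K) {
  K * m * n * exp(-lambda * score)
}

six_frames <- function(seq) {
  x <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(x)
  frames <- list()
  for (src in list(x, rc)) {
    for (off in 0:2) {
      L <- length(src) - off
      L <- L - (L %% 3)
      if (L < 3) next
      aa <- suppressWarnings(Biostrings::translate(
        src[(off + 1):(off + L)], if.fuzzy.codon = "X"
      ))
      frames[[length(frames) + 1L]] <- gsub("\\*", "X", as.character(aa))
    }
  }
  unlist(frames)
}

## best local alignment score of each query against a database, seeded
best_db_score <- function(queries, qmasks, db_seqs, k, type, submat, go, ge) {
  n_q <- length(queries)
  best <- data.frame(score = rep(NA_real_, n_q), gene = NA_character_)
  db_masks <- lapply(nchar(db_seqs), function(l) rep(FALSE, l))
  cand <- kmer_candidates(queries, qmasks, db_seqs, db_masks, k)
  if (nrow(cand) == 0L) return(best)
  cls <- if (type == "DNA") Biostrings::DNAStringSet else Biostrings::AAStringSet
  pa <- Biostrings::pairwiseAlignment(
    cls(queries[cand$i]), cls(db_seqs[cand$j]),
    type = "local", substitutionMatrix = submat,
    gapOpening = go, gapExtension = ge
  )
  sc <- Biostrings::score(pa)
  for (r in order(-sc)) {
    qi <- cand$i[r]
    if (is.na(best$score[qi])) {
      best$score[qi] <- sc[r]
      best$gene[qi] <- names(db_seqs)[cand$j[r]] %||% as.character(cand$j[r])
    }
  }
  best
}

#' Flag genic loci by similarity search against a gene database
#'
#' Each locus is searched (seeded local alignment, both strands in
#' nucleotide mode, all 6x6 reading-frame pairs in translated mode) against
#' the gene database; a locus is genic iff the significance of its best hit
#' falls below the configured threshold. Repeat-masked bases are excluded
#' from seeding.
#'
#' @param loci a [rad_loci] table.
#' @param gene_db a named `DNAStringSet` or path to a gene FASTA.
#' @param config an [annotation_config()].
#' @return A `data.frame` with columns `locus_id`, `genic`, `best_gene`,
#'   `score`, `evalue`.
#' @export
annotate_loci <- function(loci, gene_db, config = annotation_config()) {
  stopifnot(inherits(loci, "rad_loci"), inherits(config, "annotation_config"))
  if (is.character(gene_db)) gene_db <- Biostrings::readDNAStringSet(gene_db)
  out <- data.frame(locus_id = loci$id, genic = FALSE,
                    best_gene = NA_character_, score = NA_real_,
                    evalue = NA_real_, stringsAsFactors = FALSE)
  if (length(gene_db) == 0L) {
    warning("empty gene database: all loci flagged non-genic")
    return(out)
  }
  genes <- as.character(gene_db)
  names(genes) <- sub("\\s.*$", "", names(gene_db) %||% as.character(seq_along(gene_db)))
  if (config$search_mode == "nucleotide") {
    db <- c(genes, setNames(reverse_complement(genes), paste0(names(genes), ":-")))
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                       baseOnly = FALSE)
    best <- best_db_score(loci$seq, loci$mask, db, config$min_seed,
                          "DNA", submat, 5, 2)
    lambda <- 1.33; K <- 0.621
    m <- nchar(loci$seq); n <- sum(nchar(genes))
  } else {
    k_aa <- max(3L, config$min_seed %/% 3L)
    gene_frames <- lapply(genes, six_frames)
    db <- unlist(gene_frames)
    names(db) <- rep(names(genes), lengths(gene_frames))
    data("BLOSUM62", package = "Biostrings", envir = environment())
    submat <- get("BLOSUM62", envir = environment())
    best <- data.frame(score = rep(NA_real_, nrow(loci)), gene = NA_character_)
    for (i in seq_len(nrow(loci))) {
      fr <- six_frames(loci$seq[i])
      if (!length(fr)) next
      b <- best_db_score(fr, lapply(nchar(fr), function(l) rep(FALSE, l)),
                         db, k_aa, "AA", submat, 11, 1)
      j <- which.max(b$score)
      if (length(j) && !is.na(b$score[j])) {
        best$score[i] <- b$score[j]
        best$gene[i] <- b$gene[j]
      }
    }
    lambda <- 0.267; K <- 0.041
    m <- nchar(loci$seq) %/% 3L
    n <- sum(nchar(genes) %/% 3L)
  }
  has <- !is.na(best$score)
  out$score[has] <- best$score[has]
  out$best_gene[has] <- sub(":-$", "", best$gene[has])
  out$evalue[has] <- karlin_evalue(best$score[has], m[has], n, lambda, K)
  out$genic <- has & out$evalue < config$evalue_threshold
  out
}

#' Cluster-level genic flags and fraction
#'
#' @param clusters an `ortholog_clusters` table.
#' @param locus_annotation output of [annotate_loci()] covering the member
#'   loci.
#' @param rule `"any"` (default: a cluster is genic if any member is) or
#'   `"all"`.
#' @return A list: `cluster_genic` (named logical by cluster id), `n_genic`,
#'   `pct_genic` (percentage of clusters flagged genic, 1 decimal).
#' @export
annotate_clusters <- function(clusters, locus_annotation, rule = c("any", "all")) {
  rule <- match.arg(rule)
  flags <- setNames(locus_annotation$genic, locus_annotation$locus_id)
  ids <- unique(clusters$cluster_id)
  agg <- vapply(ids, function(cid) {
    f <- flags[clusters$locus_id[clusters$cluster_id == cid]]
    f[is.na(f)] <- FALSE
    if (rule == "any") any(f) else all(f)
  }, logical(1))
  list(
    cluster_genic = agg,
    n_genic = sum(agg),
    pct_genic = if (length(ids)) round(100 * sum(agg) / length(ids), 1) else NA_real_
  )
}
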