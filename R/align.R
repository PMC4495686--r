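#' Alignment threshold sets
#'
#' Two named presets bind the threshold triples used throughout the
#' package: `"strict"` (identity >= 0.95, alignment length >= 50 bp,
#' mismatches <= 2), intended for comparisons among closely related species
#' where paralogy must be discriminated, and `"relaxed"` (identity >= 0.85,
#' length >= 45 bp, mismatches <= 10) for distant comparisons.
#'
#' @param preset `"strict"` or `"relaxed"`; ignored if all three thresholds
#'   are supplied explicitly.
#' @param identity_min,aln_length_min,mismatch_max explicit overrides.
#' @return A list of class `alignment_thresholds`.
#' @export
alignment_thresholds <- function(preset = c("strict", "relaxed"),
                                 identity_min = NULL, aln_length_min = NULL,
                                 mismatch_max = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    strict  = list(identity_min = 0.95, aln_length_min = 50L, mismatch_max = 2L),
    relaxed = list(identity_min = 0.85, aln_length_min = 45L, mismatch_max = 10L)
  )
  out <- list(
    identity_min = identity_min %||% def$identity_min,
    aln_length_min = as.integer(aln_length_min %||% def$aln_length_min),
    mismatch_max = as.integer(mismatch_max %||% def$mismatch_max),
    preset = preset
  )
  stopifnot(out$identity_min > 0, out$identity_min <= 1,
            out$aln_length_min >= 1L, out$mismatch_max >= 0L)
  structure(out, class = "alignment_thresholds")
}

default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -5, gap_extend = -2)
}

empty_hits <- function() {
  data.frame(
    query_id = character(), subject_id = character(),
    query_species = character(), subject_species = character(),
    strand = character(), aln_length = integer(), identity = numeric(),
    mismatches = integer(), gaps = integer(), score = numeric(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
    rank = integer(), stringsAsFactors = FALSE
  )
}

#' Seeded all-vs-all local alignment between two species' loci
#'
#' Every query/subject pair sharing at least one unmasked exact k-mer (on
#' either strand) is locally aligned with affine-gap Smith-Waterman scoring;
#' hits scoring below `score_floor` are suppressed. A gap of length g costs
#' `|gap_open| + g * |gap_extend|`. Identity is
#' `(aln_length - mismatches - gaps) / aln_length`, where `gaps` counts gap
#' columns; minus-strand subject coordinates follow the usual convention
#' `sstart > send`.
#'
#' @param query_loci,subject_loci [rad_loci] tables from two different
#'   species (one species each).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (defaults +1/-2/-5/-2).
#' @param k exact-seed length (default 11); seeds must be unmasked and
#'   N-free in both sequences, so fully masked loci produce no hits.
#' @param score_floor minimum reported alignment score (default 20).
#' @param query_kmers,subject_kmers,subject_kmers_rc optional precomputed
#'   k-mer tables from prior calls (performance cache used by
#'   [run_pipeline()]); leave `NULL` to compute internally.
#' @return A `pairwise_hits` data frame (see [empty_hits] columns). `rank` is
#'   `NA` until [extract_best_hits()].
#' @export
align_all_pairs <- function(query_loci, subject_loci,
                            scoring = default_scoring(),
                            k = 11L, score_floor = 20,
                            query_kmers = NULL, subject_kmers = NULL,
                            subject_kmers_rc = NULL) {
  stopifnot(inherits(query_loci, "rad_loci"), inherits(subject_loci, "rad_loci"))
  qs <- unique(query_loci$species)
  ss <- unique(subject_loci$species)
  if (length(qs) != 1L || length(ss) != 1L) stop("each input must hold one species")
  if (qs == ss) stop("query and subject species must differ")
  if (nrow(query_loci) == 0L || nrow(subject_loci) == 0L) return(empty_hits())

  rc_subj <- reverse_complement(subject_loci$seq)
  rc_mask <- lapply(subject_loci$mask, rev)
  cand_f <- kmer_candidates(query_loci$seq, query_loci$mask,
                            subject_loci$seq, subject_loci$mask, k,
                            kmersA = query_kmers, kmersB = subject_kmers)
  cand_r <- kmer_candidates(query_loci$seq, query_loci$mask, rc_subj, rc_mask, k,
                            kmersA = query_kmers, kmersB = subject_kmers_rc)
  cand <- rbind(
    if (nrow(cand_f)) cbind(cand_f, strand = "+"),
    if (nrow(cand_r)) cbind(cand_r, strand = "-")
  )
  if (is.null(cand) || nrow(cand) == 0L) return(empty_hits())

  subj_seq <- ifelse(cand$strand == "+", subject_loci$seq[cand$j], rc_subj[cand$j])
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(query_loci$seq[cand$i]),
    Biostrings::DNAStringSet(subj_seq),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE
    ),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend)
  )
  sc <- Biostrings::score(pa)
  keep <- sc >= score_floor
  if (!any(keep)) return(empty_hits())
  pa <- pa[keep]
  cand <- cand[keep, , drop = FALSE]
  sc <- sc[keep]

  ni <- Biostrings::nindel(pa)
  gap_cols <- Biostrings::insertion(ni)[, "WidthSum"] +
    Biostrings::deletion(ni)[, "WidthSum"]
  aln_len <- Biostrings::end(Biostrings::pattern(pa)) -
    Biostrings::start(Biostrings::pattern(pa)) + 1L +
    Biostrings::deletion(ni)[, "WidthSum"]
  n_match <- Biostrings::nmatch(pa)
  n_mm <- Biostrings::nmismatch(pa)
  s_start <- Biostrings::start(Biostrings::subject(pa))
  s_end <- Biostrings::end(Biostrings::subject(pa))
  s_len <- nchar(subject_loci$seq[cand$j])
  minus <- cand$strand == "-"
  sstart <- ifelse(minus, s_len - s_start + 1L, s_start)
  send <- ifelse(minus, s_len - s_end + 1L, s_end)

  out <- data.frame(
    query_id = query_loci$id[cand$i],
    subject_id = subject_loci$id[cand$j],
    query_species = qs, subject_species = ss,
    strand = cand$strand,
    aln_length = as.integer(aln_len),
    identity = n_match / aln_len,
    mismatches = as.integer(n_mm),
    gaps = as.integer(gap_cols),
    score = sc,
    qstart = Biostrings::start(Biostrings::pattern(pa)),
    qend = Biostrings::end(Biostrings::pattern(pa)),
    sstart = as.integer(sstart), send = as.integer(send),
    rank = NA_integer_, stringsAsFactors = FALSE
  )
  class(out) <- c("pairwise_hits", "data.frame")
  out
}

#' Swap hit direction
#'
#' Local alignment scores are symmetric in query and subject, so hits
#' computed for species pair (A, B) can be reused for direction (B, A) by
#' swapping roles. Used by the pipeline to halve alignment work.
#'
#' @param hits a `pairwise_hits` data frame.
#' @return The same hits with query/subject roles exchanged.
#' @export
swap_hits <- function(hits) {
  out <- hits
  out$query_id <- hits$subject_id
  out$subject_id <- hits$query_id
  out$query_species <- hits$subject_species
  out$subject_species <- hits$query_species
  out$qstart <- pmin(hits$sstart, hits$send)
  out$qend <- pmax(hits$sstart, hits$send)
  out$sstart <- ifelse(hits$strand == "-", hits$qend, hits$qstart)
  out$send <- ifelse(hits$strand == "-", hits$qstart, hits$qend)
  out$rank <- NA_integer_
  class(out) <- c("pairwise_hits", "data.frame")
  out
}

#' Best hit per query per subject species
#'
#' Keeps, for each query, its maximal-score hit against each subject
#' species; ties are broken by higher identity, then longer alignment,
#' then lexicographically smallest subject id. `rank` is set to 1.
#'
#' @param hits a `pairwise_hits` data frame.
#' @return The best-hit subset.
#' @export
extract_best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, hits$subject_species,
               -hits$score, -hits$identity, -hits$aln_length, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(paste(h$query_id, h$subject_species, sep = "\r"))
  out <- h[first, , drop = FALSE]
  out$rank <- 1L
  rownames(out) <- NULL
  class(out) <- c("pairwise_hits", "data.frame")
  out
}

#' Threshold-filter hits
#'
#' A hit survives iff `identity >= identity_min` and
#' `aln_length >= aln_length_min` and `mismatches <= mismatch_max`.
#'
#' @param hits a `pairwise_hits` data frame.
#' @param thresholds an [alignment_thresholds()].
#' @return The surviving subset.
#' @export
filter_hits <- function(hits, thresholds) {
  stopifnot(inherits(thresholds, "alignment_thresholds"))
  keep <- hits$identity >= thresholds$identity_min &
    hits$aln_length >= thresholds$aln_length_min &
    hits$mismatches <= thresholds$mismatch_max
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pairwise_hits", "data.frame")
  out
}

#' Uniqueness filter
#'
#' Within each directed species pair, any subject locus that is the best hit
#' of two or more queries is discarded together with every hit pointing at
#' it — such multi-hit subjects are symptomatic of repeats or (in duplicated
#' genomes) paralogous regions. Remaining subjects each have exactly one
#' incoming best hit.
#'
#' @param hits best hits (after [extract_best_hits()] and [filter_hits()]).
#' @return The unique subset, with `attr(, "n_removed")`.
#' @export
filter_unique <- function(hits) {
  if (nrow(hits) == 0L) {
    attr(hits, "n_removed") <- 0L
    return(hits)
  }
  key <- paste(hits$query_species, hits$subject_species, hits$subject_id, sep = "\r")
  dup_subject <- key %in% key[duplicated(key)]
  out <- hits[!dup_subject, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pairwise_hits", "data.frame")
  attr(out, "n_removed") <- sum(dup_subject)
  out
}

#' Write hits as 12+-column tab-separated table
#'
#' @param hits a `pairwise_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "identity", "aln_length", "mismatches",
            "gaps", "qstart", "qend", "sstart", "send", "score", "rank")
  tab <- hits[, cols, drop = FALSE]
  tab$identity <- round(100 * tab$identity, 2)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
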