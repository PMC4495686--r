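#' Trim loci to a common length
#'
#' Consensus loci from different studies have different read lengths; to keep
#' alignment statistics comparable every locus is cut down to its first
#' `target_length` bases. Loci shorter than the target carry too little
#' comparable sequence and are dropped (the count is recorded in the
#' `"trim_log"` attribute).
#'
#' @param loci a [rad_loci] table.
#' @param target_length trimmed length in bp (> 0; default 60).
#' @return The trimmed [rad_loci] table, with `attr(, "trim_log")` a list
#'   holding `n_in`, `n_dropped`, `dropped_ids`.
#' @export
trim_loci <- function(loci, target_length = 60L) {
  stopifnot(inherits(loci, "rad_loci"), target_length > 0L)
  short <- nchar(loci$seq) < target_length
  out <- loci[!short, , drop = FALSE]
  out$seq <- substring(out$seq, 1L, target_length)
  out$mask <- lapply(out$mask, function(m) m[seq_len(target_length)])
  class(out) <- c("rad_loci", "data.frame")
  attr(out, "trim_log") <- list(
    n_in = nrow(loci), n_dropped = sum(short), dropped_ids = loci$id[short]
  )
  out
}

## DUST-style triplet score of one window of integer-coded triplets.
## score = sum c_t (c_t - 1) / 2 over triplet counts, normalised by (w - 3).
dust_window_scores <- function(trip, w) {
  n_trip <- w - 2L
  n_win <- length(trip) - n_trip + 1L
  scores <- numeric(n_win)
  for (s in seq_len(n_win)) {
    tt <- trip[s:(s + n_trip - 1L)]
    tt <- tt[!is.na(tt)]
    if (length(tt) < 2L) { scores[s] <- 0; next }
    cnt <- tabulate(tt, nbins = 64L)
    scores[s] <- sum(cnt * (cnt - 1) / 2) / (w - 3L)
  }
  scores
}

#' Mask low-complexity sequence (DUST-style)
#'
#' Slides a window along each locus, computes a triplet-composition score
#' (sum over triplet types of c(c-1)/2, normalised by window length minus 3 —
#' the score used by the DUST family of maskers), and marks every base of any
#' window whose score exceeds the threshold. Sequence letters are unchanged:
#' masking is an annotation consumed by the alignment seeding steps.
#' Triplets containing N are ignored.
#'
#' @param loci a [rad_loci] table (ACGTN only).
#' @param window window width in bp (>= 4; default 12, suited to 60 bp loci).
#' @param score_threshold windows scoring strictly above this are masked
#'   (default 2, the classic DUST cut-off).
#' @return The [rad_loci] table with updated masks (OR-ed onto any existing
#'   mask, so the operation is idempotent).
#' @export
mask_low_complexity <- function(loci, window = 12L, score_threshold = 2) {
  stopifnot(inherits(loci, "rad_loci"), window >= 4L)
  if (any(grepl("[^ACGTN]", loci$seq))) stop("non-ACGTN characters in input")
  for (i in seq_len(nrow(loci))) {
    s <- loci$seq[i]
    L <- nchar(s)
    if (L < 3L) next
    w <- min(window, L)
    code <- match(strsplit(s, "")[[1]], BASES) - 1L
    trip <- code[1:(L - 2L)] * 16L + code[2:(L - 1L)] * 4L + code[3:L] + 1L
    scores <- dust_window_scores(trip, w)
    hot <- which(scores > score_threshold)
    if (length(hot)) {
      m <- loci$mask[[i]]
      for (s0 in hot) m[s0:(s0 + w - 1L)] <- TRUE
      loci$mask[[i]] <- m
    }
  }
  loci
}

#' Mask bases matching a repeat library
#'
#' A simplified repeat-library masker: every locus base covered by a match of
#' at least 18 bp to any library sequence (up to `max_mismatch` mismatches,
#' either strand) is masked. Matching is by exhaustive scan of all 18 bp
#' windows of the library against each locus — adequate for the compact
#' libraries this package targets, not a general-purpose repeat annotator.
#'
#' @param loci a [rad_loci] table.
#' @param repeats a `DNAStringSet`, or path to a repeat-library FASTA.
#' @param max_mismatch allowed mismatches within an 18 bp match (default 2).
#' @return The [rad_loci] table with updated masks.
#' @export
mask_repeat_library <- function(loci, repeats, max_mismatch = 2L) {
  stopifnot(inherits(loci, "rad_loci"))
  if (is.character(repeats)) repeats <- Biostrings::readDNAStringSet(repeats)
  if (length(repeats) == 0L) {
    warning("empty repeat library: masking skipped")
    return(loci)
  }
  wlen <- 18L
  windows <- list()
  for (r in seq_along(repeats)) {
    rs <- repeats[[r]]
    if (length(rs) < wlen) next
    for (strand_seq in list(rs, Biostrings::reverseComplement(rs))) {
      starts <- seq_len(length(strand_seq) - wlen + 1L)
      windows <- c(windows, lapply(starts, function(s) strand_seq[s:(s + wlen - 1L)]))
    }
  }
  if (!length(windows)) return(loci)
  windows <- unique(Biostrings::DNAStringSet(windows))
  for (i in seq_len(nrow(loci))) {
    subj <- Biostrings::DNAString(loci$seq[i])
    if (length(subj) < wlen) next
    m <- loci$mask[[i]]
    for (w in seq_along(windows)) {
      hits <- Biostrings::matchPattern(windows[[w]], subj,
                                       max.mismatch = max_mismatch)
      if (length(hits)) {
        for (h in seq_along(hits)) {
          m[Biostrings::start(hits)[h]:Biostrings::end(hits)[h]] <- TRUE
        }
      }
    }
    loci$mask[[i]] <- m
  }
  loci
}

#' Merge policy for cross-study locus grouping within a species
#'
#' @param identity_min minimum full-length identity for two loci (from
#'   different studies of one species) to be the same locus (default 0.95).
#' @param mismatch_max maximum base mismatches over the full trimmed length
#'   (default 2). Both constraints are enforced.
#' @param min_studies number of distinct studies a locus group must span to
#'   be emitted as a common locus. `NULL` (default) means a majority of the
#'   studies present in the input.
#' @return A list of class `merge_policy`.
#' @export
merge_policy <- function(identity_min = 0.95, mismatch_max = 2L, min_studies = NULL) {
  stopifnot(identity_min > 0, identity_min <= 1, mismatch_max >= 0,
            is.null(min_studies) || min_studies >= 1L)
  structure(list(identity_min = identity_min, mismatch_max = as.integer(mismatch_max),
                 min_studies = if (is.null(min_studies)) NULL else as.integer(min_studies)),
            class = "merge_policy")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Merge per-study locus sets of one species into common loci
#'
#' Loci from different studies are grouped when their full-length comparison
#' (either strand) reaches `identity_min` identity and at most `mismatch_max`
#' mismatches; groups observed in at least `min_studies` studies are emitted
#' as one common locus, represented by the sequence from the
#' lexicographically first study in the group (ties broken by locus id).
#' Grouping uses maximal cliques of the match graph; a locus belonging to two
#' incompatible groups (i.e. to more than one maximal clique) is excluded and
#' logged. All loci must be pre-trimmed to one common length.
#'
#' The `"merge_log"` attribute reports study sizes, the number of emitted
#' common loci, excluded ids, and the sharing percentage — emitted common
#' loci relative to the smallest study.
#'
#' @param loci a [rad_loci] table for a single species.
#' @param policy a [merge_policy()].
#' @param k seed length for the candidate-pair prefilter (default 11).
#' @return A [rad_loci] table of common loci (study relabelled `"merged"`),
#'   with `attr(, "merge_log")`.
#' @export
merge_studies <- function(loci, policy = merge_policy(), k = 11L) {
  stopifnot(inherits(loci, "rad_loci"))
  if (length(unique(loci$species)) > 1L) stop("merge_studies takes loci of one species")
  studies <- sort(unique(loci$study))
  study_sizes <- table(loci$study)
  min_studies <- policy$min_studies %||% (length(studies) %/% 2L + 1L)
  if (nrow(loci) == 0L) {
    out <- loci
    attr(out, "merge_log") <- list(study_sizes = study_sizes, n_common = 0L,
                                   excluded_ids = character(), sharing_pct = NA_real_)
    return(out)
  }
  L <- unique(nchar(loci$seq))
  if (length(L) != 1L) stop("loci must be trimmed to equal length before merging")

  ## candidate pairs via shared k-mers, forward and reverse complement
  rc <- reverse_complement(loci$seq)
  fw <- kmer_candidates(loci$seq, loci$mask, loci$seq, loci$mask, k)
  rv <- kmer_candidates(loci$seq, loci$mask, rc, lapply(loci$mask, rev), k)
  cand <- unique(rbind(fw, rv))
  cand <- cand[cand$i < cand$j & loci$study[cand$i] != loci$study[cand$j], , drop = FALSE]

  ok <- logical(nrow(cand))
  mm_limit <- min(policy$mismatch_max, floor((1 - policy$identity_min) * L))
  for (r in seq_len(nrow(cand))) {
    a <- loci$seq[cand$i[r]]
    mm <- hamming(a, loci$seq[cand$j[r]])
    if (mm > mm_limit) mm <- min(mm, hamming(a, rc[cand$j[r]]))
    ok[r] <- mm <= policy$mismatch_max && (L - mm) / L >= policy$identity_min
  }
  cand <- cand[ok, , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    data.frame(from = loci$id[cand$i], to = loci$id[cand$j]),
    directed = FALSE, vertices = data.frame(name = loci$id)
  )
  cl <- igraph::max_cliques(g, min = 1L)
  memb <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  counts <- table(unlist(memb))
  conflicted <- names(counts)[counts > 1L]
  memb <- lapply(memb, function(m) setdiff(m, conflicted))
  memb <- unique(memb[lengths(memb) > 0L])

  rows <- integer(0)
  n_common <- 0L
  idx_of <- setNames(seq_len(nrow(loci)), loci$id)
  for (m in memb) {
    st <- unique(loci$study[idx_of[m]])
    if (length(st) < min_studies) next
    n_common <- n_common + 1L
    first_study <- sort(st)[1]
    cand_ids <- sort(m[loci$study[idx_of[m]] == first_study])
    rows <- c(rows, idx_of[cand_ids[1]])
  }
  out <- loci[sort(rows), , drop = FALSE]
  out$study <- rep("merged", nrow(out))
  class(out) <- c("rad_loci", "data.frame")
  sharing <- if (length(study_sizes)) 100 * n_common / min(study_sizes) else NA_real_
  attr(out, "merge_log") <- list(
    study_sizes = study_sizes, n_common = n_common,
    excluded_ids = conflicted, sharing_pct = sharing,
    min_studies = min_studies
  )
  out
}
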