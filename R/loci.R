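#' Construct a RAD locus table
#'
#' The central container of the package: one row per consensus RAD locus,
#' carrying the species and study it came from, its sequence, and a per-base
#' logical mask (TRUE = masked as low-complexity/repeat; masking is an
#' annotation, the sequence letters are never changed).
#'
#' @param id character vector of unique locus identifiers.
#' @param species character vector (recycled) of species labels.
#' @param study character vector (recycled) of study labels.
#' @param seq character vector of nucleotide sequences (ACGTN).
#' @param mask optional list of logical vectors, one per locus, each the same
#'   length as its sequence. Defaults to all-FALSE masks.
#' @return A `data.frame` of class `rad_loci` with columns `id`, `species`,
#'   `study`, `seq` and list-column `mask`.
#' @export
#' @examples
#' rad_loci(c("a", "b"), "sp1", "study1", c("ACGT", "GGGG"))
rad_loci <- function(id, species, study, seq, mask = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  n <- length(id)
  stopifnot(length(seq) == n)
  if (anyDuplicated(id)) stop("locus ids must be unique")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ", paste(head(id[bad], 3), collapse = ", "))
  }
  if (is.null(mask)) {
    mask <- lapply(nchar(seq), function(l) rep(FALSE, l))
  } else {
    stopifnot(length(mask) == n, all(lengths(mask) == nchar(seq)))
  }
  out <- data.frame(
    id = id,
    species = rep_len(as.character(species), n),
    study = rep_len(as.character(study), n),
    seq = seq,
    stringsAsFactors = FALSE
  )
  out$mask <- mask
  class(out) <- c("rad_loci", "data.frame")
  out
}

#' @export
print.rad_loci <- function(x, ...) {
  cat(sprintf(
    "rad_loci: %d loci, %d species, %d studies, lengths %s\n",
    nrow(x), length(unique(x$species)), length(unique(x$study)),
    if (nrow(x)) paste(range(nchar(x$seq)), collapse = "-") else "NA"
  ))
  invisible(x)
}

#' Read RAD loci from a FASTA file
#'
#' Record ids of the form `species|study|serial` are split into the species
#' and study columns; otherwise the supplied `species`/`study` labels are
#' used for all records.
#'
#' @param path FASTA file path.
#' @param species,study fallback labels when ids are not `|`-delimited.
#' @return A [rad_loci] table.
#' @export
read_loci_fasta <- function(path, species = NA_character_, study = NA_character_) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- names(dss)
  ids <- sub("\\s.*$", "", ids)
  parts <- strsplit(ids, "|", fixed = TRUE)
  three <- lengths(parts) >= 3L
  sp <- ifelse(three, vapply(parts, `[`, "", 1L), species)
  st <- ifelse(three, vapply(parts, `[`, "", 2L), study)
  rad_loci(ids, sp, st, as.character(dss))
}

#' Write RAD loci to FASTA
#'
#' @param loci a [rad_loci] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_fasta <- function(loci, path) {
  dss <- Biostrings::DNAStringSet(setNames(loci$seq, loci$id))
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Enumerate ungapped k-mers of each sequence that contain no masked base and
## no N. Returns data.frame(kmer, idx) where idx indexes into `seqs`.
unmasked_kmers <- function(seqs, masks, k) {
  L <- nchar(seqs)
  n_k <- pmax(0L, L - k + 1L)
  if (sum(n_k) == 0L) {
    return(data.frame(kmer = character(), idx = integer(), stringsAsFactors = FALSE))
  }
  idx <- rep(seq_along(seqs), n_k)
  starts <- unlist(lapply(n_k, seq_len), use.names = FALSE)
  km <- substring(seqs[idx], starts, starts + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  off <- c(0L, cumsum(n_k))
  for (i in which(vapply(masks, any, logical(1)))) {
    if (n_k[i] == 0L) next
    cm <- cumsum(masks[[i]])
    s <- seq_len(n_k[i])
    masked_in_window <- (cm[s + k - 1L] - c(0L, cm)[s]) > 0L
    keep[off[i] + s] <- keep[off[i] + s] & !masked_in_window
  }
  data.frame(kmer = km[keep], idx = idx[keep], stringsAsFactors = FALSE)
}

## Candidate index pairs (i in A, j in B) sharing >=1 unmasked exact k-mer.
## Precomputed k-mer tables (from unmasked_kmers) may be passed to avoid
## recomputation across species pairs.
kmer_candidates <- function(seqsA, masksA, seqsB, masksB, k,
                            kmersA = NULL, kmersB = NULL) {
  ka <- kmersA %||% unmasked_kmers(seqsA, masksA, k)
  kb <- kmersB %||% unmasked_kmers(seqsB, masksB, k)
  if (nrow(ka) == 0L || nrow(kb) == 0L) {
    return(data.frame(i = integer(), j = integer()))
  }
  m <- merge(ka, kb, by = "kmer")
  if (nrow(m) == 0L) return(data.frame(i = integer(), j = integer()))
  key <- (m$idx.x - 1) * (max(m$idx.y) + 1) + m$idx.y
  dd <- !duplicated(key)
  data.frame(i = m$idx.x[dd], j = m$idx.y[dd])
}
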