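## global pairwise alignment used by the center-star MSA; returns the two
## gapped strings. Scoring favours substitutions over gaps, reflecting the
## near indel-free nature of consensus RAD loci.
pairwise_global <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAStringSet(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE
    ),
    gapOpening = 4, gapExtension = 2
  )
  list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    dist = nchar(as.character(Biostrings::alignedPattern(pa))) - Biostrings::nmatch(pa)
  )
}

#' Center-star multiple alignment of one cluster
#'
#' Members are first re-oriented to the cluster's reference strand
#' (reverse-complemented where `strand == "-"`). The center sequence is the
#' member minimising the summed pairwise alignment distance (non-match
#' columns of the pairwise global alignment; ties broken by lexicographic
#' locus id); all other members are merged onto it with the standard
#' "once a gap, always a gap" rule. For indel-free members of equal length
#' the result is the trivial columnwise stacking.
#'
#' @param members rows of an `ortholog_clusters` table for one cluster.
#' @param seqs named character vector mapping locus ids to sequences.
#' @return A list of class `cluster_alignment`: `cluster_id`, `aln` (named
#'   character vector, species -> gapped sequence), `ncol`.
#' @export
align_cluster <- function(members, seqs) {
  stopifnot(all(members$locus_id %in% names(seqs)))
  if (length(unique(members$cluster_id)) != 1L) stop("one cluster at a time")
  s <- unname(seqs[members$locus_id])
  if (any(nchar(s) == 0L)) stop("zero-length member sequence")
  minus <- members$strand == "-"
  s[minus] <- reverse_complement(s[minus])
  names(s) <- members$species
  n <- length(s)
  if (n == 1L) {
    return(structure(list(cluster_id = members$cluster_id[1], aln = s,
                          ncol = unname(nchar(s[1]))), class = "cluster_alignment"))
  }
  if (length(unique(nchar(s))) == 1L) {
    ## equal lengths: substitutions only; alignment is the stacking
    return(structure(list(cluster_id = members$cluster_id[1], aln = s,
                          ncol = unname(nchar(s[1]))), class = "cluster_alignment"))
  }
  ## choose center
  ord <- order(members$locus_id)
  dist_sum <- numeric(n)
  pair_aln <- vector("list", n * n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pw <- pairwise_global(s[i], s[j])
      dist_sum[i] <- dist_sum[i] + pw$dist
      dist_sum[j] <- dist_sum[j] + pw$dist
    }
  }
  center <- ord[which.min(dist_sum[ord])] # ties -> smallest locus id
  others <- setdiff(seq_len(n), center)

  ## master alignment: list of char vectors, grown by merging pairwise
  ## alignments of center vs each other member
  center_chars <- strsplit(s[center], "")[[1]]
  master <- list()
  master[[center]] <- center_chars
  center_cols <- seq_along(center_chars) # column of each center residue
  n_cols <- length(center_chars)
  for (o in others) {
    pw <- pairwise_global(s[center], s[o])
    cp <- strsplit(pw$a, "")[[1]]
    co <- strsplit(pw$b, "")[[1]]
    new_row <- rep("-", n_cols)
    insertions <- list() # key: after-residue index (0 = before first)
    r <- 0L
    for (jj in seq_along(cp)) {
      if (cp[jj] != "-") {
        r <- r + 1L
        if (co[jj] != "-") new_row[center_cols[r]] <- co[jj]
      } else {
        k <- as.character(r)
        insertions[[k]] <- c(insertions[[k]], co[jj])
      }
    }
    if (length(insertions)) {
      ## splice insertion columns after the r-th center residue
      for (k in rev(names(insertions)[order(as.integer(names(insertions)))])) {
        r <- as.integer(k)
        ins <- insertions[[k]]
        at <- if (r == 0L) 0L else center_cols[r]
        for (idx in seq_along(master)) {
          row <- master[[idx]]
          if (is.null(row)) next
          master[[idx]] <- append(row, rep("-", length(ins)), after = at)
        }
        new_row <- append(new_row, ins, after = at)
        n_cols <- n_cols + length(ins)
        bump <- center_cols > at
        center_cols[bump] <- center_cols[bump] + length(ins)
      }
    }
    master[[o]] <- new_row
  }
  aln <- vapply(seq_len(n), function(i) paste(master[[i]], collapse = ""), "")
  names(aln) <- names(s)
  structure(list(cluster_id = members$cluster_id[1], aln = aln, ncol = n_cols),
            class = "cluster_alignment")
}

#' Extract between-species variant columns from a cluster alignment
#'
#' A column is a variant iff, treating `-` and `N` as missing, at least two
#' species have data and at least two distinct bases occur among them. Each
#' species' state at a variant column is its base, or `N` when missing.
#'
#' @param alignment a `cluster_alignment`.
#' @return A list: `variants` (character matrix, species x variant columns;
#'   zero columns when none), `columns` (alignment column indices),
#'   `cluster_id`.
#' @export
extract_variants <- function(alignment) {
  stopifnot(inherits(alignment, "cluster_alignment"))
  rows <- alignment$aln
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- names(rows)
  mat[mat == "-"] <- "N"
  is_var <- apply(mat, 2, function(col) {
    nm <- col[col != "N"]
    length(nm) >= 2L && length(unique(nm)) >= 2L
  })
  cols <- which(is_var)
  list(
    variants = mat[, cols, drop = FALSE],
    columns = cols,
    cluster_id = alignment$cluster_id
  )
}

#' Concatenate per-cluster variants into a species-by-sites supermatrix
#'
#' Columns are ordered by (cluster id, alignment column); species absent
#' from a cluster get `N` at all of that cluster's variant columns — the
#' matrix analogue of padding absent species with a string of N's before
#' alignment.
#'
#' @param variant_list list of [extract_variants()] results.
#' @param species full species vector for the analysis (row order).
#' @return A list of class `variant_supermatrix`: `species`, `matrix`
#'   (character, species x sites), `provenance` data frame
#'   (`column`, `cluster_id`, `cluster_column`), `n_clusters`, and missing
#'   statistics (`per_species_missing`, `pct_missing`).
#' @export
concatenate_variants <- function(variant_list, species) {
  ids <- vapply(variant_list, `[[`, "", "cluster_id")
  if (anyDuplicated(ids)) stop("duplicate cluster ids")
  variant_list <- variant_list[order(ids)]
  ids <- sort(ids)
  ncols <- vapply(variant_list, function(v) ncol(v$variants), integer(1))
  total <- sum(ncols)
  mat <- matrix("N", nrow = length(species), ncol = total,
                dimnames = list(species, NULL))
  prov <- data.frame(column = integer(total), cluster_id = character(total),
                     cluster_column = integer(total), stringsAsFactors = FALSE)
  at <- 0L
  for (v in variant_list) {
    nc <- ncol(v$variants)
    if (nc == 0L) next
    sp <- rownames(v$variants)
    unknown <- setdiff(sp, species)
    if (length(unknown)) stop("species not in list: ", paste(unknown, collapse = ", "))
    mat[sp, (at + 1L):(at + nc)] <- v$variants
    prov$column[(at + 1L):(at + nc)] <- (at + 1L):(at + nc)
    prov$cluster_id[(at + 1L):(at + nc)] <- v$cluster_id
    prov$cluster_column[(at + 1L):(at + nc)] <- v$columns
    at <- at + nc
  }
  per_missing <- rowSums(mat == "N")
  structure(list(
    species = species, matrix = mat, provenance = prov,
    n_clusters = length(variant_list),
    per_species_missing = per_missing,
    pct_missing = if (total > 0L) 100 * sum(per_missing) / (length(species) * total) else NA_real_
  ), class = "variant_supermatrix")
}

#' @export
print.variant_supermatrix <- function(x, ...) {
  cat(sprintf("variant_supermatrix: %d species x %d sites (%d clusters), %.2f%% missing\n",
              length(x$species), ncol(x$matrix), x$n_clusters,
              if (is.na(x$pct_missing)) 0 else x$pct_missing))
  invisible(x)
}

#' Write a supermatrix in relaxed sequential PHYLIP format
#'
#' Header `"<n_taxa> <n_sites>"`, then one line per species with the name
#' and its sequence separated by whitespace (names are not truncated to the
#' strict 10-character dialect). Round-trips via [read_phylip()].
#'
#' @param m a `variant_supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path) {
  stopifnot(inherits(m, "variant_supermatrix"))
  if (length(m$species) < 2L || ncol(m$matrix) < 1L) {
    stop("PHYLIP export needs >= 2 species and >= 1 site")
  }
  lines <- c(
    sprintf("%d %d", length(m$species), ncol(m$matrix)),
    vapply(m$species, function(sp) {
      paste(sp, paste(m$matrix[sp, ], collapse = ""), sep = "  ")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a relaxed sequential PHYLIP file
#'
#' @param path file path.
#' @return A `variant_supermatrix` (without provenance).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  n_taxa <- hdr[1]; n_sites <- hdr[2]
  body <- lines[1L + seq_len(n_taxa)]
  parts <- strsplit(trimws(body), "\\s+")
  species <- vapply(parts, `[`, "", 1L)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  if (any(nchar(seqs) != n_sites)) stop("sequence length disagrees with header")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- species
  per_missing <- rowSums(mat == "N")
  structure(list(
    species = species, matrix = mat,
    provenance = NULL, n_clusters = NA_integer_,
    per_species_missing = per_missing,
    pct_missing = 100 * sum(per_missing) / (n_taxa * n_sites)
  ), class = "variant_supermatrix")
}

#' Supermatrix summary statistics
#'
#' @param m a `variant_supermatrix`.
#' @return A list: `n_species`, `n_clusters`, `n_variants`, `pct_missing`,
#'   `per_species_missing` (named counts) and `missing_range` (min/max per
#'   species).
#' @export
matrix_stats <- function(m) {
  stopifnot(inherits(m, "variant_supermatrix"))
  pm <- m$per_species_missing
  list(
    n_species = length(m$species),
    n_clusters = m$n_clusters,
    n_variants = ncol(m$matrix),
    pct_missing = m$pct_missing,
    per_species_missing = pm,
    missing_range = if (length(pm)) range(pm) else c(NA_integer_, NA_integer_)
  )
}
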