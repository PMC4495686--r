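#' Build the reciprocal-best-hit graph
#'
#' An undirected edge joins loci `a` (species A) and `b` (species B) iff
#' `a`'s unique best hit in species B is `b` and `b`'s unique best hit in
#' species A is `a`. Vertices carry their species; edges record the relative
#' strand of the underlying alignment.
#'
#' @param unique_hits row-bound unique best hits for all directed species
#'   pairs (both directions of every pair).
#' @return An `igraph` undirected graph with vertex attribute `species` and
#'   edge attribute `strand`.
#' @export
build_rbh_graph <- function(unique_hits) {
  h <- unique_hits
  if (nrow(h) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  key <- paste(h$query_id, h$subject_id, sep = "\r")
  rev_key <- paste(h$subject_id, h$query_id, sep = "\r")
  reciprocal <- key %in% rev_key
  r <- h[reciprocal, , drop = FALSE]
  ## keep one row per unordered pair (the direction with the smaller query id)
  first_dir <- r$query_id < r$subject_id
  r <- r[first_dir, , drop = FALSE]
  verts <- unique(data.frame(
    name = c(h$query_id, h$subject_id),
    species = c(h$query_species, h$subject_species),
    stringsAsFactors = FALSE
  ))
  igraph::graph_from_data_frame(
    data.frame(from = r$query_id, to = r$subject_id, strand = r$strand,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts
  )
}

## orientation of every vertex in a connected subgraph relative to the
## lexicographically smallest member, propagating edge strands along a BFS;
## `adj` is a named list of neighbour vectors, `strand_of` a named character
## vector keyed "a\rb" in both directions
orient_members <- function(adj, strand_of, members) {
  ref <- sort(members)[1]
  ori <- setNames(rep(NA_character_, length(members)), members)
  ori[ref] <- "+"
  queue <- ref
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- intersect(adj[[v]], members)
    for (w in nb) {
      if (!is.na(ori[w])) next
      st <- strand_of[[paste(v, w, sep = "\r")]]
      ori[w] <- if (st == "+") ori[v] else if (ori[v] == "+") "-" else "+"
      queue <- c(queue, w)
    }
  }
  ori
}

#' Infer ortholog clusters from the RBH graph
#'
#' In `clique` mode (the default reading of "every member is every other
#' member's unique best match") maximal cliques of size >= 2 are emitted;
#' because RBH edges only join different species, cliques automatically
#' contain at most one locus per species. `component` mode emits connected
#' components instead, for sensitivity analysis against the stricter clique
#' semantics. Output ordering is deterministic: members sorted within a
#' cluster, clusters sorted by member ids.
#'
#' @param graph output of [build_rbh_graph()].
#' @param mode `"clique"` (default) or `"component"`.
#' @return A `data.frame` of class `ortholog_clusters` with columns
#'   `cluster_id`, `locus_id`, `species`, `strand` (orientation relative to
#'   the lexicographically smallest member).
#' @export
infer_clusters <- function(graph, mode = c("clique", "component")) {
  mode <- match.arg(mode)
  empty <- data.frame(cluster_id = character(), locus_id = character(),
                      species = character(), strand = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ortholog_clusters", "data.frame")
  if (igraph::vcount(graph) == 0L) return(empty)
  if (mode == "clique") {
    cl <- igraph::max_cliques(graph, min = 2L)
    memb <- lapply(cl, function(v) sort(v$name))
  } else {
    comp <- igraph::components(graph)
    memb <- split(names(comp$membership), comp$membership)
    memb <- lapply(memb, sort)
    memb <- memb[lengths(memb) >= 2L]
  }
  if (!length(memb)) return(empty)
  memb <- memb[order(vapply(memb, paste, "", collapse = "\r"))]
  sp <- setNames(igraph::V(graph)$species, igraph::V(graph)$name)
  ed <- igraph::as_data_frame(graph, what = "edges")
  adj <- split(c(ed$to, ed$from), c(ed$from, ed$to))
  strand_of <- setNames(c(ed$strand, ed$strand),
                        c(paste(ed$from, ed$to, sep = "\r"),
                          paste(ed$to, ed$from, sep = "\r")))
  out <- do.call(rbind, lapply(seq_along(memb), function(i) {
    m <- memb[[i]]
    ori <- orient_members(adj, strand_of, m)
    data.frame(cluster_id = sprintf("CL%05d", i), locus_id = m,
               species = unname(sp[m]), strand = unname(ori[m]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ortholog_clusters", "data.frame")
  out
}

as_clusters <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("ortholog_clusters", "data.frame")
  df
}

#' Remove clusters sharing loci with other clusters
#'
#' A locus assigned to two or more clusters flags all of those clusters as
#' potentially paralogous (or repeat-derived); every such cluster is removed
#' whole. The number removed is recorded in `attr(, "n_removed")`.
#'
#' @param clusters an `ortholog_clusters` table.
#' @return The filtered table.
#' @export
remove_multi_cluster_sequences <- function(clusters) {
  dup_loci <- unique(clusters$locus_id[duplicated(clusters$locus_id)])
  bad <- unique(clusters$cluster_id[clusters$locus_id %in% dup_loci])
  out <- as_clusters(clusters[!clusters$cluster_id %in% bad, , drop = FALSE])
  attr(out, "n_removed") <- length(bad)
  out
}

#' Remove clusters with two or more loci from one species
#'
#' @param clusters an `ortholog_clusters` table.
#' @return The filtered table, with `attr(, "n_removed")`.
#' @export
remove_multi_species_duplicates <- function(clusters) {
  key <- paste(clusters$cluster_id, clusters$species, sep = "\r")
  bad <- unique(clusters$cluster_id[key %in% key[duplicated(key)]])
  out <- as_clusters(clusters[!clusters$cluster_id %in% bad, , drop = FALSE])
  attr(out, "n_removed") <- length(bad)
  out
}

#' Taxon-coverage and species-group filters
#'
#' Keeps clusters with members from at least `min_species` distinct species.
#' `required_groups` optionally demands a minimum number of members from
#' designated species groups — e.g. `list(nonsalmonid = list(species =
#' c("stickleback", ...), min = 1))` drops clusters whose members all come
#' from outside that group (the device used to discard lineage-specific
#' clusters).
#'
#' @param clusters an `ortholog_clusters` table.
#' @param min_species minimum distinct species per cluster (>= 2).
#' @param required_groups named list of `list(species =, min =)` constraints.
#' @param known_species optional character vector of all valid species names
#'   used to validate the constraints (defaults to species seen in
#'   `clusters`).
#' @return The filtered table, with `attr(, "n_removed")`.
#' @export
filter_coverage <- function(clusters, min_species = 2L, required_groups = NULL,
                            known_species = NULL) {
  stopifnot(min_species >= 2L)
  known <- known_species %||% unique(clusters$species)
  for (gname in names(required_groups)) {
    g <- required_groups[[gname]]
    unknown <- setdiff(g$species, known)
    if (length(unknown)) {
      stop("unknown species in constraint '", gname, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  ids <- unique(clusters$cluster_id)
  keep <- vapply(ids, function(cid) {
    sp <- clusters$species[clusters$cluster_id == cid]
    if (length(unique(sp)) < min_species) return(FALSE)
    for (g in required_groups) {
      if (sum(sp %in% g$species) < (g$min %||% 1L)) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- as_clusters(clusters[clusters$cluster_id %in% ids[keep], , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Summarise a cluster set
#'
#' @param clusters an `ortholog_clusters` table.
#' @param genic optional named logical vector (cluster_id -> genic flag)
#'   from [annotate_clusters()].
#' @return A list with `n_clusters`, `species_presence` (named count of
#'   clusters containing each species), `cluster_sizes` (table), and, when
#'   annotation is supplied, `n_genic` and `pct_genic`.
#' @export
report_cluster_stats <- function(clusters, genic = NULL) {
  ids <- unique(clusters$cluster_id)
  presence <- if (nrow(clusters)) {
    tab <- table(unique(clusters[, c("cluster_id", "species")])$species)
    setNames(as.integer(tab), names(tab))
  } else integer(0)
  out <- list(
    n_clusters = length(ids),
    species_presence = presence,
    cluster_sizes = table(table(clusters$cluster_id))
  )
  if (!is.null(genic)) {
    g <- genic[ids]
    out$n_genic <- sum(g, na.rm = TRUE)
    out$pct_genic <- if (length(ids)) round(100 * out$n_genic / length(ids), 1) else NA_real_
  }
  out
}

#' Write cluster membership as tab-separated text
#'
#' @param clusters an `ortholog_clusters` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters[, c("cluster_id", "species", "locus_id", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
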