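#' Pairwise distances from a variant supermatrix
#'
#' Distances use pairwise deletion: for each species pair only columns where
#' both have data (not `N`) are compared. `p` is the mismatch proportion
#' over those shared columns; the JC69 transform is
#' `d = -(3/4) ln(1 - 4p/3)`. A pair with no shared columns, or with
#' `p >= 0.75` under JC69, is an error naming the pair.
#'
#' @param m a `variant_supermatrix`.
#' @param model `"p"` (p-distance, default) or `"JC69"`.
#' @return A symmetric `dist` object over the species.
#' @export
variant_distances <- function(m, model = c("p", "JC69")) {
  model <- match.arg(model)
  stopifnot(inherits(m, "variant_supermatrix"))
  enc <- encode_matrix(m$matrix)
  d <- distances_from_codes(enc, model, m$species)
  as.dist(d)
}

encode_matrix <- function(mat) {
  enc <- matrix(match(mat, c("A", "C", "G", "T")), nrow = nrow(mat))
  rownames(enc) <- rownames(mat)
  enc
}

distances_from_codes <- function(enc, model, species) {
  ns <- nrow(enc)
  d <- matrix(0, ns, ns, dimnames = list(species, species))
  if (ns < 2L) return(d)
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      shared <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      n_shared <- sum(shared)
      if (n_shared == 0L) {
        stop("no shared non-missing columns between ", species[i], " and ", species[j])
      }
      p <- sum(enc[i, shared] != enc[j, shared]) / n_shared
      if (model == "JC69") {
        if (p >= 0.75) {
          stop("JC69 distance undefined (p >= 0.75) between ",
               species[i], " and ", species[j])
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree with negative-branch clamping
#'
#' Standard neighbor joining (Saitou-Nei agglomeration). Negative branch
#' lengths — an artefact of non-additive distances — are clamped to zero,
#' with the total clamped length recorded in `attr(, "clamped")`.
#'
#' @param d a `dist` or symmetric matrix over >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3L) stop("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(as.dist(dm))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- deficit
  tr
}

#' Bootstrap support for the point-estimate tree
#'
#' Resamples supermatrix columns with replacement `n_replicates` times,
#' rebuilds the distance tree per replicate, and scores each internal
#' bipartition of the point tree by the percentage of replicate trees
#' containing it. Replicates whose distances are undefined (no shared
#' columns for some pair, or JC69 saturation) are skipped and excluded from
#' the denominator; the number skipped is in `attr(, "n_failed")`.
#' Deterministic given `seed`.
#'
#' @param m a `variant_supermatrix` with >= 3 species.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param model distance model passed to [variant_distances()].
#' @return The point-estimate `phylo` tree with `node.label` set to rounded
#'   percentage support (the root label is `NA`).
#' @export
bootstrap_support <- function(m, n_replicates = 1000L, seed = 1L,
                              model = c("p", "JC69")) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1L)
  enc <- encode_matrix(m$matrix)
  point <- nj_tree(distances_from_codes(enc, model, m$species))
  set.seed(seed)
  n_col <- ncol(enc)
  reps <- vector("list", n_replicates)
  ok <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    tr <- tryCatch(
      nj_tree(distances_from_codes(enc[, cols, drop = FALSE], model, m$species)),
      error = function(e) NULL
    )
    if (!is.null(tr)) {
      ok <- ok + 1L
      reps[[ok]] <- tr
    }
  }
  if (ok == 0L) stop("all bootstrap replicates failed")
  reps <- reps[seq_len(ok)]
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.character(round(100 * counts / ok))
  support[1] <- "" # root: trivial bipartition
  point$node.label <- support
  attr(point, "n_failed") <- n_replicates - ok
  attr(point, "n_replicates") <- n_replicates
  point
}

#' Robinson-Foulds distance between two topologies
#'
#' The count of bipartitions present in exactly one of the two unrooted
#' trees; 0 means identical topologies.
#'
#' @param tree_a,tree_b `phylo` trees over the same leaf set.
#' @return Integer RF distance.
#' @export
compare_topologies <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label)) {
    stop("trees have different leaf sets")
  }
  as.integer(suppressMessages(phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b),
                                                check.labels = TRUE)))
}
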