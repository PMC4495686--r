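#' Configuration for the RAD-locus dataset simulator
#'
#' Defines the study conditions for a simulated multi-species, multi-study
#' consensus RAD-locus dataset: ancestral loci evolve down a known species
#' tree under a nucleotide substitution model; restriction-site loss removes a
#' locus from every descendant of the branch on which the loss occurred;
#' paralogous duplicates and per-study technical dropout emulate the
#' nuisances the downstream filters must handle.
#'
#' @param tree newick string; branch lengths in expected substitutions/site.
#' @param n_loci number of ancestral loci.
#' @param locus_length locus length in bp (consensus RAD reads; default 60).
#' @param recognition_site restriction-site sequence whose remnant prefixes
#'   every locus (default `CCTGCAGG`, the SbfI site; reads start with the
#'   post-cut `TGCAGG` overhang remnant).
#' @param site_loss_rate per-unit-branch-length hazard of restriction-site
#'   loss (>= 0). A locus is absent from a species if any branch on the
#'   root-to-leaf path triggered loss, each with probability
#'   `1 - exp(-site_loss_rate * branch_length)`. Loss is absorbing (no
#'   regain). This rate is a free parameter of the simulator.
#' @param paralog_fraction proportion of ancestral loci duplicated at the
#'   root into a paralogous copy, in \[0, 1\].
#' @param paralog_extra_divergence extra divergence (substitutions/site)
#'   applied to each paralog copy before it evolves down the tree.
#' @param n_studies_per_species number of independent "study" replicates of
#'   each species' locus set.
#' @param study_dropout_rate per-study probability that a locus present in
#'   the species is missing from a given study's file, in \[0, 1\].
#' @param substitution_model `"JC69"` or `"K2P"`.
#' @param kappa transition/transversion rate ratio (K2P only, > 0).
#' @param indel_rate optional per-site per-unit-branch-length deletion hazard
#'   (default 0; used only to stress-test the aligner — consensus RAD loci
#'   are essentially indel-free).
#' @param seed integer master seed. Stage-specific streams (evolution, site
#'   loss, paralogs, study replication) use fixed small offsets from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_loci, locus_length = 60L,
                              recognition_site = "CCTGCAGG",
                              site_loss_rate = 0.5,
                              paralog_fraction = 0.05,
                              paralog_extra_divergence = 0.05,
                              n_studies_per_species = 1L,
                              study_dropout_rate = 0,
                              substitution_model = c("JC69", "K2P"),
                              kappa = 2, indel_rate = 0, seed = 1L) {
  substitution_model <- match.arg(substitution_model)
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                  error = function(e) NULL)
  if (is.null(phy)) stop("tree does not parse as newick")
  if (ape::Ntip(phy) < 2L) stop("tree must have at least 2 leaves")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  stopifnot(
    n_loci >= 1L, locus_length >= 1L,
    nchar(recognition_site) >= 4L,
    !grepl("[^ACGT]", recognition_site),
    site_loss_rate >= 0,
    paralog_fraction >= 0, paralog_fraction <= 1,
    paralog_extra_divergence >= 0,
    n_studies_per_species >= 1L,
    study_dropout_rate >= 0, study_dropout_rate <= 1,
    kappa > 0, indel_rate >= 0
  )
  structure(list(
    tree = tree, phy = phy, n_loci = as.integer(n_loci),
    locus_length = as.integer(locus_length),
    recognition_site = toupper(recognition_site),
    site_loss_rate = site_loss_rate,
    paralog_fraction = paralog_fraction,
    paralog_extra_divergence = paralog_extra_divergence,
    n_studies_per_species = as.integer(n_studies_per_species),
    study_dropout_rate = study_dropout_rate,
    substitution_model = substitution_model, kappa = kappa,
    indel_rate = indel_rate, seed = as.integer(seed)
  ), class = "simulation_config")
}

BASES <- c("A", "C", "G", "T")

## integer-coded (1..4) substitution step along one branch of length b
mutate_codes <- function(codes, b, model, kappa) {
  if (b == 0 || length(codes) == 0L) return(codes)
  if (model == "JC69") {
    p <- 0.75 * (1 - exp(-4 * b / 3))
    hit <- runif(length(codes)) < p
    if (any(hit)) {
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
    }
  } else { # K2P: A<->G, C<->T are transitions
    a <- kappa / (kappa + 2)  # transition rate (total rate scaled to 1)
    be <- 1 / (kappa + 2)     # each transversion rate
    p_ts <- 0.25 + 0.25 * exp(-4 * be * b) - 0.5 * exp(-2 * (a + be) * b)
    p_tv <- 0.25 - 0.25 * exp(-4 * be * b)
    u <- runif(length(codes))
    ts_partner <- c(3L, 4L, 1L, 2L)
    tv1 <- c(2L, 1L, 2L, 1L)
    tv2 <- c(4L, 3L, 4L, 3L)
    is_ts <- u < p_ts
    is_tv1 <- !is_ts & u < p_ts + p_tv
    is_tv2 <- !is_ts & !is_tv1 & u < p_ts + 2 * p_tv
    new <- codes
    new[is_ts] <- ts_partner[codes[is_ts]]
    new[is_tv1] <- tv1[codes[is_tv1]]
    new[is_tv2] <- tv2[codes[is_tv2]]
    codes <- new
  }
  codes
}

codes_to_seq <- function(codes) paste(BASES[codes], collapse = "")

#' Simulate a multi-species, multi-study RAD-locus dataset with ground truth
#'
#' Ancestral loci (optionally duplicated into paralogs) evolve along the
#' configured tree; restriction-site loss prunes loci from clades; each
#' species' surviving locus set is replicated into per-study files with
#' independent technical dropout. Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @return A list of class `rad_simulation`:
#'   * `loci` — a [rad_loci] table of every emitted record, ids
#'     `species|study|serial`;
#'   * `truth` — list with `ortholog_map` (emitted id -> ancestral id),
#'     `present_in` (ancestral id -> species vector, before study dropout),
#'     `is_paralog` (emitted id -> logical) and `true_tree` (newick);
#'   * `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  phy <- config$phy
  L <- config$locus_length
  remnant <- config$recognition_site
  remnant <- substring(remnant, max(1L, nchar(remnant) - 5L)) # post-cut overhang
  if (nchar(remnant) >= L) remnant <- substring(remnant, 1L, max(0L, L - 1L))
  rem_codes <- match(strsplit(remnant, "")[[1]], BASES)
  n_rand <- L - length(rem_codes)

  ## --- stage 1: ancestral loci + paralog duplication (streams 1 and 3) ---
  set.seed(config$seed + 1L)
  n <- config$n_loci
  anc <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(n)) {
    anc[i, ] <- c(rem_codes, sample.int(4L, n_rand, replace = TRUE))
  }
  anc_ids <- sprintf("anc%05d", seq_len(n))

  set.seed(config$seed + 3L)
  n_par <- round(config$paralog_fraction * n)
  if (n_par > 0L) {
    parents <- sort(sample.int(n, n_par))
    par_mat <- anc[parents, , drop = FALSE]
    for (i in seq_len(n_par)) {
      par_mat[i, ] <- mutate_codes(par_mat[i, ], config$paralog_extra_divergence,
                                   config$substitution_model, config$kappa)
    }
    anc <- rbind(anc, par_mat)
    anc_ids <- c(anc_ids, sprintf("anc%05dp", parents))
  }
  n_tot <- nrow(anc)
  paralog_flag <- c(rep(FALSE, n), rep(TRUE, n_par))

  ## --- stage 2: evolution + site loss down the tree (streams 1 and 2) ---
  ## Preorder traversal; per-node sequence matrix and presence vector.
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  edges <- phy$edge
  elen <- phy$edge.length
  children <- split(seq_len(nrow(edges)), edges[, 1])

  ## draw site-loss events per edge with a dedicated stream so evolution and
  ## loss are independently reproducible
  set.seed(config$seed + 2L)
  loss <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    p_loss <- 1 - exp(-config$site_loss_rate * elen[e])
    loss[[e]] <- runif(n_tot) < p_loss
  }

  set.seed(config$seed + 1L) # evolution stream continues from ancestral draw
  ## re-advance past ancestral draws is unnecessary: a fresh set.seed gives a
  ## deterministic evolution stream of its own
  node_seq <- vector("list", ntip + phy$Nnode)
  node_pres <- vector("list", ntip + phy$Nnode)
  node_seq[[root]] <- anc
  node_pres[[root]] <- rep(TRUE, n_tot)
  stack <- root
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    for (e in children[[as.character(nd)]]) {
      child <- edges[e, 2]
      b <- elen[e]
      mat <- node_seq[[nd]]
      if (b > 0) {
        if (config$indel_rate == 0) {
          mat <- matrix(
            mutate_codes(as.integer(mat), b, config$substitution_model, config$kappa),
            nrow = nrow(mat)
          )
        } else {
          mat <- lapply(seq_len(n_tot), function(i) {
            s <- mutate_codes(as.integer(mat[i, !is.na(mat[i, ])]), b,
                              config$substitution_model, config$kappa)
            keep <- runif(length(s)) >= (1 - exp(-config$indel_rate * b))
            s[keep]
          })
          maxl <- max(lengths(mat))
          mat <- t(vapply(mat, function(s) c(s, rep(NA_integer_, maxl - length(s))), integer(maxl)))
        }
      }
      node_seq[[child]] <- mat
      node_pres[[child]] <- node_pres[[nd]] & !loss[[e]]
      if (child > ntip) stack <- c(stack, child)
    }
  }

  present_in <- lapply(seq_len(n_tot), function(i) {
    phy$tip.label[vapply(seq_len(ntip), function(t) node_pres[[t]][i], logical(1))]
  })
  names(present_in) <- anc_ids

  ## --- stage 3: study replication + dropout (stream 4) ---
  set.seed(config$seed + 4L)
  rec_id <- list(); rec_sp <- list(); rec_st <- list(); rec_seq <- list()
  rec_anc <- list()
  kk <- 0L
  for (t in seq_len(ntip)) {
    sp <- phy$tip.label[t]
    idx <- which(node_pres[[t]])
    if (!length(idx)) next
    serial <- sample.int(length(idx)) # species-local numbering
    mat <- node_seq[[t]]
    seqs <- vapply(idx, function(i) codes_to_seq(mat[i, !is.na(mat[i, ])]), "")
    for (j in seq_len(config$n_studies_per_species)) {
      keep <- runif(length(idx)) >= config$study_dropout_rate
      if (!any(keep)) next
      kk <- kk + 1L
      rec_id[[kk]] <- sprintf("%s|study%d|L%05d", sp, j, serial[keep])
      rec_sp[[kk]] <- rep(sp, sum(keep))
      rec_st[[kk]] <- rep(sprintf("study%d", j), sum(keep))
      rec_seq[[kk]] <- seqs[keep]
      rec_anc[[kk]] <- anc_ids[idx[keep]]
    }
  }
  ids <- unlist(rec_id)
  loci <- rad_loci(
    id = if (is.null(ids)) character() else ids,
    species = unlist(rec_sp) %||% character(),
    study = unlist(rec_st) %||% character(),
    seq = unlist(rec_seq) %||% character()
  )
  anc_of <- setNames(unlist(rec_anc) %||% character(), ids)
  truth <- list(
    ortholog_map = anc_of,
    present_in = present_in,
    true_tree = config$tree,
    is_paralog = setNames(grepl("p$", anc_of), names(anc_of))
  )
  structure(list(loci = loci, truth = truth, config = config),
            class = "rad_simulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset as per-species per-study FASTA files
#'
#' @param sim a `rad_simulation` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written FASTA paths (named
#'   `species:study`), invisibly.
#' @export
write_dataset_fasta <- function(sim, dir) {
  stopifnot(inherits(sim, "rad_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  loci <- sim$loci
  key <- paste(loci$species, loci$study, sep = ":")
  paths <- character(0)
  for (k in sort(unique(key))) {
    sub <- loci[key == k, , drop = FALSE]
    f <- file.path(dir, paste0(gsub(":", "_", k), ".fasta"))
    write_loci_fasta(sub, f)
    paths[k] <- f
  }
  invisible(paths)
}

#' Write ground truth to a structured text file
#'
#' Tab-separated sections: a header with the true tree, one row per emitted
#' locus (`id`, `ancestral`, `is_paralog`), and one row per ancestral locus
#' (`ancestral`, comma-separated species list). Round-trips losslessly via
#' [read_truth()].
#'
#' @param truth the `truth` element of a `rad_simulation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#radortho-truth\tv1", con)
  writeLines(paste0("#tree\t", truth$true_tree), con)
  writeLines("[loci]", con)
  ids <- names(truth$ortholog_map)
  if (length(ids)) {
    writeLines(paste(ids, truth$ortholog_map[ids],
                     ifelse(truth$is_paralog[ids], "1", "0"), sep = "\t"), con)
  }
  writeLines("[presence]", con)
  anc <- names(truth$present_in)
  if (length(anc)) {
    writeLines(paste(anc,
                     vapply(truth$present_in, function(x) paste(x, collapse = ","), ""),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a ground-truth file written by [write_truth()]
#'
#' @param path truth file path.
#' @return A truth list (`ortholog_map`, `present_in`, `true_tree`,
#'   `is_paralog`).
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#radortho-truth")) stop("not a radortho truth file")
  tree <- sub("^#tree\t", "", lines[startsWith(lines, "#tree\t")][1])
  iloci <- which(lines == "[loci]")
  ipres <- which(lines == "[presence]")
  loci_lines <- if (ipres > iloci + 1L) lines[(iloci + 1L):(ipres - 1L)] else character()
  pres_lines <- if (ipres < length(lines)) lines[(ipres + 1L):length(lines)] else character()
  om <- character(0); ip <- logical(0)
  if (length(loci_lines)) {
    parts <- strsplit(loci_lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    om <- setNames(vapply(parts, `[`, "", 2L), ids)
    ip <- setNames(vapply(parts, `[`, "", 3L) == "1", ids)
  }
  pi <- list()
  if (length(pres_lines)) {
    parts <- strsplit(pres_lines, "\t", fixed = TRUE)
    anc <- vapply(parts, `[`, "", 1L)
    pi <- setNames(lapply(parts, function(p) {
      if (length(p) < 2L || p[2] == "") character(0) else strsplit(p[2], ",", fixed = TRUE)[[1]]
    }), anc)
  }
  list(ortholog_map = om, present_in = pi, true_tree = tree, is_paralog = ip)
}
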