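## helper: unique-hit rows from a list of directed pairs (q, s, species)
hit_rows <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(query_id = p[[1]], subject_id = p[[2]],
               query_species = p[[3]], subject_species = p[[4]],
               strand = if (length(p) >= 5) p[[5]] else "+",
               aln_length = 60L, identity = 1,
               mismatches = 0L, gaps = 0L, score = 60, qstart = 1L,
               qend = 60L, sstart = 1L, send = 60L, rank = 1L)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

cluster_sets <- function(clusters) {
  unname(lapply(split(clusters$locus_id, clusters$cluster_id), sort))
}

test_that("RBH edges require reciprocity", {
  ## a<->b reciprocal; c->d but d->c' not reciprocal
  h <- hit_rows(list(
    list("a1", "b1", "A", "B"), list("b1", "a1", "B", "A"),
    list("c1", "d1", "C", "D"), list("d1", "c2", "D", "C")
  ))
  g <- build_rbh_graph(h)
  expect_equal(igraph::ecount(g), 1)
  e <- igraph::as_data_frame(g, what = "edges")
  expect_setequal(c(e$from, e$to), c("a1", "b1"))
})

test_that("triangle of reciprocal hits yields one 3-species cluster", {
  h <- hit_rows(list(
    list("a1", "b1", "A", "B"), list("b1", "a1", "B", "A"),
    list("a1", "c1", "A", "C"), list("c1", "a1", "C", "A"),
    list("b1", "c1", "B", "C"), list("c1", "b1", "C", "B")
  ))
  cl <- infer_clusters(build_rbh_graph(h))
  expect_equal(cluster_sets(cl), list(c("a1", "b1", "c1")))
})

test_that("a path a-b-c without the closing edge yields two 2-clusters in clique mode", {
  h <- hit_rows(list(
    list("a1", "b1", "A", "B"), list("b1", "a1", "B", "A"),
    list("b1", "c1", "B", "C"), list("c1", "b1", "C", "B")
  ))
  g <- build_rbh_graph(h)
  cl <- infer_clusters(g, "clique")
  expect_equal(cluster_sets(cl), list(c("a1", "b1"), c("b1", "c1")))
  comp <- infer_clusters(g, "component")
  expect_equal(cluster_sets(comp), list(c("a1", "b1", "c1")))
})

test_that("clique enumeration equals brute-force subset enumeration on random RBH graphs", {
  set.seed(30)
  for (rep in 1:40) {
    n <- sample(4:15, 1)
    n_species <- sample(3:5, 1)
    species <- sample(LETTERS[1:n_species], n, replace = TRUE)
    ids <- sprintf("%s%02d", species, 1:n)
    adj <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (species[i] != species[j] && runif(1) < 0.4) {
        adj[i, j] <- adj[j, i] <- 1L
      }
    }
    pairs <- which(adj == 1L & upper.tri(adj), arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    h <- hit_rows(unlist(lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      list(list(ids[i], ids[j], species[i], species[j]),
           list(ids[j], ids[i], species[j], species[i]))
    }), recursive = FALSE))
    got <- cluster_sets(infer_clusters(build_rbh_graph(h), "clique"))
    want <- brute_max_cliques(adj)
    expect_equal(got[order(vapply(got, paste, "", collapse = "|"))], want)
  }
})

test_that("clusters sharing a locus are removed wholesale", {
  cl <- data.frame(
    cluster_id = c("CL1", "CL1", "CL1", "CL2", "CL2", "CL2", "CL3", "CL3"),
    locus_id = c("a", "b", "c", "a", "d", "e", "f", "g"),
    species = c("A", "B", "C", "A", "D", "E", "A", "B"),
    strand = "+"
  )
  out <- remove_multi_cluster_sequences(cl)
  expect_equal(unique(out$cluster_id), "CL3")
  expect_equal(attr(out, "n_removed"), 2)
  ## disjoint clusters unchanged
  out2 <- remove_multi_cluster_sequences(out)
  expect_equal(nrow(out2), nrow(out))
  expect_equal(attr(out2, "n_removed"), 0)
})

test_that("clusters with within-species duplicates are removed", {
  cl <- data.frame(
    cluster_id = c("CL1", "CL1", "CL1", "CL2", "CL2"),
    locus_id = c("a1", "a2", "b1", "c1", "d1"),
    species = c("A", "A", "B", "C", "D"),
    strand = "+"
  )
  out <- remove_multi_species_duplicates(cl)
  expect_equal(unique(out$cluster_id), "CL2")
  expect_equal(attr(out, "n_removed"), 1)
})

test_that("coverage filter enforces min species and group constraints", {
  cl <- data.frame(
    cluster_id = rep(c("CL1", "CL2", "CL3"), times = c(3, 5, 2)),
    locus_id = paste0("x", 1:10),
    species = c("sal1", "sal2", "sal3",
                "sal1", "sal2", "sal3", "sal4", "stick",
                "sal1", "stick"),
    strand = "+"
  )
  out <- filter_coverage(cl, min_species = 3)
  expect_setequal(unique(out$cluster_id), c("CL1", "CL2"))

  nonsal <- list(nonsalmonid = list(species = "stick", min = 1))
  out2 <- filter_coverage(cl, min_species = 3, required_groups = nonsal)
  expect_equal(unique(out2$cluster_id), "CL2")

  ## complete cluster kept at min_species = all
  out3 <- filter_coverage(cl, min_species = 5)
  expect_equal(unique(out3$cluster_id), "CL2")

  expect_error(
    filter_coverage(cl, 3, list(g = list(species = "nosuch", min = 1))),
    "unknown species"
  )
})

test_that("cluster count is monotone non-increasing in min_species", {
  cfg <- simulation_config(
    "(((a:0.01,b:0.01):0.005,c:0.015):0.005,(d:0.012,e:0.012):0.008);",
    n_loci = 120, site_loss_rate = 2, paralog_fraction = 0, seed = 33
  )
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$loci, pipeline_config("salmonid-strict",
                                                min_species = 2, n_bootstrap = 0))
  counts <- vapply(2:5, function(k) {
    nrow(unique(filter_coverage(res$clusters, k)[, "cluster_id", drop = FALSE]))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("zero-divergence synthetic clusters match ground-truth ortholog groups", {
  cfg <- simulation_config("((a:0,b:0):0,(c:0,d:0):0);", n_loci = 60,
                           site_loss_rate = 0, paralog_fraction = 0,
                           study_dropout_rate = 0, seed = 34)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$loci, pipeline_config("salmonid-strict",
                                                min_species = 4, n_bootstrap = 0))
  expect_equal(res$summary$n_orthologous_loci, 60)
  truth_groups <- split(names(sim$truth$ortholog_map), sim$truth$ortholog_map)
  got <- cluster_sets(res$clusters)
  want <- unname(lapply(truth_groups, sort))
  expect_setequal(lapply(got, paste, collapse = "|"),
                  lapply(want, paste, collapse = "|"))
})

test_that("paralog-contaminated clusters are purged against ground truth", {
  cfg <- simulation_config("((a:0.008,b:0.008):0.004,(c:0.01,d:0.01):0.004);",
                           n_loci = 80, site_loss_rate = 0,
                           paralog_fraction = 0.15, paralog_extra_divergence = 0.02,
                           seed = 35)
  sim <- simulate_dataset(cfg)
  res <- run_pipeline(sim$loci, pipeline_config("salmonid-strict",
                                                min_species = 2, n_bootstrap = 0))
  ## no surviving cluster mixes a paralog with its parent lineage loci:
  ## every cluster's members map to one ancestral locus
  anc <- sim$truth$ortholog_map
  per_cluster <- split(anc[res$clusters$locus_id], res$clusters$cluster_id)
  expect_true(all(vapply(per_cluster, function(x) length(unique(x)) == 1L, logical(1))))
})

test_that("cluster stats report counts and per-species presence", {
  cl <- data.frame(
    cluster_id = rep(c("CL1", "CL2"), times = c(3, 2)),
    locus_id = paste0("x", 1:5),
    species = c("a", "b", "c", "a", "b"),
    strand = "+"
  )
  st <- report_cluster_stats(cl)
  expect_equal(st$n_clusters, 2)
  expect_equal(st$species_presence, c(a = 2L, b = 2L, c = 1L))
  g <- setNames(c(TRUE, FALSE), c("CL1", "CL2"))
  st2 <- report_cluster_stats(cl, genic = g)
  expect_equal(st2$n_genic, 1)
  expect_equal(st2$pct_genic, 50.0)
  st0 <- report_cluster_stats(cl[0, ])
  expect_equal(st0$n_clusters, 0)
})
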