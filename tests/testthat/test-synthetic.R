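two_taxon_params <- function(tau, seed = 1, n_ind = 2, loci = c(non_rearranged = 10),
                             len = 100, mu = 0.002, intro = NULL) {
  st <- read_tree(text = sprintf("(A:%g,B:%g);", tau, tau))
  sim_params(st, groups = setNames(c("g", "g"), c("A", "B")),
             n_individuals = n_ind, loci_per_class = loci, locus_length = len,
             mu = mu, introgression = intro, seed = seed)
}

coal_time <- function(tree, a, b) {
  ape::cophenetic.phylo(tree)[a, b] / 2
}

test_that("gene trees are reproducible and respect the species tree", {
  p <- two_taxon_params(tau = 10, seed = 3)
  g1 <- simulate_gene_tree(p, "non_rearranged", 1)
  g2 <- simulate_gene_tree(p, "non_rearranged", 1)
  expect_identical(ape::write.tree(g1$tree), ape::write.tree(g2$tree))
  g3 <- simulate_gene_tree(p, "non_rearranged", 2)
  expect_false(identical(ape::write.tree(g1$tree), ape::write.tree(g3$tree)))

  # without introgression every between-taxon coalescence predates the split
  for (i in 1:10) {
    tr <- simulate_gene_tree(p, "non_rearranged", i)$tree
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
    expect_gt(coal_time(tr, "A_1", "B_1"), 10)
    expect_false(simulate_gene_tree(p, "non_rearranged", i)$truth$introgressed)
  }
})

test_that("a certain pulse reroutes the recipient into the donor population", {
  # one lineage per taxon: after a pulse at 0.01 the pair coalesces like two
  # lineages in a single population, E[T] = 0.01 + ne
  intro <- introgression_event("B", "A", time = 0.01,
                               p = c(non_rearranged = 1))
  p <- two_taxon_params(tau = 6, seed = 11, n_ind = 1,
                        loci = c(non_rearranged = 200), intro = intro)
  times <- vapply(1:200, function(i) {
    sim <- simulate_gene_tree(p, "non_rearranged", i)
    expect_true(sim$truth$introgressed)
    coal_time(sim$tree, "A_1", "B_1")
  }, numeric(1L))
  expect_lt(abs(mean(times) - 1.01), 0.25)  # ~3.5 SD of the mean of 200 Exp(1)
  # the X class is untouched by this pulse: coalescence stays older than the split
  x_times <- vapply(1:50, function(i)
    coal_time(simulate_gene_tree(p, "X", i)$tree, "A_1", "B_1"), numeric(1L))
  expect_true(all(x_times > 6))
})

test_that("event times must predate the recipient's divergence", {
  intro <- introgression_event("B", "A", time = 8, p = c(X = 1))
  expect_error(two_taxon_params(tau = 6, intro = intro),
               class = "chromospec_validation_error")
  expect_error(introgression_event("B", "A", 1, p = c(X = 2)),
               class = "chromospec_validation_error")
  expect_error(introgression_event("B", "A", 1, p = c(Y = 0.5)),
               class = "chromospec_validation_error")
})

test_that("sequence simulation follows the JC69 closed form", {
  tr <- read_tree(text = "(A:2,B:2);")
  zero <- simulate_alignment(tr, 200, mu = 0, seed = 4)
  expect_equal(zero$seq["A", ], zero$seq["B", ])

  mu <- 0.01
  aln <- simulate_alignment(tr, 10000, mu = mu, seed = 8)
  p_hat <- pairwise_distance(paste(aln$seq["A", ], collapse = ""),
                             paste(aln$seq["B", ], collapse = ""))$distance
  p_exp <- 0.75 * (1 - exp(-8 / 3 * mu * 2))  # divergence time t = 2
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_hat - p_exp), 3 * se)

  expect_identical(simulate_alignment(tr, 50, mu = 0.01, seed = 21)$seq,
                   simulate_alignment(tr, 50, mu = 0.01, seed = 21)$seq)
})

test_that("karyotype simulation logs replayable events bounding parsimony", {
  ex <- example_species_tree()
  still <- simulate_karyotypes(ex$tree, n_characters = 5, base_rate = 0,
                               seed = 2)
  expect_true(all(as.matrix(still$matrix[-1L]) == "a"))
  expect_equal(nrow(still$truth$events), 0L)

  k <- simulate_karyotypes(ex$tree, n_characters = 200, base_rate = 0.01,
                           hotspot_fraction = 0.2, hotspot_multiplier = 10,
                           seed = 5)
  replay <- replay_karyotype_events(ex$tree, k$truth)
  expect_equal(as.data.frame(replay), as.data.frame(k$matrix))

  idx_ok <- vapply(seq_len(nrow(k$truth$characters)), function(i) {
    ch <- k$truth$characters$character[i]
    if (k$truth$characters$n_events[i] == 0) return(TRUE)
    st <- setNames(k$matrix[[ch]], k$matrix$taxon)
    parsimony_score(ex$tree, st)$min_changes <= k$truth$characters$n_events[i]
  }, logical(1L))
  expect_true(all(idx_ok))
  expect_error(simulate_karyotypes(ex$tree, state_alphabet = character(0)),
               class = "chromospec_validation_error")
})

test_that("dataset bundles are complete, deterministic, and pipeline-ready", {
  p <- introgression_scenario(seed = 9,
                              loci_per_class = c(X = 3, rearranged = 3,
                                                 non_rearranged = 3),
                              locus_length = 80)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b <- generate_dataset(p, dir = d1, karyotype = list(n_characters = 3,
                                                      base_rate = 0.02))
  expect_length(b$loci, 9L)
  expect_equal(sort(list.files(file.path(d1, "loci"))),
               sort(paste0(names(b$loci), ".fasta")))
  generate_dataset(p, dir = d2, karyotype = list(n_characters = 3,
                                                 base_rate = 0.02))
  files <- list.files(d1, recursive = TRUE)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  cfg <- pipeline_config(loci_dir = file.path(d1, "loci"),
                         taxon_map = file.path(d1, "taxon_map.tsv"),
                         class_map = file.path(d1, "class_map.tsv"),
                         karyotype_matrix = file.path(d1, "karyotype.csv"),
                         species_tree = file.path(d1, "species_tree.nwk"))
  res <- run_pipeline(cfg)
  expect_true(nrow(res$divergence) >= 6L)
})

test_that("deep splits drive taxon monophyly toward one", {
  # 4 deeply split taxa (>= 5 coalescent units), 10 x 500 bp = 5 kb
  st <- read_tree(text = "(((A:5,B:5):5,C:10):5,D:15);")
  fr <- vapply(1:20, function(r) {
    p <- sim_params(st, groups = setNames(rep("g", 4), st$tip.label),
                    loci_per_class = c(non_rearranged = 10),
                    locus_length = 500, mu = 0.002, seed = 100 + r)
    b <- generate_dataset(p, karyotype = FALSE)
    tr <- nj_fallback_tree(b$loci)
    monophyly_fraction(tr, b$taxon_map, rooted = FALSE)$fraction
  }, numeric(1L))
  expect_gte(mean(fr), 0.95)
})

test_that("the smaller effective size of the X speeds lineage sorting", {
  # no introgression; X at 3/4 Ne should sort at least as fast as autosomes
  wins <- vapply(1:20, function(r) {
    p <- introgression_scenario(seed = 300 + r, p = c(),
                                loci_per_class = c(X = 60,
                                                   non_rearranged = 60),
                                locus_length = 300)
    b <- generate_dataset(p, karyotype = FALSE)
    by_class <- split(b$loci, vapply(b$loci, function(a) a$class,
                                     character(1L)))
    fx <- monophyly_fraction(nj_fallback_tree(by_class$X), b$taxon_map,
                             rooted = FALSE)$fraction
    fa <- monophyly_fraction(nj_fallback_tree(by_class$non_rearranged),
                             b$taxon_map, rooted = FALSE)$fraction
    fx >= fa
  }, logical(1L))
  expect_gte(sum(wins), 16L)
})
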