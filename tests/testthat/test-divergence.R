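test_that("pairwise distances count mismatches with pairwise deletion", {
  expect_equal(pairwise_distance("AAAA", "AAAT"),
               list(distance = 0.25, compared_sites = 4L))
  expect_equal(pairwise_distance("AA-A", "AAAT"),
               list(distance = 1 / 3, compared_sites = 3L))
  # ambiguity codes are missing too
  expect_equal(pairwise_distance("AANA", "AAAT")$compared_sites, 3L)
  expect_equal(pairwise_distance("AAAA", "AAAT", model = "jc69")$distance,
               -0.75 * log(2 / 3), tolerance = 1e-9)
  expect_error(pairwise_distance("A-", "-T"),
               class = "chromospec_validation_error")
  expect_error(pairwise_distance("AAAA", "TTTT", model = "jc69"),
               "saturat", class = "chromospec_validation_error")
  expect_error(pairwise_distance("AAA", "AAAA"),
               class = "chromospec_validation_error")
})

test_that("p-distance is symmetric and JC69 dominates p", {
  withr::local_seed(7)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "-"), 30, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), 30, replace = TRUE),
               collapse = "")
    d1 <- pairwise_distance(a, b)
    expect_identical(d1, pairwise_distance(b, a))
    if (d1$distance > 0 && d1$distance < 0.75) {
      expect_gt(pairwise_distance(a, b, "jc69")$distance, d1$distance)
    }
  }
})

test_that("net divergence matches hand counting and the dA identity", {
  tm <- toy_taxon_map()
  aln <- locus_alignment(c(X1 = "AAAA", X2 = "AAAT", Y1 = "TTTT",
                           Y2 = "TTTA"), locus_id = "l1")
  r <- net_divergence(aln, tm, "X", "Y")
  expect_equal(r$d_x, 0.25)
  expect_equal(r$d_y, 0.25)
  expect_equal(r$d_xy, 0.875)
  expect_equal(r$d_a, 0.625)
  expect_equal(r$d_a, r$d_xy - (r$d_x + r$d_y) / 2)

  same <- locus_alignment(c(X1 = "ACGT", X2 = "ACGT", Y1 = "ACGT",
                            Y2 = "ACGT"))
  expect_equal(net_divergence(same, tm, "X", "Y")$d_a, 0)

  nodiv <- locus_alignment(c(X1 = "AAAA", X2 = "AAAA", Y1 = "AAAT",
                             Y2 = "AAAT"))
  r2 <- net_divergence(nodiv, tm, "X", "Y")
  expect_equal(r2$d_a, 0.25)
  expect_equal(r2$d_a, r2$d_xy)

  expect_error(net_divergence(aln, tm, "X", "Z"),
               class = "chromospec_validation_error")
})

test_that("a single sampled individual degrades dA to d_XY with a flag", {
  tm <- taxon_map(tibble::tibble(individual = c("X1", "Y1", "Y2"),
                                 taxon = c("X", "Y", "Y"), group = "g1"))
  aln <- locus_alignment(c(X1 = "AAAA", Y1 = "TTTT", Y2 = "TTTT"))
  r <- net_divergence(aln, tm, "X", "Y")
  expect_true(r$single_individual)
  expect_equal(r$d_x, 0)
  expect_equal(r$d_a, r$d_xy - r$d_y / 2)
})

test_that("class summaries are length-weighted and order-invariant", {
  tm <- toy_taxon_map()
  # two loci engineered to dA = 0.02 over 100 sites and 0.04 over 300 sites
  # with zero within-taxon diversity
  mk <- function(n, k, id) {
    x <- strrep("A", n)
    y <- paste0(strrep("T", k), strrep("A", n - k))
    locus_alignment(c(X1 = x, X2 = x, Y1 = y, Y2 = y), locus_id = id,
                    class = "rearranged")
  }
  l1 <- mk(100, 2, "l1")   # dA = 0.02
  l2 <- mk(300, 12, "l2")  # dA = 0.04
  s <- class_group_summary(list(l1, l2), tm)
  expect_equal(s$mean_dA, (2 + 12) / 400)  # 0.035
  expect_equal(s$n_loci, 2L)
  expect_equal(s$total_sites, 400)
  s_rev <- class_group_summary(list(l2, l1), tm)
  expect_equal(s_rev$mean_dA, s$mean_dA)

  one <- class_group_summary(list(l1), tm)
  expect_equal(one$mean_dA, net_divergence(l1, tm, "X", "Y")$d_a)

  expect_error(class_group_summary(list(l1), tm, classes = "X"),
               class = "chromospec_validation_error")
  solo <- taxon_map(tibble::tibble(individual = c("X1", "X2"), taxon = "X",
                                   group = "g1"))
  expect_error(class_group_summary(list(l1), solo),
               class = "chromospec_validation_error")
})

test_that("length-weighted aggregation equals concatenation", {
  withr::local_seed(31)
  tm <- toy_taxon_map()
  loci <- lapply(1:6, function(i) {
    a <- random_alignment(tm$individual, sample(40:120, 1L), p_missing = 0.1,
                          locus_id = paste0("l", i), class = "rearranged")
    a
  })
  s <- class_group_summary(loci, tm)
  cat_rec <- net_divergence(concat_alignments(loci), tm, "X", "Y")
  expect_equal(s$mean_dA, cat_rec$d_a, tolerance = 1e-12)
})

test_that("within-taxon diversity is pooled by class and scale-invariant", {
  tm <- toy_taxon_map()
  same <- locus_alignment(c(X1 = "ACGT", X2 = "ACGT", Y1 = "ACGT",
                            Y2 = "ACGT"), locus_id = "l1", class = "X")
  expect_equal(diversity_by_class(list(same), tm)$mean_diversity, 0)

  one <- locus_alignment(c(X1 = "AAAA", X2 = "AAAT"), locus_id = "l2",
                         class = "X")
  expect_equal(diversity_by_class(list(one), tm)$mean_diversity, 0.25)

  doubled <- locus_alignment(c(X1 = "AAAAAAAA", X2 = "AAATAAAT"),
                             locus_id = "l3", class = "X")
  expect_equal(diversity_by_class(list(one, doubled), tm)$mean_diversity,
               0.25)

  solo <- taxon_map(tibble::tibble(individual = "X1", taxon = "X",
                                   group = "g1"))
  expect_error(diversity_by_class(list(one), solo),
               class = "chromospec_validation_error")
})

test_that("bootstrap CIs are deterministic and collapse for constant data", {
  tm <- toy_taxon_map()
  mk <- function(id) locus_alignment(c(X1 = "AAAA", X2 = "AAAA",
                                       Y1 = "AAAT", Y2 = "AAAT"),
                                     locus_id = id, class = "rearranged")
  recs <- divergence_records(list(mk("l1"), mk("l2"), mk("l3")), tm)
  stat <- function(r) mean(r$d_a)
  ci <- bootstrap_ci(recs, stat, reps = 200, seed = 5)
  expect_equal(ci$lower, 0.25)
  expect_equal(ci$upper, 0.25)
  expect_identical(bootstrap_ci(recs, stat, reps = 200, seed = 5), ci)
  expect_error(bootstrap_ci(recs[recs$locus == "l1", ], stat, reps = 200,
                            seed = 1),
               class = "chromospec_validation_error")
  expect_error(bootstrap_ci(recs, stat, reps = 50, seed = 1),
               class = "chromospec_validation_error")
})
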