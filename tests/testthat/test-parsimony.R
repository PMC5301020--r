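quartet <- function() read_tree(text = "((A,B),(C,D));")

test_that("parsimony scores match hand-worked characters", {
  tr <- quartet()
  expect_equal(parsimony_score(tr, c(A = "a", B = "a", C = "m", D = "m"))$min_changes, 1)
  expect_equal(parsimony_score(tr, c(A = "a", B = "a", C = "a", D = "a"))$min_changes, 0)
  tr5 <- read_tree(text = "(((A,B),(C,D)),E);")
  expect_equal(parsimony_score(tr5, c(A = "m", B = "a", C = "m", D = "a",
                                      E = "a"))$min_changes, 2)
})

test_that("missing states contribute the full alphabet at zero cost", {
  tr <- quartet()
  full <- parsimony_score(tr, c(A = "a", B = "a", C = "m", D = "m"))
  miss <- parsimony_score(tr, c(A = "a", B = NA, C = "m", D = "m"))
  expect_equal(miss$min_changes, full$min_changes)
  expect_equal(miss$node_state_sets$B, c("a", "m"))
  # pruning a missing-state leaf leaves the score unchanged
  pruned <- parsimony_score(ape::drop.tip(tr, "B"),
                            c(A = "a", C = "m", D = "m"))
  expect_equal(pruned$min_changes, miss$min_changes)
  expect_error(parsimony_score(tr, c(A = NA, B = NA, C = NA, D = NA)),
               class = "chromospec_validation_error")
  expect_error(parsimony_score(tr, c(A = "a", B = "a", C = "m")),
               "D", class = "chromospec_validation_error")
})

test_that("MPR enumeration is complete, duplicate-free and self-consistent", {
  tr <- quartet()
  const <- enumerate_mprs(tr, c(A = "a", B = "a", C = "a", D = "a"))
  expect_length(const, 1L)
  expect_true(all(const[[1L]] == "a"))

  split <- enumerate_mprs(tr, c(A = "a", B = "a", C = "m", D = "m"))
  expect_length(split, 2L)
  expect_false(identical(split[[1L]], split[[2L]]))
  sc <- parsimony_score(tr, c(A = "a", B = "a", C = "m", D = "m"))$min_changes
  for (a in split) {
    expect_equal(chromospec:::assignment_changes(tr, a), sc)
  }
  expect_error(enumerate_mprs(tr, c(A = "a", B = "a", C = "m", D = "m"),
                              limit = 1),
               class = "chromospec_capacity_error")
})

test_that("origin ranges match hand-worked cases and honour root constraints", {
  tr <- quartet()
  one <- count_origins(tr, c(A = "m", B = "a", C = "a", D = "a"), "m")
  expect_equal(unname(one), c(1, 1))
  tr5 <- read_tree(text = "(((A,B),(C,D)),E);")
  two <- count_origins(tr5, c(A = "m", B = "a", C = "m", D = "a", E = "a"), "m")
  expect_equal(unname(two), c(2, 2))
  const <- count_origins(tr, c(A = "a", B = "a", C = "a", D = "a"), "a")
  expect_equal(unname(const), c(0, 0))
  # fixing the root at the derived state turns the split character into a
  # single loss rather than a single gain
  rooted <- count_origins(tr, c(A = "a", B = "a", C = "m", D = "m"), "a",
                          root_state = "m")
  expect_equal(unname(rooted), c(1, 1))
  expect_error(count_origins(tr, c(A = "a", B = "a", C = "a", D = "a"), "a",
                             root_state = "m"),
               class = "chromospec_validation_error")
})

test_that("reconstruction agrees with the brute-force oracle on random cases", {
  withr::local_seed(421)
  for (i in 1:40) {
    case <- random_parsimony_case(sample(4:8, 1L), sample(2:4, 1L))
    orc <- oracle_reconstruction(case$tree, case$states)
    ps <- parsimony_score(case$tree, case$states)
    expect_equal(ps$min_changes, orc$min_changes,
                 info = paste("case", i))
    for (s in orc$alphabet) {
      expect_equal(unname(count_origins(case$tree, case$states, s)),
                   unname(orc$origins(s)), info = paste("case", i, "state", s))
    }
    # enumeration is complete and duplicate-free
    mprs <- enumerate_mprs(case$tree, case$states, limit = 1e6)
    expect_equal(length(mprs), length(unique(lapply(mprs, unname))))
    expect_equal(length(mprs), orc$n_opt)
  }
})

test_that("adding a taxon never decreases the minimum change count", {
  withr::local_seed(99)
  for (i in 1:20) {
    case <- random_parsimony_case(sample(5:8, 1L), sample(2:3, 1L),
                                  p_missing = 0)
    full <- parsimony_score(case$tree, case$states)$min_changes
    drop <- sample(case$tree$tip.label, 1L)
    sub <- ape::drop.tip(case$tree, drop)
    st <- case$states[sub$tip.label]
    if (length(unique(st[!is.na(st)])) == 0L) next
    expect_lte(parsimony_score(sub, st)$min_changes, full)
  }
})

test_that("a step-cost matrix is honoured (Sankoff hook)", {
  tr <- quartet()
  ch <- c(A = "a", B = "a", C = "m", D = "m")
  cost <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(parsimony_score(tr, ch, cost = cost)$min_changes, 3)
})

test_that("map_events composes reconstructions, flags homoplasy, marks ambiguity", {
  tr5 <- read_tree(text = "(((A,B),(C,D)),E);")
  km <- karyotype_matrix(tibble::tibble(
    taxon = c("A", "B", "C", "D", "E"),
    chr1 = "a",                                  # constant
    chr2 = c("m", "a", "a", "a", "a"),           # single origin on branch A
    chr3 = c("m", "a", "m", "a", "a"),           # homoplasious (2 origins)
    chr4 = c("m", "m", "a", "a", NA)))           # root state ambiguous
  ev <- map_events(tr5, km)
  expect_s3_class(ev, "karyotype_events")
  expect_equal(ev$summary$min_changes, c(0, 1, 2, 1))
  expect_equal(ev$summary$homoplasious, c(FALSE, FALSE, TRUE, FALSE))
  chr2 <- ev$events[ev$events$character == "chr2", ]
  expect_equal(nrow(chr2), 1L)
  expect_equal(chr2$branch, "A")
  expect_equal(chr2$event_kind, "origin")
  expect_false(chr2$ambiguous)
  chr3 <- ev$events[ev$events$character == "chr3", ]
  expect_true(all(c("A", "C") %in% chr3$branch))
  # tidy/glance accessors
  expect_equal(tidy(ev), ev$events)
  g <- glance(ev)
  expect_equal(g$n_characters, 4L)
  expect_equal(g$n_homoplasious, 1L)
  # chr4's root can be either state in an MPR: reported unresolved, and its
  # event placements are flagged ambiguous
  expect_gt(length(ev$results$chr4$unresolved_nodes), 0L)
  expect_true(all(ev$events$ambiguous[ev$events$character == "chr4"]))
  expect_error(map_events(read_tree(text = "((A,B),(C,X));"), km),
               class = "chromospec_validation_error")
})

test_that("ambiguous placements are reported, or resolved early/late on request", {
  # A=m, B=m, C=a, D=a on an unbalanced tree: one change, but its branch
  # placement is unambiguous only across the AB clade
  tr <- read_tree(text = "(((A,B),C),D);")
  km <- karyotype_matrix(tibble::tibble(taxon = c("A", "B", "C", "D"),
                                        chr1 = c("m", "m", "a", "a")))
  all_ev <- map_events(tr, km)$events
  expect_true(nrow(all_ev) >= 1L)
  acc <- map_events(tr, km, resolve = "acctran")$events
  del <- map_events(tr, km, resolve = "deltran")$events
  expect_equal(nrow(acc), 1L)
  expect_equal(nrow(del), 1L)
})
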