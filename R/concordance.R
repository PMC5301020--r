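## Per-taxon monophyly across locus-class trees and topological incongruence
## between partition trees (e.g. mitochondrial vs nuclear), quantified as
## Robinson-Foulds split distances with the shared and conflicting splits
## listed explicitly.

## canonical string for one side of a split, on the side excluding `ref`
split_key <- function(labels, ref) {
  paste(sort(labels), collapse = "|")
}

## nontrivial splits of a tree as canonical keys (unrooted sense)
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  ref <- sort(tree$tip.label)[1L]
  parts <- ape::prop.part(ape::unroot(tree))
  keys <- vapply(parts, function(idx) {
    side <- tree$tip.label[idx]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    split_key(side, ref)
  }, character(1L))
  unique(keys[!is.na(keys)])
}

## descendant-leaf sets of all internal nodes (rooted sense)
tree_clades <- function(tree) {
  parts <- ape::prop.part(tree)
  lapply(parts, function(idx) sort(tree$tip.label[idx]))
}

#' Test whether a set of leaves is monophyletic
#'
#' On a rooted tree the set must be exactly the descendant leaves of some
#' node; on an unrooted tree it must be one side of some split (so the root
#' placement cannot break it).
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf_set Nonempty character vector of leaf labels.
#' @param rooted Treat the tree as rooted? Defaults to [ape::is.rooted()].
#' @return Logical flag.
#' @export
is_monophyletic <- function(tree, leaf_set, rooted = ape::is.rooted(tree)) {
  leaf_set <- unique(leaf_set)
  if (!length(leaf_set)) stop_validation("leaf_set is empty")
  unknown <- setdiff(leaf_set, tree$tip.label)
  if (length(unknown)) stop_validation("unknown leaf label(s): %s",
                                       paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  if (length(leaf_set) == 1L || length(leaf_set) == n) return(TRUE)
  target <- sort(leaf_set)
  clades <- tree_clades(tree)
  hit <- any(vapply(clades, identical, logical(1L), y = target))
  if (rooted) return(hit)
  comp <- sort(setdiff(tree$tip.label, leaf_set))
  hit || any(vapply(clades, identical, logical(1L), y = comp)) ||
    length(comp) == 1L
}

#' Per-taxon monophyly report for one tree
#'
#' For every taxon with leaves in the tree, tests whether its sampled
#' individuals form an exclusive clade (rooted) or split (unrooted). Taxa
#' with a single sampled individual are trivially monophyletic and excluded
#' from the summary fraction by default, matching a two-individuals-per-taxon
#' sampling design where only multi-individual taxa are informative.
#'
#' @param tree An [ape::phylo] tree whose leaves are individual ids.
#' @param taxon_map A [taxon_map()].
#' @param group_filter Optional chromosomal group id(s); restricts the report
#'   to taxa of those groups.
#' @param rooted Use the rooted test? Defaults to the tree's rootedness.
#' @param include_trivial Count single-individual taxa in the fraction?
#' @param tree_id Identifier recorded in the report.
#' @return An object of class `monophyly_report`: list with `taxa` (per-taxon
#'   tibble), `fraction`, `n_informative`, `excluded_taxa` (taxa with no leaf
#'   in the tree) and `tree_id`.
#' @export
monophyly_fraction <- function(tree, taxon_map, group_filter = NULL,
                               rooted = ape::is.rooted(tree),
                               include_trivial = FALSE, tree_id = "tree") {
  tm <- taxon_map
  if (!is.null(group_filter)) tm <- tm[tm$group %in% group_filter, ]
  taxa <- unique(tm$taxon)
  present <- vapply(taxa, function(tx) {
    any(tm$individual[tm$taxon == tx] %in% tree$tip.label)
  }, logical(1L))
  excluded <- taxa[!present]
  taxa <- taxa[present]
  if (!length(taxa)) stop_validation("no taxa with leaves in the tree")
  rows <- purrr::map_dfr(taxa, function(tx) {
    leaves <- intersect(tm$individual[tm$taxon == tx], tree$tip.label)
    tibble(taxon = tx,
           group = tm$group[match(tx, tm$taxon)],
           n_individuals = length(leaves),
           monophyletic = is_monophyletic(tree, leaves, rooted = rooted),
           trivial = length(leaves) == 1L)
  })
  use <- if (include_trivial) rows else rows[!rows$trivial, ]
  if (!nrow(use)) stop_validation("no non-trivial taxa: monophyly fraction undefined")
  structure(list(taxa = rows, fraction = mean(use$monophyletic),
                 n_informative = nrow(use), excluded_taxa = excluded,
                 tree_id = tree_id),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("<monophyly_report> %s: %.3f (%d informative taxa)\n",
              x$tree_id, x$fraction, x$n_informative))
  print(x$taxa)
  invisible(x)
}

#' @rdname monophyly_fraction
#' @param x A `monophyly_report`.
#' @param ... Unused.
#' @export
tidy.monophyly_report <- function(x, ...) x$taxa

#' @rdname monophyly_fraction
#' @export
glance.monophyly_report <- function(x, ...) {
  tibble(tree_id = x$tree_id, fraction_monophyletic = x$fraction,
         n_informative = x$n_informative,
         n_taxa = nrow(x$taxa), n_trivial = sum(x$taxa$trivial),
         n_excluded = length(x$excluded_taxa))
}

#' Robinson-Foulds incongruence between two trees
#'
#' Unrooted Robinson-Foulds distance on nontrivial splits after pruning both
#' trees to their common leaf set. Also reports the shared split count and
#' the conflicting splits unique to each tree.
#'
#' @param tree_a,tree_b [ape::phylo] trees sharing at least four leaves.
#' @param id_a,id_b Identifiers recorded in the result.
#' @return An object of class `congruence_result`: list with `rf_distance`,
#'   `shared_splits`, `normalized_rf` (`rf / (2 (n - 3))`), `n_leaves`, and
#'   `conflicting_clades` (leaf sets unique to each tree).
#' @export
rf_distance <- function(tree_a, tree_b, id_a = "tree_a", id_b = "tree_b") {
  common <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(common) < 4L) {
    stop_validation("trees share only %d leaves (>= 4 required)", length(common))
  }
  ta <- ape::keep.tip(tree_a, common)
  tb <- ape::keep.tip(tree_b, common)
  sa <- tree_splits(ta)
  sb <- tree_splits(tb)
  only_a <- setdiff(sa, sb)
  only_b <- setdiff(sb, sa)
  n <- length(common)
  ## report each conflicting split by its minority side for readability
  minority <- function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1L]]
    if (length(side) > n / 2) sort(setdiff(common, side)) else side
  }
  structure(list(
    tree_pair = c(id_a, id_b),
    rf_distance = length(only_a) + length(only_b),
    shared_splits = length(intersect(sa, sb)),
    normalized_rf = (length(only_a) + length(only_b)) / (2 * (n - 3)),
    n_leaves = n,
    conflicting_clades = list(
      only_a = lapply(only_a, minority),
      only_b = lapply(only_b, minority))),
    class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf("<congruence_result> %s vs %s: RF %d (normalized %.3f), %d shared splits on %d leaves\n",
              x$tree_pair[1L], x$tree_pair[2L], x$rf_distance,
              x$normalized_rf, x$shared_splits, x$n_leaves))
  invisible(x)
}

#' @rdname rf_distance
#' @param x A `congruence_result`.
#' @param ... Unused.
#' @export
tidy.congruence_result <- function(x, ...) {
  tibble(tree_a = x$tree_pair[1L], tree_b = x$tree_pair[2L],
         rf_distance = x$rf_distance, shared_splits = x$shared_splits,
         normalized_rf = x$normalized_rf, n_leaves = x$n_leaves)
}

#' Concordance table across chromosome-class trees
#'
#' Combines, in one tidy table, the per-class monophyly fractions (overall
#' and within each chromosomal group) and the pairwise Robinson-Foulds
#' incongruence between class trees. Rows of kind `"monophyly"` carry
#' `class`, `group` and `fraction`; rows of kind `"congruence"` carry
#' `class`, `other_class`, `rf`, `shared_splits` and `normalized_rf`.
#'
#' @param trees Named list of [ape::phylo] trees, one per chromosome class,
#'   leaves labelled by individual id.
#' @param taxon_map A [taxon_map()].
#' @param rooted Use rooted monophyly tests (default: each tree's
#'   rootedness).
#' @param include_trivial Passed to [monophyly_fraction()].
#' @return A tibble.
#' @export
class_concordance_table <- function(trees, taxon_map, rooted = NULL,
                                    include_trivial = FALSE) {
  if (length(trees) < 2L) stop_validation("need >= 2 class trees")
  if (is.null(names(trees)) || any(names(trees) == "")) {
    stop_validation("trees must be named by chromosome class")
  }
  groups <- sort(unique(taxon_map$group))
  mono <- purrr::map_dfr(names(trees), function(cl) {
    tr <- trees[[cl]]
    r <- if (is.null(rooted)) ape::is.rooted(tr) else rooted
    one <- function(gf, gname) {
      rep <- tryCatch(
        monophyly_fraction(tr, taxon_map, group_filter = gf, rooted = r,
                           include_trivial = include_trivial, tree_id = cl),
        chromospec_validation_error = function(e) NULL)
      tibble(kind = "monophyly", class = cl, other_class = NA_character_,
             group = gname,
             fraction = if (is.null(rep)) NA_real_ else rep$fraction,
             n = if (is.null(rep)) 0L else rep$n_informative,
             rf = NA_integer_, shared_splits = NA_integer_,
             normalized_rf = NA_real_)
    }
    dplyr::bind_rows(one(NULL, "overall"),
                     purrr::map_dfr(groups, function(g) one(g, g)))
  })
  pairs <- combn(names(trees), 2L)
  cong <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    res <- rf_distance(trees[[a]], trees[[b]], id_a = a, id_b = b)
    tibble(kind = "congruence", class = a, other_class = b,
           group = NA_character_, fraction = NA_real_,
           n = res$n_leaves, rf = res$rf_distance,
           shared_splits = res$shared_splits,
           normalized_rf = res$normalized_rf)
  })
  dplyr::bind_rows(mono, cong)
}
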