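## Ancestral karyotype reconstruction by unordered-state parsimony on a fixed
## rooted species tree. The dynamic programme is Sankoff's; with the default
## uniform cost matrix it reduces to Fitch/Hartigan counting (polytomies are
## handled naturally because each child contributes independently). Origin
## ranges are taken over the complete set of most-parsimonious reconstructions
## (MPRs) rather than resolved by ACCTRAN/DELTRAN, so ambiguity is reported,
## not hidden.

## Index a rooted tree once so repeated per-character passes are cheap.
tree_index <- function(tree) {
  if (!ape::is.rooted(tree)) stop_validation("tree must be rooted")
  n_tip <- length(tree$tip.label)
  n_tot <- n_tip + tree$Nnode
  root <- n_tip + 1L
  children <- vector("list", n_tot)
  parent <- rep(NA_integer_, n_tot)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    children[[p]] <- c(children[[p]], c)
    parent[c] <- p
  }
  ## internal nodes in postorder (children before parents)
  post <- integer(0)
  stack <- root; visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, v)
    stack <- c(stack, children[[v]])
  }
  pre <- visit
  post <- rev(pre)
  inner_lab <- tree$node.label
  if (is.null(inner_lab) || !length(inner_lab) ||
      anyDuplicated(c(tree$tip.label, inner_lab)) || any(inner_lab == "")) {
    inner_lab <- paste0("node", seq_len(tree$Nnode) + n_tip)
  }
  labels <- c(tree$tip.label, inner_lab)
  list(tree = tree, n_tip = n_tip, n_tot = n_tot, root = root,
       children = children, parent = parent, preorder = pre,
       postorder = post, labels = labels)
}

## Core per-character reconstruction. `states` is a named vector over the
## tips (NA = missing, which contributes the full alphabet at zero cost).
recon_character <- function(idx, states, alphabet = NULL, cost = NULL,
                            root_state = NULL) {
  tips <- idx$tree$tip.label
  miss <- setdiff(tips, names(states))
  if (length(miss)) {
    stop_validation("leaves absent from character states: %s",
                    paste(miss, collapse = ", "))
  }
  obs <- states[tips]
  alphabet <- sort(unique(c(alphabet, obs[!is.na(obs)], root_state)))
  K <- length(alphabet)
  if (K == 0L) stop_validation("character is entirely missing")
  if (is.null(cost)) {
    cost <- matrix(1, K, K); diag(cost) <- 0
  } else {
    stopifnot(is.matrix(cost), nrow(cost) == K, ncol(cost) == K)
  }
  n_tot <- idx$n_tot
  C <- matrix(Inf, K, n_tot)
  ## leaf costs
  for (i in seq_len(idx$n_tip)) {
    if (is.na(obs[i])) C[, i] <- 0 else C[match(obs[i], alphabet), i] <- 0
  }
  ## B[[v]][s_parent, s_child]: TRUE if s_child is an optimal choice for node v
  ## given its parent (or root choice) has state s_parent.
  B <- vector("list", n_tot)
  for (v in idx$postorder) {
    kids <- idx$children[[v]]
    if (length(kids)) {
      acc <- numeric(K)
      for (c in kids) {
        tmp <- cost + matrix(C[, c], K, K, byrow = TRUE)
        m <- apply(tmp, 1L, min)
        B[[c]] <- tmp == m  # K x K logical
        acc <- acc + m
      }
      C[, v] <- acc
    }
  }
  min_changes <- min(C[, idx$root])
  root_set <- which(C[, idx$root] == min_changes)
  if (!is.null(root_state)) {
    ri <- match(root_state, alphabet)
    if (!(ri %in% root_set)) {
      stop_validation("root state '%s' is incompatible with every most-parsimonious reconstruction",
                      root_state)
    }
    root_set <- ri
  }
  ## MPR-consistent state sets per node (Hartigan-style up pass).
  sets <- vector("list", n_tot)
  sets[[idx$root]] <- root_set
  for (v in idx$preorder) {
    if (v == idx$root) next
    ps <- sets[[idx$parent[v]]]
    if (length(ps) == 1L) {
      sets[[v]] <- which(B[[v]][ps, ])
    } else {
      sets[[v]] <- which(apply(B[[v]][ps, , drop = FALSE], 2L, any))
    }
  }
  ## number of MPRs (double; compared against caller limits)
  N <- matrix(1, K, n_tot)
  for (v in idx$postorder) {
    kids <- idx$children[[v]]
    for (c in kids) {
      sums <- as.vector(B[[c]] %*% N[, c])
      N[, v] <- N[, v] * sums
    }
  }
  n_mpr <- sum(N[root_set, idx$root])
  list(alphabet = alphabet, cost = cost, C = C, B = B,
       min_changes = min_changes, root_set = root_set, state_sets = sets,
       n_mpr = n_mpr, obs = obs)
}

## Min/max number of origins of `state` over all MPRs (root-restricted by
## rec$root_set). An origin is an edge whose parent lacks the state and whose
## child has it.
origin_range_dp <- function(idx, rec, state) {
  t_i <- match(state, rec$alphabet)
  if (is.na(t_i)) stop_validation("state '%s' not in character alphabet", state)
  K <- length(rec$alphabet)
  Omin <- matrix(0, K, idx$n_tot)
  Omax <- matrix(0, K, idx$n_tot)
  gain <- outer(seq_len(K) != t_i, seq_len(K) == t_i) * 1  # [s_parent, s_child]
  for (v in idx$postorder) {
    kids <- idx$children[[v]]
    for (c in kids) {
      lo <- gain + matrix(Omin[, c], K, K, byrow = TRUE)
      hi <- gain + matrix(Omax[, c], K, K, byrow = TRUE)
      lo[!rec$B[[c]]] <- Inf
      hi[!rec$B[[c]]] <- -Inf
      Omin[, v] <- Omin[, v] + apply(lo, 1L, min)
      Omax[, v] <- Omax[, v] + apply(hi, 1L, max)
    }
  }
  c(min_origins = min(Omin[rec$root_set, idx$root]),
    max_origins = max(Omax[rec$root_set, idx$root]))
}

as_character_states <- function(character) {
  if (is.null(names(character))) {
    stop_validation("character states must be named by taxon")
  }
  x <- as.character(character)
  names(x) <- names(character)
  x[x %in% c("?", "")] <- NA_character_
  x
}

#' Parsimony score and ancestral state sets for one character
#'
#' Unordered, equally weighted parsimony (Fitch/Hartigan; Sankoff when a cost
#' matrix is supplied) on a rooted tree, polytomies allowed. Missing states
#' (`NA` or `"?"`) contribute the full alphabet at zero cost. The returned
#' state sets contain, for each node, every state that appears at that node
#' in at least one most-parsimonious reconstruction; leaves with missing data
#' are reported as the full alphabet.
#'
#' @param tree A rooted [ape::phylo] tree whose tips cover the character.
#' @param character Named character vector of tip states (names = taxa;
#'   `NA`/`"?"` = missing).
#' @param cost Optional square step-cost matrix over the character's sorted
#'   alphabet; default is uniform (all changes cost 1).
#' @param root_state Optional state the root is required to take; it must be
#'   attainable by some most-parsimonious reconstruction.
#' @return A list with `min_changes`, `node_state_sets` (named list of state
#'   vectors, tips then internal nodes), `alphabet` and `n_mpr` (number of
#'   most-parsimonious reconstructions).
#' @export
parsimony_score <- function(tree, character, cost = NULL, root_state = NULL) {
  idx <- tree_index(tree)
  states <- as_character_states(character)
  rec <- recon_character(idx, states, cost = cost, root_state = root_state)
  sets <- lapply(seq_len(idx$n_tot), function(v) {
    if (v <= idx$n_tip && is.na(rec$obs[v])) rec$alphabet
    else rec$alphabet[rec$state_sets[[v]]]
  })
  names(sets) <- idx$labels
  list(min_changes = rec$min_changes, node_state_sets = sets,
       alphabet = rec$alphabet, n_mpr = rec$n_mpr)
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Returns every complete ancestral assignment attaining the minimum change
#' count. Leaves with observed states are fixed; missing leaves are assigned
#' like internal nodes. Intended for small problems; the count is checked
#' against `limit` before any enumeration.
#'
#' @inheritParams parsimony_score
#' @param limit Maximum number of reconstructions to enumerate.
#' @return A list of named character vectors (one state per node, tips then
#'   internal nodes).
#' @export
enumerate_mprs <- function(tree, character, limit = 1e6, cost = NULL,
                           root_state = NULL) {
  idx <- tree_index(tree)
  states <- as_character_states(character)
  rec <- recon_character(idx, states, cost = cost, root_state = root_state)
  if (rec$n_mpr > limit) {
    stop_capacity("%.0f most-parsimonious reconstructions exceed limit %g; use count_origins() ranges instead",
                  rec$n_mpr, limit)
  }
  ## grow the assignment matrix in preorder; each node's options depend only
  ## on its parent's assigned state
  A <- matrix(rec$root_set, ncol = 1L)
  cols <- idx$root
  for (v in idx$preorder) {
    if (v == idx$root) next
    p_col <- match(idx$parent[v], cols)
    opts <- lapply(A[, p_col], function(ps) which(rec$B[[v]][ps, ]))
    reps <- lengths(opts)
    A <- A[rep(seq_len(nrow(A)), times = reps), , drop = FALSE]
    A <- cbind(A, unlist(opts))
    cols <- c(cols, v)
  }
  ord <- order(cols)
  A <- A[, ord, drop = FALSE]
  lapply(seq_len(nrow(A)), function(i) {
    setNames(rec$alphabet[A[i, ]], idx$labels)
  })
}

## changes implied by a complete assignment (used for self-consistency tests)
assignment_changes <- function(tree, assignment, cost = NULL) {
  idx <- tree_index(tree)
  a <- assignment[idx$labels]
  states <- sort(unique(a))
  if (is.null(cost)) {
    sum(a[idx$tree$edge[, 1L]] != a[idx$tree$edge[, 2L]])
  } else {
    sum(cost[cbind(match(a[idx$tree$edge[, 1L]], states),
                   match(a[idx$tree$edge[, 2L]], states))])
  }
}

#' Range of independent origins of a state over all MPRs
#'
#' An origin is a branch whose parent node lacks the state and whose child
#' node has it. The minimum and maximum are taken over every
#' most-parsimonious reconstruction (optionally restricted to those with a
#' given root state). A range with `min_origins >= 2` indicates homoplasy —
#' the state must have arisen independently more than once.
#'
#' @inheritParams parsimony_score
#' @param state State whose origins are counted.
#' @return Named numeric vector `c(min_origins, max_origins)`.
#' @export
count_origins <- function(tree, character, state, root_state = NULL,
                          cost = NULL) {
  idx <- tree_index(tree)
  states <- as_character_states(character)
  rec <- recon_character(idx, states, cost = cost, root_state = root_state)
  origin_range_dp(idx, rec, state)
}

## canonical single MPR by backtracking; tie_break "late" keeps the parent
## state where possible (DELTRAN-like), "early" prefers a change (ACCTRAN-like)
canonical_mpr <- function(idx, rec, tie_break = c("late", "early")) {
  tie_break <- match.arg(tie_break)
  assign <- integer(idx$n_tot)
  assign[idx$root] <- rec$root_set[1L]
  for (v in idx$preorder) {
    if (v == idx$root) next
    ps <- assign[idx$parent[v]]
    opts <- which(rec$B[[v]][ps, ])
    if (ps %in% opts && tie_break == "late") {
      assign[v] <- ps
    } else if (tie_break == "early" && length(setdiff(opts, ps))) {
      assign[v] <- setdiff(opts, ps)[1L]
    } else {
      assign[v] <- opts[1L]
    }
  }
  assign
}

#' Map rearrangement events onto a species tree
#'
#' Runs the parsimony reconstruction for every character of a karyotype
#' matrix, flags homoplasy (some derived state with at least two independent
#' origins in every MPR), reports unresolved nodes (more than one
#' MPR-consistent state), and builds a branch-level event table.
#'
#' By default events are compiled over the complete MPR set (capped at
#' `enumerate_limit`; beyond the cap a single canonical reconstruction is
#' used and all its rows are marked ambiguous). `resolve = "acctran"` /
#' `"deltran"` instead place ambiguous changes early/late along a single
#' reconstruction. An edge whose child regains the reconstruction's root
#' state is classified a reversal.
#'
#' @param tree Rooted [ape::phylo] species tree (tips may exceed the matrix;
#'   extra tips are pruned).
#' @param matrix A [karyotype_matrix()].
#' @param root_constraints Optional named character vector
#'   `c(character = state)` fixing the root state of selected characters.
#' @param resolve `"all"` (default; union over MPRs with ambiguity flags),
#'   `"acctran"` or `"deltran"`.
#' @param enumerate_limit Cap on MPRs enumerated per character.
#' @return An object of class `karyotype_events` with elements `summary`
#'   (per-character tibble), `events` (event tibble), `results` (per-character
#'   reconstruction details) and `tree`.
#' @export
map_events <- function(tree, matrix, root_constraints = NULL,
                       resolve = c("all", "acctran", "deltran"),
                       enumerate_limit = 1e5) {
  resolve <- match.arg(resolve)
  stopifnot(inherits(matrix, "karyotype_matrix"))
  taxa <- matrix$taxon
  missing_tips <- setdiff(taxa, tree$tip.label)
  if (length(missing_tips)) {
    stop_validation("matrix taxa absent from tree: %s",
                    paste(missing_tips, collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  idx <- tree_index(tree)
  chars <- setdiff(names(matrix), "taxon")
  results <- list()
  ev_rows <- list()
  sum_rows <- list()
  for (ch in chars) {
    states <- setNames(matrix[[ch]], taxa)
    rs <- if (!is.null(root_constraints) && ch %in% names(root_constraints))
      root_constraints[[ch]] else NULL
    rec <- recon_character(idx, as_character_states(states), root_state = rs)
    ranges <- t(vapply(rec$alphabet, function(s) origin_range_dp(idx, rec, s),
                       numeric(2L)))
    origin_range <- tibble(character = ch, state = rec$alphabet,
                           min_origins = ranges[, 1L],
                           max_origins = ranges[, 2L],
                           unambiguous = ranges[, 1L] == ranges[, 2L])
    unresolved <- idx$labels[-seq_len(idx$n_tip)][
      vapply(rec$state_sets[-seq_len(idx$n_tip)], length, 1L) > 1L]
    homoplasious <- any(ranges[, 1L] >= 2)
    ## event rows from one or all MPRs
    mprs <- if (resolve == "all" && rec$n_mpr <= enumerate_limit) {
      A <- enumerate_mprs(tree, states, limit = enumerate_limit,
                          root_state = rs)
      lapply(A, function(a) match(a[idx$labels], rec$alphabet))
    } else if (resolve == "acctran") {
      list(canonical_mpr(idx, rec, "early"))
    } else {
      list(canonical_mpr(idx, rec, "late"))
    }
    n_m <- length(mprs)
    edge <- idx$tree$edge
    key_count <- new.env(parent = emptyenv())
    for (a in mprs) {
      root_s <- a[idx$root]
      chg <- which(a[edge[, 1L]] != a[edge[, 2L]])
      for (e in chg) {
        to <- a[edge[e, 2L]]
        kind <- if (to == root_s) "reversal" else "origin"
        key <- paste(rec$alphabet[to], idx$labels[edge[e, 2L]], kind, sep = "\r")
        key_count[[key]] <- (key_count[[key]] %||% 0L) + 1L
      }
    }
    keys <- ls(key_count)
    if (length(keys)) {
      parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
      cnt <- vapply(keys, function(k) key_count[[k]], numeric(1L))
      ev_rows[[ch]] <- tibble(character = ch, state = parts[, 1L],
                              branch = parts[, 2L], event_kind = parts[, 3L],
                              ambiguous = if (resolve == "all" && rec$n_mpr <= enumerate_limit)
                                cnt < n_m
                              else !origin_range$unambiguous[
                                match(parts[, 1L], origin_range$state)])
    }
    results[[ch]] <- list(
      character_id = ch, min_changes = rec$min_changes,
      node_state_sets = setNames(lapply(seq_len(idx$n_tot), function(v) {
        if (v <= idx$n_tip && is.na(rec$obs[v])) rec$alphabet
        else rec$alphabet[rec$state_sets[[v]]]
      }), idx$labels),
      origin_range = origin_range, n_mpr = rec$n_mpr,
      unresolved_nodes = unresolved, homoplasious = homoplasious)
    sum_rows[[ch]] <- tibble(character = ch, min_changes = rec$min_changes,
                             n_states = length(rec$alphabet),
                             n_mpr = rec$n_mpr,
                             homoplasious = homoplasious,
                             n_unresolved_nodes = length(unresolved))
  }
  events <- if (length(ev_rows)) {
    dplyr::arrange(dplyr::bind_rows(ev_rows), .data$character, .data$state,
                   .data$branch, .data$event_kind)
  } else {
    tibble(character = character(), state = character(), branch = character(),
           event_kind = character(), ambiguous = logical())
  }
  structure(list(summary = dplyr::bind_rows(sum_rows), events = events,
                 results = results, tree = tree),
            class = "karyotype_events")
}

#' @export
print.karyotype_events <- function(x, ...) {
  cat(sprintf("<karyotype_events> %d characters on %d taxa; %d homoplasious, %d event rows\n",
              nrow(x$summary), length(x$tree$tip.label),
              sum(x$summary$homoplasious), nrow(x$events)))
  print(x$summary)
  invisible(x)
}

#' @rdname map_events
#' @param x A `karyotype_events` object.
#' @param ... Unused.
#' @export
tidy.karyotype_events <- function(x, ...) x$events

#' @rdname map_events
#' @export
glance.karyotype_events <- function(x, ...) {
  tibble(n_characters = nrow(x$summary),
         total_min_changes = sum(x$summary$min_changes),
         n_homoplasious = sum(x$summary$homoplasious),
         n_ambiguous_events = sum(x$events$ambiguous),
         n_unresolved_nodes = sum(x$summary$n_unresolved_nodes))
}
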