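# Independent brute-force parsimony oracle: enumerates every complete
# ancestral assignment (internal nodes plus missing leaves; observed leaves
# fixed), scores each by counting changed edges, and derives the minimum
# score and per-state origin ranges over the optimal assignments. Shares no
# code with the package's dynamic programme.

oracle_reconstruction <- function(tree, states, root_state = NULL) {
  tips <- tree$tip.label
  obs <- states[tips]
  alph <- sort(unique(obs[!is.na(obs) & obs != "?"]))
  alph <- sort(unique(c(alph, root_state)))
  n_tip <- length(tips)
  n_tot <- n_tip + tree$Nnode
  fixed <- match(obs, alph)
  fixed[obs %in% c(NA, "?")] <- NA
  fixed <- c(fixed, rep(NA_integer_, tree$Nnode))
  free <- which(is.na(fixed))
  K <- length(alph)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(free))))
  A <- matrix(rep(fixed, each = nrow(grid)), nrow(grid), n_tot)
  A[, free] <- grid
  e1 <- tree$edge[, 1L]; e2 <- tree$edge[, 2L]
  scores <- rowSums(A[, e1, drop = FALSE] != A[, e2, drop = FALSE])
  min_changes <- min(scores)
  root <- n_tip + 1L
  opt <- scores == min_changes
  if (!is.null(root_state)) {
    ri <- match(root_state, alph)
    keep <- opt & A[, root] == ri
    if (!any(keep)) return(list(min_changes = min_changes, feasible = FALSE))
    opt <- keep
  }
  origins <- function(state) {
    ti <- match(state, alph)
    n_or <- rowSums((A[opt, e1, drop = FALSE] != ti) &
                      (A[opt, e2, drop = FALSE] == ti))
    c(min_origins = min(n_or), max_origins = max(n_or))
  }
  list(min_changes = min_changes, feasible = TRUE, origins = origins,
       alphabet = alph, n_opt = sum(opt))
}

# random test case: tree with n leaves, character over k states with
# optional missing data
random_parsimony_case <- function(n_leaves, k_states, p_missing = 0.1) {
  tr <- ape::rtree(n_leaves, br = NULL)
  st <- setNames(sample(letters[seq_len(k_states)], n_leaves, replace = TRUE),
                 tr$tip.label)
  miss <- runif(n_leaves) < p_missing
  if (all(miss)) miss[1L] <- FALSE
  st[miss] <- NA
  list(tree = tr, states = st)
}
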