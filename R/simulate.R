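## Generator for datasets with the statistical structure the analysis
## assumes: a species tree with chromosomal groups, multispecies-coalescent
## gene trees with class-specific effective sizes (X at 3/4 of the
## autosomes) and discrete introgression pulses, JC69 sequence evolution,
## and karyotype characters evolving with rearrangement hotspots. Every
## simulated object comes with a truth log so downstream inferences can be
## checked against the generating events. Time is measured in coalescent
## units of 2N generations; rates are per coalescent unit.

SIM_CLASSES <- c("X", "rearranged", "non_rearranged")

## caterpillar newick for labels joined at increasing heights
caterpillar_newick <- function(labels, times) {
  nwk <- labels[1L]; h <- 0
  for (i in seq_along(times)) {
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, times[i] - h, labels[i + 1L], times[i])
    h <- times[i]
  }
  list(nwk = nwk, h = h)
}

#' Example species tree with four chromosomal groups
#'
#' A 20-taxon ultrametric species tree (branch lengths in coalescent units)
#' shaped like a recent marsupial radiation: four groups of five taxa,
#' within-group splits at 0.5-2 coalescent units and group divergences at
#' 3-5, deep enough for substantial but incomplete lineage sorting.
#'
#' @param n_groups,taxa_per_group Tree dimensions.
#' @return A list with `tree` ([ape::phylo]) and `groups` (named character
#'   vector taxon -> group id).
#' @export
example_species_tree <- function(n_groups = 4, taxa_per_group = 5) {
  grp_ids <- sprintf("g%d", seq_len(n_groups))
  clades <- lapply(grp_ids, function(g) {
    taxa <- sprintf("%s_t%d", g, seq_len(taxa_per_group))
    caterpillar_newick(taxa, times = 0.5 * seq_len(taxa_per_group - 1L))
  })
  join_times <- 3 + seq_len(n_groups - 1L)
  nwk <- clades[[1L]]$nwk; h <- clades[[1L]]$h
  for (i in seq_len(n_groups - 1L)) {
    t <- join_times[i]
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, t - h, clades[[i + 1L]]$nwk,
                   t - clades[[i + 1L]]$h)
    h <- t
  }
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  groups <- setNames(sub("_t.*", "", tree$tip.label), tree$tip.label)
  list(tree = tree, groups = groups)
}

#' Describe one introgression pulse
#'
#' A pulse (replacement) event: at `time`, with a class-specific probability,
#' every sampled lineage of the recipient taxon is rerouted into the donor
#' population, modelling a discrete episode of introgression.
#'
#' @param donor,recipient Taxon ids (tips of the species tree).
#' @param time Event time in coalescent units; must predate neither taxon's
#'   divergence (younger than both tips' parent nodes).
#' @param p Named probabilities per chromosome class, e.g.
#'   `c(X = 0, rearranged = 0, non_rearranged = 0.8)`; omitted classes get 0.
#' @return A one-row tibble.
#' @export
introgression_event <- function(donor, recipient, time, p = c()) {
  prob <- setNames(rep(0, length(SIM_CLASSES)), SIM_CLASSES)
  if (length(p)) {
    bad <- setdiff(names(p), SIM_CLASSES)
    if (length(bad)) stop_validation("unknown class(es) in p: %s",
                                     paste(bad, collapse = ", "))
    prob[names(p)] <- p
  }
  if (any(prob < 0 | prob > 1)) stop_validation("introgression probabilities must be in [0,1]")
  tibble(donor = donor, recipient = recipient, time = time,
         p_X = prob[["X"]], p_rearranged = prob[["rearranged"]],
         p_non_rearranged = prob[["non_rearranged"]])
}

#' Simulation parameters
#'
#' Bundles and validates everything the generator needs. Defaults emulate
#' the case-study sampling design: 20 taxa in four chromosomal groups, two
#' individuals per taxon, and an exon set partitioned as 21 X loci (426 bp),
#' 160 rearranged-autosome loci (226 bp) and 140 non-rearranged loci
#' (538 bp), with the X at three quarters of the autosomal effective size.
#'
#' @param species_tree Ultrametric [ape::phylo] with branch lengths in
#'   coalescent units (2N generations); default [example_species_tree()].
#' @param groups Named character vector taxon -> group id.
#' @param n_individuals Sampled individuals per taxon.
#' @param loci_per_class Named integer vector of locus counts per class.
#' @param locus_length Sites per locus; scalar or named per class.
#' @param mu Substitution rate per site per coalescent unit.
#' @param ne_scale Named per-class effective-size factors (X defaults to
#'   0.75).
#' @param introgression Tibble of [introgression_event()] rows (or `NULL`).
#' @param seed Master seed; every per-locus stream is derived from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(species_tree = NULL, groups = NULL,
                       n_individuals = 2,
                       loci_per_class = c(X = 21, rearranged = 160,
                                          non_rearranged = 140),
                       locus_length = c(X = 426, rearranged = 226,
                                        non_rearranged = 538),
                       mu = 0.002,
                       ne_scale = c(X = 0.75, rearranged = 1,
                                    non_rearranged = 1),
                       introgression = NULL, seed = 1) {
  if (is.null(species_tree)) {
    ex <- example_species_tree()
    species_tree <- ex$tree
    if (is.null(groups)) groups <- ex$groups
  }
  if (is.null(groups)) {
    groups <- setNames(rep("g1", length(species_tree$tip.label)),
                       species_tree$tip.label)
  }
  if (!ape::is.rooted(species_tree)) stop_validation("species tree must be rooted")
  if (is.null(species_tree$edge.length)) stop_validation("species tree needs branch lengths")
  depths <- ape::node.depth.edgelength(species_tree)
  tip_d <- depths[seq_along(species_tree$tip.label)]
  if (diff(range(tip_d)) > 1e-8 * max(tip_d, 1)) {
    stop_validation("species tree must be ultrametric")
  }
  stopifnot(all(names(loci_per_class) %in% SIM_CLASSES),
            all(loci_per_class >= 0))
  if (length(locus_length) == 1L && is.null(names(locus_length))) {
    locus_length <- setNames(rep(locus_length, length(loci_per_class)),
                             names(loci_per_class))
  }
  if (mu <= 0) stop_validation("mu must be > 0")
  if (any(ne_scale <= 0)) stop_validation("ne_scale factors must be > 0")
  miss_ne <- setdiff(names(loci_per_class), names(ne_scale))
  if (length(miss_ne)) stop_validation("ne_scale missing class(es): %s",
                                       paste(miss_ne, collapse = ", "))
  st <- species_tree_index(species_tree)
  if (!is.null(introgression) && nrow(introgression)) {
    for (i in seq_len(nrow(introgression))) {
      ev <- introgression[i, ]
      for (who in c(ev$donor, ev$recipient)) {
        ti <- match(who, species_tree$tip.label)
        if (is.na(ti)) stop_validation("introgression taxon '%s' not in tree", who)
        if (ev$time < 0 || ev$time >= st$time[st$parent[ti]]) {
          stop_validation("introgression at time %g invalid: taxon '%s' merges into its ancestor at %g",
                          ev$time, who, st$time[st$parent[ti]])
        }
      }
    }
  }
  structure(list(species_tree = species_tree, groups = groups,
                 n_individuals = as.integer(n_individuals),
                 loci_per_class = loci_per_class,
                 locus_length = locus_length, mu = mu, ne_scale = ne_scale,
                 introgression = introgression, seed = as.integer(seed)),
            class = "sim_params")
}

#' Two-group introgression scenario
#'
#' A compact validation scenario: eight taxa in two groups of four
#' (within-group splits at 1-3 coalescent units, groups diverging at 6),
#' two individuals per taxon, and one recent introgression pulse between
#' the non-sister pair `a1`/`a4` whose strength differs by chromosome
#' class. With gene flow confined to the non-rearranged class, net
#' divergence for the admixed pair collapses on non-rearranged loci but is
#' retained on rearranged (and X) loci -- the signature the divergence and
#' concordance modules are designed to detect.
#'
#' @param seed Master seed.
#' @param p Named per-class pulse probabilities (default: non-rearranged
#'   0.8, others 0).
#' @param loci_per_class,locus_length,mu,n_individuals,ne_scale Passed to
#'   [sim_params()].
#' @param time Pulse time in coalescent units.
#' @return A [sim_params()] object; the admixed pair is `a1`/`a4`.
#' @export
introgression_scenario <- function(seed,
                                   p = c(non_rearranged = 0.8),
                                   loci_per_class = c(X = 200,
                                                      rearranged = 200,
                                                      non_rearranged = 200),
                                   locus_length = 500, mu = 0.002,
                                   n_individuals = 2,
                                   ne_scale = c(X = 0.75, rearranged = 1,
                                                non_rearranged = 1),
                                   time = 0.1) {
  st <- ape::read.tree(text = paste0(
    "((((a1:1,a2:1):1,a3:2):1,a4:3):3,",
    "(((b1:1,b2:1):1,b3:2):1,b4:3):3);"))
  groups <- setNames(rep(c("gA", "gB"), each = 4L), st$tip.label)
  intro <- if (any(p > 0)) introgression_event("a4", "a1", time, p) else NULL
  sim_params(st, groups, n_individuals = n_individuals,
             loci_per_class = loci_per_class, locus_length = locus_length,
             mu = mu, ne_scale = ne_scale, introgression = intro,
             seed = seed)
}

## times/parents/children of the species tree, tips at time 0
species_tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  time <- max(depths[seq_len(n_tip)]) - depths
  time[seq_len(n_tip)] <- 0
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  children <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]],
                                      tree$edge[i, 2L])
  }
  list(time = time, parent = parent, children = children,
       root = n_tip + 1L, n_tip = n_tip)
}

## deterministic per-locus seed below 2^31
locus_seed <- function(seed, class, locus_index, salt = 0) {
  ci <- match(class, SIM_CLASSES)
  (as.double(seed) * 97 + ci * 15485863 + as.double(locus_index) * 104729 +
     salt * 49979687) %% 2147483629 + 1
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Lineages coalesce within species-tree populations at rate
#' `choose(k, 2) / ne` per coalescent unit, where `ne` is the class-specific
#' effective-size factor (all populations share it). At each introgression
#' pulse the whole sampled lineage set of the recipient is rerouted into the
#' donor population with the class's pulse probability. The RNG stream is
#' derived from `(seed, class, locus_index)`, so any locus is reproducible
#' in isolation.
#'
#' @param params A [sim_params()].
#' @param class Chromosome class of the locus.
#' @param locus_index Locus index within the class.
#' @return A list with `tree` (ultrametric [ape::phylo], tips
#'   `taxon_i`), and `truth` (one-row tibble: class, locus index,
#'   introgressed flag, donor).
#' @export
simulate_gene_tree <- function(params, class, locus_index) {
  stopifnot(inherits(params, "sim_params"))
  class <- match.arg(class, SIM_CLASSES)
  withr::with_seed(locus_seed(params$seed, class, locus_index), {
    simulate_gene_tree_impl(params, class, locus_index)
  })
}

simulate_gene_tree_impl <- function(params, class, locus_index) {
  st <- species_tree_index(params$species_tree)
  tips <- params$species_tree$tip.label
  ne <- params$ne_scale[[class]]
  n_ind <- params$n_individuals
  ## lineage state
  pop <- rep(seq_along(tips), each = n_ind)
  nwk <- as.vector(vapply(tips, function(tx) paste0(tx, "_", seq_len(n_ind)),
                          character(n_ind)))
  h <- rep(0, length(pop))
  ## event schedule: species-tree nodes and introgression pulses
  ev <- tibble(time = st$time[(st$n_tip + 1L):length(st$time)],
               type = "join",
               node = (st$n_tip + 1L):length(st$time), row = NA_integer_)
  intro <- params$introgression
  if (!is.null(intro) && nrow(intro)) {
    ev <- dplyr::bind_rows(ev, tibble(time = intro$time, type = "pulse",
                                      node = NA_integer_,
                                      row = seq_len(nrow(intro))))
  }
  ev <- ev[order(ev$time, ev$type != "pulse"), ]
  fired <- character(0)
  t_now <- 0
  coalesce_upto <- function(t_end) {
    repeat {
      tab <- table(pop)
      k <- as.integer(tab)
      rates <- k * (k - 1) / 2 / ne
      R <- sum(rates)
      if (R == 0) { t_now <<- t_end; return(invisible()) }
      dt <- rexp(1L, R)
      if (t_now + dt > t_end) { t_now <<- t_end; return(invisible()) }
      t_now <<- t_now + dt
      p_id <- as.integer(names(tab))[sample.int(length(rates), 1L,
                                                prob = rates)]
      in_pop <- which(pop == p_id)
      pair <- in_pop[sample.int(length(in_pop), 2L)]
      a <- pair[1L]; b <- pair[2L]
      nwk[a] <<- sprintf("(%s:%.10g,%s:%.10g)", nwk[a], t_now - h[a],
                         nwk[b], t_now - h[b])
      h[a] <<- t_now
      pop <<- pop[-b]; nwk <<- nwk[-b]; h <<- h[-b]
    }
  }
  for (i in seq_len(nrow(ev))) {
    coalesce_upto(ev$time[i])
    if (ev$type[i] == "join") {
      kids <- st$children[[ev$node[i]]]
      pop[pop %in% kids] <- ev$node[i]
    } else {
      e <- intro[ev$row[i], ]
      p <- e[[paste0("p_", class)]]
      if (runif(1L) < p) {
        rec <- match(e$recipient, tips)
        don <- match(e$donor, tips)
        if (any(pop == rec)) {
          pop[pop == rec] <- don
          fired <- c(fired, e$donor)
        }
      }
    }
  }
  coalesce_upto(Inf)
  tree <- ape::read.tree(text = paste0(nwk[1L], ";"))
  list(tree = tree,
       truth = tibble(class = class, locus_index = locus_index,
                      introgressed = length(fired) > 0,
                      donor = if (length(fired)) paste(unique(fired), collapse = ";")
                              else NA_character_))
}

#' Simulate a sequence alignment along a gene tree
#'
#' Jukes-Cantor substitution process (via [phangorn::simSeq()]) at rate `mu`
#' per site per coalescent unit along the gene-tree branches; no indels.
#'
#' @param gene_tree [ape::phylo] genealogy in coalescent units.
#' @param locus_length Number of sites.
#' @param mu Substitution rate per site per coalescent unit.
#' @param locus_id Locus id for the returned alignment.
#' @param class Chromosome class label.
#' @param seed Optional seed for a self-contained reproducible draw.
#' @return A [locus_alignment()].
#' @export
simulate_alignment <- function(gene_tree, locus_length, mu,
                               locus_id = "locus", class = "unassigned",
                               seed = NULL) {
  stopifnot(locus_length >= 1, mu >= 0)
  sim <- function() {
    dat <- phangorn::simSeq(gene_tree, l = locus_length, rate = mu)
    m <- toupper(as.character(dat))
    locus_alignment(m, locus_id = locus_id, class = class)
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate karyotype characters with rearrangement hotspots
#'
#' Each character starts from the first alphabet state at the root and
#' changes along branches by a Poisson process (`base_rate` events per
#' coalescent unit, times `hotspot_multiplier` for the hotspot fraction of
#' characters); each event draws a new state uniformly from the other
#' states. Returns the tip matrix together with a complete, replayable
#' event log.
#'
#' @param species_tree Rooted [ape::phylo] with branch lengths.
#' @param n_characters Number of characters.
#' @param base_rate Events per coalescent unit on non-hotspot characters.
#' @param hotspot_fraction Fraction of characters that are hotspots.
#' @param hotspot_multiplier Rate multiplier for hotspot characters.
#' @param state_alphabet Character states (first element = root state).
#' @param seed RNG seed.
#' @return A list with `matrix` (a [karyotype_matrix()]) and `truth`
#'   (list of `characters` and `events` tibbles).
#' @export
simulate_karyotypes <- function(species_tree, n_characters = 10,
                                base_rate = 0.005, hotspot_fraction = 0.2,
                                hotspot_multiplier = 10,
                                state_alphabet = c("a", "m", "sm", "i"),
                                seed = 1) {
  if (!length(state_alphabet)) stop_validation("state alphabet is empty")
  stopifnot(base_rate >= 0, hotspot_multiplier >= 0,
            hotspot_fraction >= 0, hotspot_fraction <= 1)
  idx <- tree_index(species_tree)
  edges <- species_tree$edge
  elen <- species_tree$edge.length
  withr::with_seed(seed, {
    char_ids <- sprintf("char%03d", seq_len(n_characters))
    hot <- runif(n_characters) < hotspot_fraction
    ev_rows <- list()
    cells <- matrix(state_alphabet[1L], length(species_tree$tip.label),
                    n_characters,
                    dimnames = list(species_tree$tip.label, char_ids))
    for (ci in seq_len(n_characters)) {
      rate <- base_rate * if (hot[ci]) hotspot_multiplier else 1
      state <- rep(state_alphabet[1L], idx$n_tot)
      rows <- list()
      for (v in idx$preorder) {
        if (v == idx$root) next
        e <- which(edges[, 2L] == v)
        s <- state[idx$parent[v]]
        k <- rpois(1L, rate * elen[e])
        if (k > 0 && length(state_alphabet) > 1L) {
          for (j in seq_len(k)) {
            new_s <- sample(setdiff(state_alphabet, s), 1L)
            rows[[length(rows) + 1L]] <- tibble(
              character = char_ids[ci], branch = idx$labels[v],
              event = j, from = s, to = new_s)
            s <- new_s
          }
        }
        state[v] <- s
      }
      cells[, ci] <- state[seq_len(idx$n_tip)]
      ev_rows[[ci]] <- if (length(rows)) dplyr::bind_rows(rows) else NULL
    }
    events <- if (length(purrr::compact(ev_rows)))
      dplyr::bind_rows(purrr::compact(ev_rows))
    else tibble(character = character(), branch = character(),
                event = integer(), from = character(), to = character())
    truth_chars <- tibble(character = char_ids, hotspot = hot,
                          root_state = state_alphabet[1L],
                          n_events = vapply(char_ids, function(id)
                            sum(events$character == id), numeric(1L)))
    km <- karyotype_matrix(tibble::as_tibble(cells) |>
                             dplyr::mutate(taxon = rownames(cells),
                                           .before = 1L))
    list(matrix = km, truth = list(characters = truth_chars, events = events))
  })
}

#' Replay a karyotype truth log
#'
#' Re-applies the logged events along the tree from each character's root
#' state; the resulting tip states must reproduce the simulated matrix
#' exactly.
#'
#' @param species_tree The tree the log was simulated on.
#' @param truth Truth log from [simulate_karyotypes()].
#' @return A [karyotype_matrix()].
#' @export
replay_karyotype_events <- function(species_tree, truth) {
  idx <- tree_index(species_tree)
  chars <- truth$characters
  cells <- matrix(NA_character_, idx$n_tip, nrow(chars),
                  dimnames = list(species_tree$tip.label, chars$character))
  for (ci in seq_len(nrow(chars))) {
    ev <- truth$events[truth$events$character == chars$character[ci], ]
    state <- rep(chars$root_state[ci], idx$n_tot)
    for (v in idx$preorder) {
      if (v == idx$root) next
      state[v] <- state[idx$parent[v]]
      sub <- ev[ev$branch == idx$labels[v], ]
      if (nrow(sub)) state[v] <- sub$to[order(sub$event)][nrow(sub)]
    }
    cells[, ci] <- state[seq_len(idx$n_tip)]
  }
  karyotype_matrix(tibble::as_tibble(cells) |>
                     dplyr::mutate(taxon = rownames(cells), .before = 1L))
}

#' Generate a complete synthetic dataset bundle
#'
#' Simulates gene trees, alignments and karyotypes under `params`, and
#' (optionally) writes everything in the package's input formats: per-locus
#' FASTA files, the taxon and class maps, the karyotype matrix, the species
#' tree, truth logs, and a JSON manifest echoing the parameters and seed.
#' Regeneration with the same parameters is byte-identical.
#'
#' @param params A [sim_params()].
#' @param dir Output directory (`NULL` = return objects only).
#' @param karyotype Arguments passed on to [simulate_karyotypes()] (list),
#'   or `FALSE` to skip the karyotype layer.
#' @return Invisibly, a list with `loci` (list of [locus_alignment()]),
#'   `gene_trees`, `truth`, `taxon_map`, `class_map`, `karyotype`,
#'   `species_tree`, and `dir`.
#' @export
generate_dataset <- function(params, dir = NULL, karyotype = list()) {
  stopifnot(inherits(params, "sim_params"))
  tm <- taxon_map(tibble(
    individual = as.vector(vapply(params$species_tree$tip.label, function(tx)
      paste0(tx, "_", seq_len(params$n_individuals)),
      character(params$n_individuals))),
    taxon = rep(params$species_tree$tip.label, each = params$n_individuals),
    group = rep(unname(params$groups[params$species_tree$tip.label]),
                each = params$n_individuals)))
  loci <- list(); gtrees <- list(); truth_rows <- list()
  for (cl in names(params$loci_per_class)) {
    n <- params$loci_per_class[[cl]]
    if (n == 0) next
    len <- if (cl %in% names(params$locus_length)) params$locus_length[[cl]]
           else params$locus_length[[1L]]
    for (i in seq_len(n)) {
      gs <- simulate_gene_tree(params, cl, i)
      id <- sprintf("%s_%04d", cl, i)
      aln <- simulate_alignment(gs$tree, len, params$mu, locus_id = id,
                                class = cl,
                                seed = locus_seed(params$seed, cl, i, salt = 1))
      loci[[id]] <- aln
      gtrees[[id]] <- gs$tree
      truth_rows[[id]] <- dplyr::mutate(gs$truth, locus = id, .before = 1L)
    }
  }
  cm <- locus_class_map(tibble(locus = names(loci),
                               class = vapply(loci, function(a) a$class,
                                              character(1L))))
  karyo <- NULL
  if (!identical(karyotype, FALSE)) {
    karyo <- do.call(simulate_karyotypes,
                     c(list(species_tree = params$species_tree),
                       karyotype,
                       if (!"seed" %in% names(karyotype))
                         list(seed = params$seed)))
  }
  truth <- list(loci = dplyr::bind_rows(truth_rows),
                karyotype = if (!is.null(karyo)) karyo$truth)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    for (id in names(loci)) {
      write_alignment(loci[[id]], file.path(dir, "loci", paste0(id, ".fasta")))
    }
    write_taxon_map(tm, file.path(dir, "taxon_map.tsv"))
    write_locus_class_map(cm, file.path(dir, "class_map.tsv"))
    write_tree(params$species_tree, file.path(dir, "species_tree.nwk"))
    if (!is.null(karyo)) {
      write_karyotype_matrix(karyo$matrix, file.path(dir, "karyotype.csv"))
      write_report(karyo$truth$events,
                   file.path(dir, "truth", "karyotype_events.tsv"), "tsv")
      write_report(karyo$truth$characters,
                   file.path(dir, "truth", "karyotype_characters.tsv"), "tsv")
    }
    gt <- truth$loci
    gt$newick <- vapply(gtrees[gt$locus], ape::write.tree, character(1L))
    write_report(gt, file.path(dir, "truth", "gene_trees.tsv"), "tsv")
    manifest <- list(seed = params$seed,
                     n_individuals = params$n_individuals,
                     loci_per_class = as.list(params$loci_per_class),
                     locus_length = as.list(params$locus_length),
                     mu = params$mu, ne_scale = as.list(params$ne_scale),
                     species_tree = ape::write.tree(params$species_tree),
                     introgression = if (is.null(params$introgression)) list()
                                     else params$introgression)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(loci = loci, gene_trees = gtrees, truth = truth,
                 taxon_map = tm, class_map = cm, karyotype = karyo,
                 species_tree = params$species_tree, dir = dir))
}
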