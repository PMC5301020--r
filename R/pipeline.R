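## End-to-end orchestration: read and cross-validate the inputs, then run
## partition -> divergence -> concordance -> parsimony and write a report
## bundle (divergence.tsv, concordance.tsv, events.tsv, summary.json plus a
## run manifest). Every number in summary.json is reproducible by calling
## the corresponding module function directly.

#' Assemble and validate a pipeline configuration
#'
#' @param loci_dir Directory of per-locus FASTA files.
#' @param taxon_map Path to the individual/taxon/group TSV.
#' @param class_map Path to the locus/class TSV.
#' @param karyotype_matrix Optional path to the karyotype CSV (enables the
#'   parsimony stage; requires `species_tree`).
#' @param species_tree Optional path to the species tree (Newick, taxon
#'   labels).
#' @param trees Optional named character vector `class = path` of
#'   individual-level partition trees; when absent, neighbour-joining trees
#'   from concatenated p-distances are built per class
#'   ([nj_fallback_tree()]; exploratory quality only).
#' @param model Distance model, `"p"` or `"jc69"`.
#' @param bootstrap Bootstrap replicates for divergence CIs (0 = none).
#' @param seed Seed; required when `bootstrap > 0`.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @param outgroup Outgroup taxon ids (used to root fallback trees).
#' @param root_constraints Named character vector of root-state constraints
#'   for the parsimony stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(loci_dir, taxon_map, class_map,
                            karyotype_matrix = NULL, species_tree = NULL,
                            trees = NULL, model = "p", bootstrap = 0,
                            seed = NULL, out_dir = NULL,
                            outgroup = character(),
                            root_constraints = NULL) {
  if (missing(loci_dir) || is.null(loci_dir)) {
    stop_validation("config field 'loci_dir' is required")
  }
  if (missing(taxon_map) || is.null(taxon_map)) {
    stop_validation("config field 'taxon_map' is required")
  }
  if (missing(class_map) || is.null(class_map)) {
    stop_validation("config field 'class_map' is required")
  }
  if (bootstrap > 0 && is.null(seed)) {
    stop_validation("config field 'seed' is required when bootstrap > 0")
  }
  structure(list(loci_dir = loci_dir, taxon_map = taxon_map,
                 class_map = class_map, karyotype_matrix = karyotype_matrix,
                 species_tree = species_tree, trees = trees, model = model,
                 bootstrap = bootstrap, seed = seed, out_dir = out_dir,
                 outgroup = outgroup, root_constraints = root_constraints),
            class = "pipeline_config")
}

read_loci_dir <- function(dir, class_map = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(paths)) stop_format("no FASTA files in %s", dir)
  loci <- lapply(paths, read_alignment)
  names(loci) <- vapply(loci, function(a) a$locus_id, character(1L))
  resolve_classes(loci, class_map)
}

#' Cross-validate pipeline inputs
#'
#' Checks file existence, that every sequenced individual and tree leaf
#' resolves through the taxon map, that loci have class assignments, and
#' that karyotype taxa appear in the species tree. Always returns a report;
#' fatal findings abort [run_pipeline()].
#'
#' @param config A [pipeline_config()].
#' @return A tibble with columns `level` (`"fatal"`/`"warning"`), `check`,
#'   `message`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  f <- list()
  note <- function(level, check, msg, ...) {
    f[[length(f) + 1L]] <<- tibble(level = level, check = check,
                                   message = sprintf(msg, ...))
  }
  paths <- c(loci_dir = config$loci_dir, taxon_map = config$taxon_map,
             class_map = config$class_map,
             karyotype_matrix = config$karyotype_matrix,
             species_tree = config$species_tree, config$trees)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      note("fatal", "paths", "input '%s' does not exist: %s", nm, paths[[nm]])
    }
  }
  if (length(f)) return(dplyr::bind_rows(f))
  tm <- read_taxon_map(config$taxon_map, outgroup = config$outgroup)
  cm <- read_locus_class_map(config$class_map)
  loci <- read_loci_dir(config$loci_dir)
  inds <- unique(unlist(lapply(loci, function(a) rownames(a$seq))))
  unmapped <- setdiff(inds, tm$individual)
  if (length(unmapped)) {
    note("fatal", "individuals", "sequenced individual(s) missing from taxon map: %s",
         paste(unmapped, collapse = ", "))
  }
  no_class <- setdiff(names(loci), cm$locus)
  if (length(no_class)) {
    note("warning", "classes", "locus(i) without class entry, treated as unassigned: %s",
         paste(no_class, collapse = ", "))
  }
  if (!is.null(config$trees)) {
    for (cl in names(config$trees)) {
      tr <- read_tree(config$trees[[cl]])
      bad <- setdiff(tr$tip.label, tm$individual)
      if (length(bad)) {
        note("fatal", "trees", "tree '%s' leaf(ves) missing from taxon map: %s",
             cl, paste(bad, collapse = ", "))
      }
    }
  }
  if (!is.null(config$karyotype_matrix)) {
    if (is.null(config$species_tree)) {
      note("fatal", "karyotype", "karyotype matrix given without a species tree")
    } else {
      km <- read_karyotype_matrix(config$karyotype_matrix)
      st <- read_tree(config$species_tree)
      bad <- setdiff(km$taxon, st$tip.label)
      if (length(bad)) {
        note("fatal", "karyotype", "matrix taxa absent from species tree: %s",
             paste(bad, collapse = ", "))
      }
    }
  }
  n_per_group <- table(unique(tm[c("taxon", "group")])$group)
  small <- names(n_per_group)[n_per_group < 2]
  if (length(small)) {
    note("warning", "groups", "group(s) with a single taxon are skipped in divergence: %s",
         paste(small, collapse = ", "))
  }
  if (!length(f)) note("ok", "all", "no findings")
  dplyr::bind_rows(f)
}

#' Neighbour-joining tree from concatenated p-distances
#'
#' Convenience fallback for partition trees when no externally inferred
#' trees are supplied: pools mismatch and compared-site counts across the
#' given loci (concatenation under pairwise deletion) and runs
#' neighbour-joining on the resulting p-distance matrix. Exploratory
#' quality only -- not a substitute for model-based tree inference.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param outgroup_individuals Optional individual ids to root the tree on.
#' @return An [ape::phylo] tree with individual-id leaves.
#' @export
nj_fallback_tree <- function(loci, outgroup_individuals = NULL) {
  inds <- sort(unique(unlist(lapply(loci, function(a) rownames(a$seq)))))
  mm <- matrix(0, length(inds), length(inds), dimnames = list(inds, inds))
  cs <- mm
  for (a in loci) {
    tab <- mismatch_tables(a)
    r <- rownames(a$seq)
    mm[r, r] <- mm[r, r] + tab$mm
    cs[r, r] <- cs[r, r] + tab$cs
  }
  if (any(cs[upper.tri(cs)] == 0)) {
    stop_validation("individual pair(s) share no compared sites; cannot build NJ tree")
  }
  tr <- ape::nj(stats::as.dist(mm / pmax(cs, 1)))
  tr$edge.length[tr$edge.length < 0] <- 0
  og <- intersect(outgroup_individuals %||% character(), tr$tip.label)
  if (length(og) &&
      is_monophyletic(tr, og, rooted = FALSE)) {
    tr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
  }
  tr
}

#' Run the full case-study pipeline
#'
#' Reads and validates all inputs, computes the class-by-group divergence
#' summary and per-class diversity, builds (or reads) partition trees and
#' the concordance table, maps karyotype events by parsimony, and -- when
#' `out_dir` is set -- writes `divergence.tsv`, `concordance.tsv`,
#' `events.tsv`, `summary.json` and `manifest.json`. Reruns with the same
#' config and inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `divergence`, `diversity`, `concordance`,
#'   `events` (a `karyotype_events` or `NULL`), `trees`, `summary`,
#'   `findings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- validate_inputs(config)
  fatal <- findings[findings$level == "fatal", ]
  if (nrow(fatal)) {
    stop_validation("input validation failed:\n%s",
                    paste(sprintf("- [%s] %s", fatal$check, fatal$message),
                          collapse = "\n"))
  }
  for (w in findings$message[findings$level == "warning"]) {
    message("[validate] warning: ", w)
  }
  tm <- read_taxon_map(config$taxon_map, outgroup = config$outgroup)
  cm <- read_locus_class_map(config$class_map)
  loci <- read_loci_dir(config$loci_dir, cm)
  message(sprintf("[divergence] %d loci, %d individuals, model %s",
                  length(loci), nrow(tm), config$model))
  classes_present <- sort(unique(vapply(loci, function(a) a$class,
                                        character(1L))))
  divergence <- class_group_summary(loci, tm, model = config$model,
                                    bootstrap = config$bootstrap,
                                    seed = config$seed)
  diversity <- diversity_by_class(loci, tm, model = config$model)
  ## partition trees
  og_ind <- tm$individual[tm$taxon %in% attr(tm, "outgroup")]
  trees <- if (!is.null(config$trees)) {
    lapply(config$trees, read_tree)
  } else {
    by_class <- split(loci, vapply(loci, function(a) a$class, character(1L)))
    lapply(by_class, nj_fallback_tree, outgroup_individuals = og_ind)
  }
  message(sprintf("[concordance] %d class trees (%s)", length(trees),
                  paste(names(trees), collapse = ", ")))
  concordance <- class_concordance_table(trees, tm)
  events <- NULL
  if (!is.null(config$karyotype_matrix)) {
    km <- read_karyotype_matrix(config$karyotype_matrix)
    st <- read_tree(config$species_tree)
    message(sprintf("[parsimony] %d characters on %d taxa",
                    ncol(km) - 1L, nrow(km)))
    events <- map_events(st, km, root_constraints = config$root_constraints)
  }
  summary <- list(
    seed = config$seed, model = config$model,
    classes = classes_present,
    divergence = lapply(seq_len(nrow(divergence)), function(i)
      as.list(divergence[i, c("group", "class", "mean_dA", "mean_diversity",
                              "n_loci")])),
    monophyly = {
      mono <- concordance[concordance$kind == "monophyly" &
                            concordance$group == "overall", ]
      setNames(as.list(mono$fraction), mono$class)
    },
    congruence = {
      cg <- concordance[concordance$kind == "congruence", ]
      lapply(seq_len(nrow(cg)), function(i)
        as.list(cg[i, c("class", "other_class", "rf", "normalized_rf")]))
    },
    parsimony = if (!is.null(events)) list(
      total_min_changes = sum(events$summary$min_changes),
      n_homoplasious = sum(events$summary$homoplasious),
      per_character = setNames(as.list(events$summary$min_changes),
                               events$summary$character)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(divergence, file.path(config$out_dir, "divergence.tsv"), "tsv")
    write_report(concordance, file.path(config$out_dir, "concordance.tsv"), "tsv")
    write_report(if (is.null(events)) tibble() else events$events,
                 file.path(config$out_dir, "events.tsv"), "tsv")
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    inputs <- c(config$taxon_map, config$class_map, config$karyotype_matrix,
                config$species_tree, unlist(config$trees))
    manifest <- list(
      package_version = as.character(utils::packageVersion("chromospec")),
      seed = config$seed, model = config$model,
      bootstrap = config$bootstrap,
      input_md5 = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message("[report] written to ", config$out_dir)
  }
  invisible(list(divergence = divergence, diversity = diversity,
                 concordance = concordance, events = events, trees = trees,
                 summary = summary, findings = findings))
}
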