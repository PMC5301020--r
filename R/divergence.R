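## Within-taxon diversity and between-taxon net divergence (Nei's dA),
## partitioned by chromosome class and chromosomal group. Distances are
## uncorrected p-distances by default (JC69 optional) with pairwise deletion:
## a site enters a comparison only when both sequences carry an unambiguous
## base, so gaps, "?" and IUPAC ambiguity codes are missing.

UNAMBIGUOUS_BASES <- c("A", "C", "G", "T")

## mismatch and compared-site counts for every pair of rows, via one-hot
## cross-products (fast enough to cover thousands of loci)
mismatch_tables <- function(alignment) {
  m <- alignment$seq
  ok <- matrix(m %in% UNAMBIGUOUS_BASES, nrow(m), ncol(m))
  okn <- ok * 1
  cs <- okn %*% t(okn)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in UNAMBIGUOUS_BASES) {
    ind <- (m == b & ok) * 1
    matches <- matches + tcrossprod(ind)
  }
  dimnames(cs) <- list(rownames(m), rownames(m))
  list(mm = cs - matches, cs = cs)
}

jc69_correct <- function(p) {
  if (any(p >= 0.75)) {
    stop_validation("p-distance %.3f >= 0.75: JC69 correction is saturated",
                    max(p))
  }
  -0.75 * log(1 - 4 * p / 3)
}

apply_model <- function(p, model) {
  if (model == "jc69") jc69_correct(p) else p
}

#' Pairwise sequence distance with pairwise deletion
#'
#' @param seq_a,seq_b Equal-length sequence strings (or character vectors of
#'   residues). Sites where either sequence is a gap, `?` or an IUPAC
#'   ambiguity code are excluded.
#' @param model `"p"` (uncorrected proportion of differing sites) or
#'   `"jc69"` (Jukes-Cantor, `-(3/4) log(1 - 4p/3)`).
#' @return A list with `distance` and `compared_sites`.
#' @export
pairwise_distance <- function(seq_a, seq_b, model = c("p", "jc69")) {
  model <- match.arg(model)
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1L]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1L]] else toupper(seq_b)
  if (length(a) != length(b)) stop_validation("sequences have unequal lengths")
  use <- a %in% UNAMBIGUOUS_BASES & b %in% UNAMBIGUOUS_BASES
  n <- sum(use)
  if (n == 0L) stop_validation("no mutually unambiguous sites: distance undefined")
  p <- sum(a[use] != b[use]) / n
  list(distance = apply_model(p, model), compared_sites = n)
}

## individuals of a taxon present in an alignment
taxon_rows <- function(alignment, map, taxon) {
  ind <- map$individual[map$taxon == taxon]
  intersect(rownames(alignment$seq), ind)
}

sum_pairs <- function(tab, rows_a, rows_b = NULL) {
  if (is.null(rows_b)) { # unordered within-group pairs
    if (length(rows_a) < 2L) return(c(n = 0, mm = 0, cs = 0))
    sub_mm <- tab$mm[rows_a, rows_a, drop = FALSE]
    sub_cs <- tab$cs[rows_a, rows_a, drop = FALSE]
    up <- upper.tri(sub_mm)
    c(n = sum(up), mm = sum(sub_mm[up]), cs = sum(sub_cs[up]))
  } else {
    c(n = length(rows_a) * length(rows_b),
      mm = sum(tab$mm[rows_a, rows_b, drop = FALSE]),
      cs = sum(tab$cs[rows_a, rows_b, drop = FALSE]))
  }
}

#' Net divergence between two taxa at one locus
#'
#' Computes the mean between-taxon distance `d_XY`, the mean within-taxon
#' distances `d_X` and `d_Y`, and the net divergence
#' `dA = d_XY - (d_X + d_Y)/2`, which discounts shared ancestral diversity.
#' Means over individual pairs pool mismatch and compared-site counts, so a
#' record aggregated across loci equals the distance computed on the
#' concatenated alignment. A taxon with a single sampled individual
#' contributes a within-taxon term of 0 and the record is flagged.
#'
#' @param alignment A [locus_alignment()].
#' @param taxon_map A [taxon_map()] resolving individuals to taxa.
#' @param taxon_a,taxon_b Taxon ids present in the alignment.
#' @param model `"p"` or `"jc69"`.
#' @return A one-row tibble (locus, class, taxa, `d_xy`, `d_x`, `d_y`, `d_a`,
#'   `compared_sites`, pooled counts, `single_individual` flag).
#' @export
net_divergence <- function(alignment, taxon_map, taxon_a, taxon_b,
                           model = c("p", "jc69")) {
  model <- match.arg(model)
  tab <- mismatch_tables(alignment)
  rows_a <- taxon_rows(alignment, taxon_map, taxon_a)
  rows_b <- taxon_rows(alignment, taxon_map, taxon_b)
  if (!length(rows_a)) stop_validation("taxon '%s' absent from locus '%s'",
                                       taxon_a, alignment$locus_id)
  if (!length(rows_b)) stop_validation("taxon '%s' absent from locus '%s'",
                                       taxon_b, alignment$locus_id)
  bt <- sum_pairs(tab, rows_a, rows_b)
  wa <- sum_pairs(tab, rows_a)
  wb <- sum_pairs(tab, rows_b)
  if (bt[["cs"]] == 0) stop_validation("no comparable sites between '%s' and '%s' at locus '%s'",
                                       taxon_a, taxon_b, alignment$locus_id)
  d_xy <- apply_model(bt[["mm"]] / bt[["cs"]], model)
  d_x <- if (wa[["cs"]] > 0) apply_model(wa[["mm"]] / wa[["cs"]], model) else 0
  d_y <- if (wb[["cs"]] > 0) apply_model(wb[["mm"]] / wb[["cs"]], model) else 0
  tibble(locus = alignment$locus_id, class = alignment$class,
         taxon_a = taxon_a, taxon_b = taxon_b,
         d_xy = d_xy, d_x = d_x, d_y = d_y,
         d_a = d_xy - (d_x + d_y) / 2,
         compared_sites = as.integer(round(bt[["cs"]] / max(bt[["n"]], 1))),
         n_pairs_between = as.integer(bt[["n"]]),
         mm_between = bt[["mm"]], cs_between = bt[["cs"]],
         n_pairs_a = as.integer(wa[["n"]]), mm_a = wa[["mm"]], cs_a = wa[["cs"]],
         n_pairs_b = as.integer(wb[["n"]]), mm_b = wb[["mm"]], cs_b = wb[["cs"]],
         single_individual = wa[["n"]] == 0 || wb[["n"]] == 0)
}

resolve_classes <- function(loci, class_map) {
  lapply(loci, function(a) {
    if (!is.null(class_map)) a$class <- locus_class(class_map, a$locus_id)
    a
  })
}

#' Per-locus, per-taxon-pair divergence records
#'
#' Applies [net_divergence()] to every requested taxon pair at every locus.
#' By default the pairs are all unordered pairs of taxa that share a
#' chromosomal group. Pairs with a taxon absent from a locus are skipped.
#'
#' @param loci List of [locus_alignment()] objects.
#' @param taxon_map A [taxon_map()].
#' @param class_map Optional [locus_class_map()]; when given it overrides the
#'   per-locus class labels.
#' @param pairs Optional data frame with columns `taxon_a`, `taxon_b`.
#' @param model `"p"` or `"jc69"`.
#' @return A tibble with one row per locus x pair, plus a `group` column.
#' @export
divergence_records <- function(loci, taxon_map, class_map = NULL,
                               pairs = NULL, model = c("p", "jc69")) {
  model <- match.arg(model)
  loci <- resolve_classes(loci, class_map)
  if (is.null(pairs)) {
    pairs <- dplyr::bind_rows(lapply(split(taxon_map, taxon_map$group), function(g) {
      tx <- unique(g$taxon)
      if (length(tx) < 2L) return(NULL)
      cmb <- combn(sort(tx), 2L)
      tibble(taxon_a = cmb[1L, ], taxon_b = cmb[2L, ])
    }))
  }
  grp <- setNames(taxon_map$group, taxon_map$taxon)
  recs <- purrr::map_dfr(loci, function(a) {
    tab <- mismatch_tables(a)
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      ta <- pairs$taxon_a[i]; tb <- pairs$taxon_b[i]
      rows_a <- taxon_rows(a, taxon_map, ta)
      rows_b <- taxon_rows(a, taxon_map, tb)
      if (!length(rows_a) || !length(rows_b)) return(NULL)
      bt <- sum_pairs(tab, rows_a, rows_b)
      if (bt[["cs"]] == 0) return(NULL)
      wa <- sum_pairs(tab, rows_a)
      wb <- sum_pairs(tab, rows_b)
      d_xy <- apply_model(bt[["mm"]] / bt[["cs"]], model)
      d_x <- if (wa[["cs"]] > 0) apply_model(wa[["mm"]] / wa[["cs"]], model) else 0
      d_y <- if (wb[["cs"]] > 0) apply_model(wb[["mm"]] / wb[["cs"]], model) else 0
      tibble(locus = a$locus_id, class = a$class, taxon_a = ta, taxon_b = tb,
             d_xy = d_xy, d_x = d_x, d_y = d_y, d_a = d_xy - (d_x + d_y) / 2,
             compared_sites = as.integer(round(bt[["cs"]] / bt[["n"]])),
             n_pairs_between = as.integer(bt[["n"]]),
             mm_between = bt[["mm"]], cs_between = bt[["cs"]],
             n_pairs_a = as.integer(wa[["n"]]), mm_a = wa[["mm"]], cs_a = wa[["cs"]],
             n_pairs_b = as.integer(wb[["n"]]), mm_b = wb[["mm"]], cs_b = wb[["cs"]],
             single_individual = wa[["n"]] == 0 || wb[["n"]] == 0)
    })
  })
  if (nrow(recs)) recs$group <- unname(grp[recs$taxon_a])
  recs
}

#' Length-weighted mean net divergence over a record subset
#'
#' Pools mismatch and compared-site counts across the loci of a
#' [divergence_records()] subset before forming distances (equivalent to
#' concatenation under pairwise-deletion p-distance), computes per-pair net
#' divergence, and averages over the unordered taxon pairs present.
#'
#' @param records Rows of a [divergence_records()] tibble.
#' @param model `"p"` or `"jc69"`.
#' @return A single number.
#' @export
weighted_mean_dA <- function(records, model = "p") {
  per_pair <- records |>
    dplyr::group_by(.data$taxon_a, .data$taxon_b) |>
    dplyr::summarise(
      d_xy = apply_model(sum(.data$mm_between) / sum(.data$cs_between), model),
      d_x = ifelse(sum(.data$cs_a) > 0,
                   apply_model(sum(.data$mm_a) / max(sum(.data$cs_a), 1), model), 0),
      d_y = ifelse(sum(.data$cs_b) > 0,
                   apply_model(sum(.data$mm_b) / max(sum(.data$cs_b), 1), model), 0),
      .groups = "drop") |>
    dplyr::mutate(d_a = .data$d_xy - (.data$d_x + .data$d_y) / 2)
  mean(per_pair$d_a)
}

#' Class-by-group divergence summary
#'
#' Length-weighted mean net divergence (and within-taxon diversity) for each
#' chromosomal group and chromosome class. Weighting pools mismatch and
#' compared-site counts across loci before forming distances, which is
#' equivalent to computing the distance on the concatenated alignment under
#' pairwise-deletion p-distance; the per-pair net divergences are then
#' averaged over all unordered taxon pairs within the group. A nonparametric
#' percentile bootstrap over loci supplies confidence intervals.
#'
#' @inheritParams divergence_records
#' @param groups Groups to summarise; `"all"` (default) = every group with at
#'   least two taxa.
#' @param classes Classes to summarise; default all classes present.
#' @param bootstrap Number of bootstrap replicates (0 = none; otherwise at
#'   least 100).
#' @param seed RNG seed, required when `bootstrap > 0`.
#' @param conf Confidence level for the percentile interval.
#' @return A tibble with one row per group x class: `mean_dA`,
#'   `mean_diversity`, `n_loci`, `total_sites`, and CI columns when
#'   bootstrapped.
#' @export
class_group_summary <- function(loci, taxon_map, class_map = NULL,
                                groups = "all", classes = NULL,
                                model = c("p", "jc69"),
                                bootstrap = 0, seed = NULL, conf = 0.95) {
  model <- match.arg(model)
  records <- divergence_records(loci, taxon_map, class_map, model = model)
  if (!nrow(records)) stop_validation("no divergence records: check groups have >= 2 taxa")
  if (identical(groups, "all")) {
    groups <- sort(unique(records$group))
  } else {
    bad <- setdiff(groups, unique(records$group))
    if (length(bad)) stop_validation("group(s) with < 2 taxa or unknown: %s",
                                     paste(bad, collapse = ", "))
  }
  if (is.null(classes)) classes <- sort(unique(records$class))
  if (bootstrap > 0) {
    if (bootstrap < 100) stop_validation("bootstrap replicates must be >= 100")
    if (is.null(seed)) stop_validation("seed is required for bootstrap")
  }
  combos <- tidyr::expand_grid(group = groups, class = classes)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    g <- combos$group[i]; cl <- combos$class[i]
    sub <- records[records$group == g & records$class == cl, ]
    if (!nrow(sub)) stop_validation("no loci of class '%s' for group '%s'", cl, g)
    mean_dA <- weighted_mean_dA(sub, model)
    div_cs <- sum(sub$cs_a[!duplicated(paste(sub$locus, sub$taxon_a))]) +
      sum(sub$cs_b[!duplicated(paste(sub$locus, sub$taxon_b))])
    div_mm <- sum(sub$mm_a[!duplicated(paste(sub$locus, sub$taxon_a))]) +
      sum(sub$mm_b[!duplicated(paste(sub$locus, sub$taxon_b))])
    mean_div <- if (div_cs > 0) apply_model(div_mm / div_cs, model) else NA_real_
    out <- tibble(group = g, class = cl, mean_dA = mean_dA,
                  mean_diversity = mean_div,
                  n_loci = dplyr::n_distinct(sub$locus),
                  total_sites = sum(sub$cs_between[!duplicated(sub$locus)] /
                                      sub$n_pairs_between[!duplicated(sub$locus)]))
    if (bootstrap > 0) {
      ci <- bootstrap_ci(sub, function(r) weighted_mean_dA(r, model),
                         reps = bootstrap, seed = seed + i, conf = conf)
      out$ci_lower <- ci[[1L]]; out$ci_upper <- ci[[2L]]
      out$boot_reps <- bootstrap; out$boot_seed <- seed + i
    }
    out
  })
}

#' Within-taxon diversity by chromosome class
#'
#' Length-weighted mean within-taxon diversity per class, pooled over all
#' taxa with at least two sampled individuals.
#'
#' @inheritParams divergence_records
#' @return A tibble with one row per class: `mean_diversity`, `n_loci`,
#'   `n_taxa`, `total_sites`.
#' @export
diversity_by_class <- function(loci, taxon_map, class_map = NULL,
                               model = c("p", "jc69")) {
  model <- match.arg(model)
  loci <- resolve_classes(loci, class_map)
  rows <- purrr::map_dfr(loci, function(a) {
    tab <- mismatch_tables(a)
    purrr::map_dfr(unique(taxon_map$taxon), function(tx) {
      r <- taxon_rows(a, taxon_map, tx)
      if (length(r) < 2L) return(NULL)
      w <- sum_pairs(tab, r)
      tibble(locus = a$locus_id, class = a$class, taxon = tx,
             mm = w[["mm"]], cs = w[["cs"]])
    })
  })
  if (!nrow(rows)) stop_validation("no taxon with >= 2 individuals: diversity undefined")
  rows |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(mean_diversity = apply_model(sum(.data$mm) / sum(.data$cs), model),
                     n_loci = dplyr::n_distinct(.data$locus),
                     n_taxa = dplyr::n_distinct(.data$taxon),
                     total_sites = sum(.data$cs), .groups = "drop")
}

#' Percentile bootstrap over loci
#'
#' Resamples loci (the natural exchangeable unit of an exon-capture dataset)
#' with replacement and returns a percentile confidence interval for any
#' statistic of a record table. Deterministic for a fixed seed.
#'
#' @param records A tibble with a `locus` column (e.g. from
#'   [divergence_records()]).
#' @param statistic Function mapping a record tibble to a single number.
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed RNG seed (required).
#' @param conf Confidence level.
#' @return Named list `lower`, `upper`.
#' @export
bootstrap_ci <- function(records, statistic, reps = 1000, seed, conf = 0.95) {
  if (missing(seed) || is.null(seed)) stop_validation("seed is required")
  if (reps < 100) stop_validation("bootstrap replicates must be >= 100")
  loci <- unique(records$locus)
  if (length(loci) < 2L) stop_validation("fewer than 2 loci: CI undefined")
  by_locus <- split(records, records$locus)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      pick <- sample(loci, length(loci), replace = TRUE)
      statistic(dplyr::bind_rows(by_locus[pick]))
    }, numeric(1L))
  })
  alpha <- (1 - conf) / 2
  q <- unname(quantile(vals, c(alpha, 1 - alpha), type = 7, names = FALSE))
  list(lower = q[1L], upper = q[2L])
}
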