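## Readers/writers for the formats the pipeline touches, each returning a
## validated domain object. Conventions: sequences are case-folded to upper
## case on input; "-" and "?" are missing at a site, as are IUPAC ambiguity
## codes for distance purposes; tabular files are tab-separated with a header;
## site coordinates are 1-based in reports.

ALIGNMENT_ALPHABET <- c("A", "C", "G", "T",
                        "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N",
                        "-", "?")

#' Construct a locus alignment
#'
#' A locus alignment holds the aligned sequences of one locus as a character
#' matrix (individuals in rows, sites in columns), together with the locus id
#' and an optional chromosome-class label.
#'
#' @param sequences Named character vector of equal-length sequence strings,
#'   or a character matrix of single residues with individual ids as row
#'   names.
#' @param locus_id Locus identifier.
#' @param class Chromosome class label, one of `"X"`, `"rearranged"`,
#'   `"non_rearranged"`, `"unassigned"`.
#' @return An object of class `locus_alignment` with fields `locus_id`,
#'   `seq` (residue matrix), `class`.
#' @export
locus_alignment <- function(sequences, locus_id = "locus", class = "unassigned") {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences)) || anyNA(names(sequences))) {
      stop_validation("sequences must be named by individual id")
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      stop_format("alignment '%s': rows have unequal lengths (%s)",
                  locus_id, paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(m) <- names(sequences)
  }
  m[] <- toupper(m)
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop_format("alignment '%s' is empty", locus_id)
  }
  if (anyDuplicated(rownames(m))) {
    stop_validation("alignment '%s': duplicate individual ids: %s", locus_id,
                    paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  bad <- which(!(m %in% ALIGNMENT_ALPHABET))
  if (length(bad)) {
    i <- bad[1L]
    row <- ((i - 1L) %% nrow(m)) + 1L
    col <- ((i - 1L) %/% nrow(m)) + 1L
    stop_format("alignment '%s': illegal residue '%s' in row '%s', site %d",
                locus_id, m[i], rownames(m)[row], col)
  }
  class <- match.arg(class, LOCUS_CLASSES)
  structure(list(locus_id = locus_id, seq = m, class = class),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d sites (class %s)\n",
              x$locus_id, nrow(x$seq), ncol(x$seq), x$class))
  invisible(x)
}

#' @export
length.locus_alignment <- function(x) ncol(x$seq)

#' Read one locus alignment from FASTA
#'
#' @param path Path to a FASTA file.
#' @param format Only `"fasta"` is supported.
#' @param locus_id Locus id; defaults to the file name without extension.
#' @param class Chromosome class label for the locus.
#' @return A [locus_alignment()].
#' @export
read_alignment <- function(path, format = "fasta", locus_id = NULL,
                           class = "unassigned") {
  format <- match.arg(tolower(format), "fasta")
  if (!file.exists(path)) stop_format("no such file: %s", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) stop_format("cannot parse FASTA '%s': %s", path,
                                    conditionMessage(e)))
  if (length(recs) == 0L) stop_format("FASTA '%s' contains no records", path)
  seqs <- setNames(vapply(recs, as.character, character(1L)), names(recs))
  if (is.null(locus_id)) locus_id <- sub("\\.[^.]*$", "", basename(path))
  locus_alignment(seqs, locus_id = locus_id, class = class)
}

#' Write one locus alignment to FASTA
#'
#' @param alignment A [locus_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "locus_alignment"))
  seqs <- apply(alignment$seq, 1L, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phylogenetic tree from Newick
#'
#' Parses labels, branch lengths and support values (stored as internal node
#' labels, the RAxML convention). Polytomies are permitted.
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param format Only `"newick"` is supported.
#' @param text Optional literal Newick string (then `path` is ignored).
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, format = "newick", text = NULL) {
  format <- match.arg(tolower(format), "newick")
  tr <- tryCatch({
    withCallingHandlers(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
      warning = function(w) {
        stop_format("cannot parse Newick: %s", conditionMessage(w))
      })
  }, error = function(e) {
    if (inherits(e, "chromospec_format_error")) rlang::cnd_signal(e)
    stop_format("cannot parse Newick: %s", conditionMessage(e))
  })
  if (is.null(tr)) stop_format("cannot parse Newick input")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    stop_validation("duplicate leaf labels: %s",
                    paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                          collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop_validation("negative branch lengths")
  }
  tr
}

#' Write a tree to Newick
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct an individual-to-taxon-to-group map
#'
#' The taxon map is the grouping backbone of every analysis: each sampled
#' individual belongs to exactly one taxon, and each taxon to exactly one
#' chromosomal group. Outgroup taxa are carried as an attribute.
#'
#' @param entries Data frame with columns `individual`, `taxon`, `group`.
#' @param outgroup Character vector of outgroup taxon ids (subset of `taxon`).
#' @return A tibble of class `taxon_map` with attribute `outgroup`.
#' @export
taxon_map <- function(entries, outgroup = character()) {
  need <- c("individual", "taxon", "group")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop_format("taxon map missing column(s): %s",
                                paste(miss, collapse = ", "))
  tm <- as_tibble(entries)[need]
  tm[] <- lapply(tm, as.character)
  if (anyDuplicated(tm$individual)) {
    stop_validation("duplicate individual id(s): %s",
                    paste(unique(tm$individual[duplicated(tm$individual)]),
                          collapse = ", "))
  }
  tg <- unique(tm[c("taxon", "group")])
  if (anyDuplicated(tg$taxon)) {
    stop_validation("taxon assigned to more than one group: %s",
                    paste(unique(tg$taxon[duplicated(tg$taxon)]), collapse = ", "))
  }
  bad_og <- setdiff(outgroup, tm$taxon)
  if (length(bad_og)) stop_validation("outgroup taxa not in map: %s",
                                      paste(bad_og, collapse = ", "))
  structure(tm, outgroup = as.character(outgroup),
            class = c("taxon_map", class(tm)))
}

#' Read a taxon map from TSV
#'
#' Expects a tab-separated file with header columns `individual`, `taxon`,
#' `group`.
#'
#' @param path Path to the TSV file.
#' @param outgroup Character vector of outgroup taxon ids.
#' @return A [taxon_map()].
#' @export
read_taxon_map <- function(path, outgroup = character()) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  taxon_map(df, outgroup = outgroup)
}

#' @rdname read_taxon_map
#' @param map A [taxon_map()] to write.
#' @export
write_taxon_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a locus-to-chromosome-class map
#'
#' @param assignments Data frame with columns `locus`, `class`; classes are
#'   restricted to `"X"`, `"rearranged"`, `"non_rearranged"`, `"unassigned"`.
#' @param class_chromosomes Named list mapping each class to the chromosome
#'   labels it covers. Defaults to the rock-wallaby partition (X; rearranged
#'   autosomes 5, 6, 9, 10; non-rearranged autosomes 2, 4, 7, 8).
#' @return A tibble of class `locus_class_map`.
#' @export
locus_class_map <- function(assignments,
                            class_chromosomes = list(
                              X = "X",
                              rearranged = c("5", "6", "9", "10"),
                              non_rearranged = c("2", "4", "7", "8"))) {
  need <- c("locus", "class")
  miss <- setdiff(need, names(assignments))
  if (length(miss)) stop_format("class map missing column(s): %s",
                                paste(miss, collapse = ", "))
  cm <- as_tibble(assignments)[need]
  cm[] <- lapply(cm, as.character)
  bad <- setdiff(unique(cm$class), LOCUS_CLASSES)
  if (length(bad)) {
    stop_validation("unknown locus class token(s): %s (allowed: %s)",
                    paste(bad, collapse = ", "),
                    paste(LOCUS_CLASSES, collapse = ", "))
  }
  if (anyDuplicated(cm$locus)) {
    stop_validation("duplicate locus id(s): %s",
                    paste(unique(cm$locus[duplicated(cm$locus)]), collapse = ", "))
  }
  structure(cm, class_chromosomes = class_chromosomes,
            class = c("locus_class_map", class(cm)))
}

#' Look up the class of a locus, defaulting to "unassigned"
#' @param class_map A [locus_class_map()].
#' @param locus_id Locus id(s).
#' @return Character vector of classes.
#' @export
locus_class <- function(class_map, locus_id) {
  i <- match(locus_id, class_map$locus)
  out <- class_map$class[i]
  out[is.na(i)] <- "unassigned"
  out
}

#' Read a locus class map from TSV
#' @param path Path to a TSV with header columns `locus`, `class`.
#' @inheritParams locus_class_map
#' @return A [locus_class_map()].
#' @export
read_locus_class_map <- function(path, class_chromosomes = list(
                                   X = "X",
                                   rearranged = c("5", "6", "9", "10"),
                                   non_rearranged = c("2", "4", "7", "8"))) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  locus_class_map(df, class_chromosomes = class_chromosomes)
}

#' @rdname read_locus_class_map
#' @param map A [locus_class_map()] to write.
#' @export
write_locus_class_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("locus", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a karyotype character-state matrix
#'
#' Taxa in rows, chromosome characters in columns. States are unordered
#' morphology codes (`a` acrocentric, `m` metacentric, `sm` submetacentric,
#' `i` inversion) or fusion tokens such as `"5-10"`; `"?"`/`NA` is missing.
#' Per-character state alphabets are induced from the observed tokens.
#'
#' @param cells Data frame with a `taxon` column plus one column per
#'   character.
#' @param diploid Optional named integer vector of diploid numbers (2n) per
#'   taxon; must be even and at least 2.
#' @return A tibble of class `karyotype_matrix` with attributes `alphabets`
#'   (per-character state sets) and `diploid`.
#' @export
karyotype_matrix <- function(cells, diploid = NULL) {
  if (!"taxon" %in% names(cells)) stop_format("karyotype matrix needs a 'taxon' column")
  km <- as_tibble(cells)
  km[] <- lapply(km, as.character)
  if (anyDuplicated(km$taxon)) {
    stop_validation("duplicate taxa in karyotype matrix: %s",
                    paste(unique(km$taxon[duplicated(km$taxon)]), collapse = ", "))
  }
  chars <- setdiff(names(km), "taxon")
  if (!length(chars)) stop_format("karyotype matrix has no character columns")
  for (ch in chars) km[[ch]][km[[ch]] %in% c("?", "", "NA")] <- NA_character_
  alphabets <- lapply(km[chars], function(col) sort(unique(col[!is.na(col)])))
  empty <- chars[vapply(alphabets, length, 1L) == 0L]
  if (length(empty)) {
    stop_validation("character(s) with no observed states: %s",
                    paste(empty, collapse = ", "))
  }
  if (!is.null(diploid)) {
    diploid <- diploid[!is.na(diploid)]
    if (any(diploid < 2L | diploid %% 2L != 0L)) {
      stop_validation("2n values must be even integers >= 2")
    }
  }
  structure(km, alphabets = alphabets, diploid = diploid,
            class = c("karyotype_matrix", class(km)))
}

#' Read a karyotype matrix
#'
#' Accepts a comma-separated table (taxa in rows, first column `taxon`,
#' remaining columns characters) or a NEXUS file with a characters block
#' (single-character state symbols only; fusion tokens need the CSV layout).
#'
#' @param path Input path.
#' @param format `"csv"` or `"nexus"`; default guesses from the extension.
#' @param diploid Optional named 2n vector, passed to [karyotype_matrix()].
#' @return A [karyotype_matrix()].
#' @export
read_karyotype_matrix <- function(path, format = NULL, diploid = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "csv"
  }
  format <- match.arg(tolower(format), c("csv", "nexus"))
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, colClasses = "character",
                                   check.names = FALSE),
                   error = function(e) stop_format("cannot parse CSV '%s': %s",
                                                   path, conditionMessage(e)))
  } else {
    lst <- tryCatch(ape::read.nexus.data(path),
                    error = function(e) stop_format("cannot parse NEXUS '%s': %s",
                                                    path, conditionMessage(e)))
    nch <- unique(lengths(lst))
    if (length(nch) != 1L) stop_format("NEXUS characters block is ragged")
    df <- data.frame(taxon = names(lst),
                     do.call(rbind, lst), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[-1L] <- paste0("char", seq_len(nch))
  }
  karyotype_matrix(df, diploid = diploid)
}

#' @rdname read_karyotype_matrix
#' @param matrix A [karyotype_matrix()] to write (CSV layout).
#' @export
write_karyotype_matrix <- function(matrix, path) {
  df <- as.data.frame(matrix)
  df[is.na(df)] <- "?"
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Census of distinct fusions involving one chromosome
#'
#' Fusion states are coded as `"5-10"`-style tokens joining the two
#' participating chromosomes. The same fusion may appear in the columns of
#' both chromosomes involved; the census deduplicates by token so each
#' distinct fusion is counted once. In wild rock-wallaby karyotypes
#' chromosome 10 participates in five of the eight known fusions, matching
#' its elevated in-vitro fusion rate.
#'
#' @param matrix A [karyotype_matrix()].
#' @param chromosome Chromosome label, e.g. `"10"`.
#' @return A one-row tibble with `chromosome`, `n_involving`, `n_fusions`.
#' @export
fusion_census <- function(matrix, chromosome) {
  stopifnot(inherits(matrix, "karyotype_matrix"))
  states <- unlist(lapply(attr(matrix, "alphabets"), identity), use.names = FALSE)
  fus <- unique(states[grepl("^[^-]+-[^-]+$", states)])
  parts <- strsplit(fus, "-", fixed = TRUE)
  inv <- vapply(parts, function(p) chromosome %in% p, logical(1L))
  tibble(chromosome = as.character(chromosome),
         n_involving = sum(inv), n_fusions = length(fus))
}

#' Write a result table to TSV or JSON
#'
#' Deterministic: column order is preserved, floating point values are
#' rendered with six decimals, and writing the same table twice produces
#' byte-identical files.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  num <- vapply(df, is.double, logical(1L))
  if (format == "tsv") {
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
  } else {
    df[num] <- lapply(df[num], function(x) round(x, 6L))
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = FALSE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    as_tibble(read.delim(path, sep = "\t"))
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
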