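# Shared in-code fixtures.

toy_taxon_map <- function() {
  taxon_map(tibble::tibble(
    individual = c("X1", "X2", "Y1", "Y2"),
    taxon = c("X", "X", "Y", "Y"),
    group = "g1"))
}

write_fasta_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# concatenate locus alignments over the shared individual set
concat_alignments <- function(loci, locus_id = "concat") {
  inds <- Reduce(intersect, lapply(loci, function(a) rownames(a$seq)))
  m <- do.call(cbind, lapply(loci, function(a) a$seq[inds, , drop = FALSE]))
  locus_alignment(m, locus_id = locus_id)
}

random_alignment <- function(individuals, n_sites, p_missing = 0,
                             locus_id = "locus", class = "unassigned") {
  m <- matrix(sample(c("A", "C", "G", "T"), length(individuals) * n_sites,
                     replace = TRUE),
              length(individuals), n_sites,
              dimnames = list(individuals, NULL))
  if (p_missing > 0) {
    mask <- matrix(runif(length(m)) < p_missing, nrow(m))
    m[mask] <- "-"
  }
  locus_alignment(m, locus_id = locus_id, class = class)
}
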