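# Validators for the plain-data.frame containers used throughout the
# package.
#
# A genome build is a data.frame with columns `chrom` (unique names, in
# karyotype order) and `length` (bp). A haplotype panel is a long-format
# data.frame with columns `strain`, `chrom`, `start`, `end`, `haplotype`:
# one row per block, 0-based half-open coordinates, blocks sorted and
# non-overlapping within a strain/chromosome. Uncovered spans are missing
# data, not an error.

validate_genome <- function(genome) {
  assert_columns(genome, c("chrom", "length"), "genome")
  if (nrow(genome) == 0) stopf("genome build is empty")
  if (anyDuplicated(genome$chrom)) {
    stopf("duplicate chromosome name(s) in genome build: %s",
          paste(unique(genome$chrom[duplicated(genome$chrom)]), collapse = ", "))
  }
  len <- genome$length
  if (!is.numeric(len) || anyNA(len) || any(len <= 0) || any(len != trunc(len))) {
    stopf("chromosome lengths must be positive integers")
  }
  invisible(genome)
}

genome_length <- function(genome) {
  validate_genome(genome)
  sum(as.double(genome$length))
}

validate_panel <- function(panel, genome = NULL, strict = TRUE) {
  assert_columns(panel, c("strain", "chrom", "start", "end", "haplotype"),
                 "panel")
  if (nrow(panel) == 0) return(invisible(panel))
  if (!is.numeric(panel$start) || !is.numeric(panel$end) ||
      anyNA(panel$start) || anyNA(panel$end)) {
    stopf("block coordinates must be non-missing numbers")
  }
  if (any(panel$start < 0)) stopf("block start coordinates must be >= 0")
  bad <- which(panel$start >= panel$end)
  if (length(bad) > 0) {
    stopf("block with start >= end for strain %s on %s ([%d, %d))",
          panel$strain[bad[1]], panel$chrom[bad[1]],
          panel$start[bad[1]], panel$end[bad[1]])
  }
  if (anyNA(panel$haplotype) || any(!nzchar(panel$haplotype))) {
    stopf("haplotype labels must be non-empty strings")
  }
  # overlap check within each strain/chromosome
  key <- split(seq_len(nrow(panel)), list(panel$strain, panel$chrom),
               drop = TRUE)
  for (idx in key) {
    if (length(idx) < 2) next
    o <- idx[order(panel$start[idx])]
    if (any(panel$start[o][-1] < panel$end[o][-length(o)])) {
      stopf("overlapping blocks for strain %s on chromosome %s",
            panel$strain[o[1]], panel$chrom[o[1]])
    }
  }
  if (!is.null(genome)) {
    validate_genome(genome)
    unknown <- setdiff(unique(panel$chrom), genome$chrom)
    if (length(unknown) > 0 && strict) {
      stopf("panel uses chromosome(s) absent from the genome build: %s",
            paste(unknown, collapse = ", "))
    }
    m <- match(panel$chrom, genome$chrom)
    over <- which(!is.na(m) & panel$end > genome$length[m])
    if (length(over) > 0) {
      stopf("block end %d exceeds length of chromosome %s",
            panel$end[over[1]], panel$chrom[over[1]])
    }
  }
  invisible(panel)
}

validate_regions <- function(regions, genome = NULL, require_disjoint = TRUE) {
  assert_columns(regions, c("chrom", "start", "end"), "regions")
  if (nrow(regions) == 0) return(invisible(regions))
  if (any(regions$start < 0) || any(regions$start >= regions$end)) {
    stopf("regions must satisfy 0 <= start < end")
  }
  if (!is.null(genome)) {
    validate_genome(genome)
    m <- match(regions$chrom, genome$chrom)
    if (anyNA(m)) {
      stopf("region chromosome(s) absent from genome build: %s",
            paste(unique(regions$chrom[is.na(m)]), collapse = ", "))
    }
    if (any(regions$end > genome$length[m])) {
      stopf("region exceeds chromosome length")
    }
  }
  if (require_disjoint) {
    for (idx in split(seq_len(nrow(regions)), regions$chrom)) {
      if (length(idx) < 2) next
      o <- idx[order(regions$start[idx])]
      if (any(regions$start[o][-1] < regions$end[o][-length(o)])) {
        stopf("regions overlap on chromosome %s; merge them first",
              regions$chrom[o[1]])
      }
    }
  }
  invisible(regions)
}

GENE_CATEGORIES <- c("cancer", "dna_repair", "immune", "non_neoplastic",
                     "unknown_function")
REGION_CATEGORIES <- c(GENE_CATEGORIES, "gene_desert")
GENOTYPES <- c("wt", "het", "null")

validate_cohort <- function(cohort) {
  assert_columns(cohort, c("id", "genotype", "time_weeks", "event"), "cohort")
  if (nrow(cohort) == 0) stopf("cohort is empty")
  if (!all(cohort$genotype %in% GENOTYPES)) {
    stopf("genotype must be one of: %s", paste(GENOTYPES, collapse = ", "))
  }
  if (!is.numeric(cohort$time_weeks) || anyNA(cohort$time_weeks) ||
      any(cohort$time_weeks <= 0)) {
    stopf("event/censoring times must be positive")
  }
  if (!is.logical(cohort$event) || anyNA(cohort$event)) {
    stopf("`event` must be logical with no missing values")
  }
  invisible(cohort)
}
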