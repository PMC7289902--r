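#' Define a strain-contrast design
#'
#' The scan predicate on a strain distribution pattern: all strains of the
#' shared group must carry one identical haplotype label, and every
#' "distinct" strain must carry a label different from the shared one (and,
#' by default, different from each other's). This encodes the classic
#' phenotype-contrast design where a trait separates a group of resistant
#' strains from individual susceptible strains.
#'
#' @param shared Character vector (length >= 1) of strains required to share
#'   one haplotype.
#' @param distinct Character vector (length >= 1) of strains each required
#'   to carry a haplotype different from the shared one.
#' @param require_pairwise_distinct When `TRUE` (default) the distinct
#'   strains must also differ from one another; `FALSE` relaxes the
#'   predicate so that two susceptible strains may share a haplotype as long
#'   as it differs from the shared group's.
#' @param missing_as_wildcard A base where a designated strain has no
#'   haplotype call never qualifies under the default (`FALSE`). When
#'   `TRUE`, a missing call is treated as compatible with any requirement
#'   (the shared group still needs at least one non-missing witness label).
#' @return An object of class `contrast_design`.
#' @examples
#' contrast_design(
#'   shared = c("C57BL/6J", "FVB/NJ", "C3H/HeJ", "129S1/SvImJ"),
#'   distinct = c("SJL/J", "BALB/cJ")
#' )
#' @export
contrast_design <- function(shared, distinct,
                            require_pairwise_distinct = TRUE,
                            missing_as_wildcard = FALSE) {
  shared <- as.character(shared)
  distinct <- as.character(distinct)
  if (length(shared) < 1 || length(distinct) < 1) {
    stopf("both `shared` and `distinct` must name at least one strain")
  }
  if (anyDuplicated(c(shared, distinct))) {
    stopf("`shared` and `distinct` must be disjoint lists of unique strains")
  }
  structure(
    list(shared = shared, distinct = distinct,
         require_pairwise_distinct = isTRUE(require_pairwise_distinct),
         missing_as_wildcard = isTRUE(missing_as_wildcard)),
    class = "contrast_design"
  )
}

#' @export
print.contrast_design <- function(x, ...) {
  cat("contrast design:\n")
  cat("  shared  :", paste(x$shared, collapse = ", "), "\n")
  cat("  distinct:", paste(x$distinct, collapse = ", "),
      if (x$require_pairwise_distinct) "(pairwise distinct)" else "", "\n")
  if (x$missing_as_wildcard) cat("  missing calls treated as wildcards\n")
  invisible(x)
}

#' Segment the genome into intervals of constant joint haplotype assignment
#'
#' Takes the union of all strains' block boundaries per chromosome and cuts
#' the genome at every one of them, producing maximal segments within which
#' each strain's label (or its absence) is constant. Segments tile exactly
#' the bases covered by at least one strain; spans covered by no strain are
#' omitted.
#'
#' @param panel Haplotype panel data.frame (see [read_haplotype_table()]).
#' @param genome Genome build data.frame; every block must lie on a build
#'   chromosome and within its length.
#' @return A list with elements `segments` (data.frame `chrom`, `start`,
#'   `end`) and `labels` (character matrix, one row per segment, one column
#'   per strain, `NA` where the strain has no call).
#' @export
segment_joint <- function(panel, genome) {
  validate_genome(genome)
  validate_panel(panel, genome = genome, strict = TRUE)
  strains <- unique(panel$strain)
  chroms <- genome$chrom[genome$chrom %in% unique(panel$chrom)]

  seg_list <- vector("list", length(chroms))
  lab_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    on_chrom <- panel[panel$chrom == chrom, , drop = FALSE]
    bp <- sort(unique(c(on_chrom$start, on_chrom$end)))
    starts <- bp[-length(bp)]
    ends <- bp[-1]
    labs <- matrix(NA_character_, nrow = length(starts),
                   ncol = length(strains),
                   dimnames = list(NULL, strains))
    for (s in strains) {
      blk <- on_chrom[on_chrom$strain == s, , drop = FALSE]
      if (nrow(blk) == 0) next
      blk <- blk[order(blk$start), , drop = FALSE]
      idx <- findInterval(starts, blk$start)
      hit <- idx >= 1L & starts < blk$end[pmax(idx, 1L)]
      labs[hit, s] <- blk$haplotype[idx[hit]]
    }
    covered <- rowSums(!is.na(labs)) > 0
    seg_list[[ci]] <- data.frame(chrom = chrom, start = starts[covered],
                                 end = ends[covered],
                                 stringsAsFactors = FALSE)
    lab_list[[ci]] <- labs[covered, , drop = FALSE]
  }
  segments <- do.call(rbind, seg_list)
  if (is.null(segments)) {
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  }
  rownames(segments) <- NULL
  labels <- do.call(rbind, lab_list)
  if (is.null(labels)) {
    labels <- matrix(NA_character_, nrow = 0, ncol = length(strains),
                     dimnames = list(NULL, strains))
  }
  list(segments = segments, labels = labels, strains = strains)
}

#' Test a strain distribution pattern against a contrast design
#'
#' @param labels Named character vector mapping strain name to haplotype
#'   label, with `NA` for a missing call. Every strain named in the design
#'   must be present.
#' @param design A [contrast_design()].
#' @return `TRUE` iff the pattern satisfies the design predicate.
#' @examples
#' d <- contrast_design(shared = c("s1", "s2"), distinct = c("s3", "s4"))
#' matches_pattern(c(s1 = "a", s2 = "a", s3 = "b", s4 = "c"), d)  # TRUE
#' matches_pattern(c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"), d)  # FALSE
#' @export
matches_pattern <- function(labels, design) {
  stopifnot(inherits(design, "contrast_design"))
  need <- c(design$shared, design$distinct)
  if (!all(need %in% names(labels))) {
    stopf("pattern lacks strain(s) named in the design: %s",
          paste(setdiff(need, names(labels)), collapse = ", "))
  }
  m <- matrix(labels[need], nrow = 1, dimnames = list(NULL, need))
  match_pattern_matrix(m, design)[1]
}

# Vectorised predicate over a segment-by-strain label matrix. Returns one
# logical per row.
match_pattern_matrix <- function(labels, design) {
  if (!all(c(design$shared, design$distinct) %in% colnames(labels))) {
    stopf("label matrix lacks strain(s) named in the design: %s",
          paste(setdiff(c(design$shared, design$distinct), colnames(labels)),
                collapse = ", "))
  }
  sh <- labels[, design$shared, drop = FALSE]
  di <- labels[, design$distinct, drop = FALSE]
  n <- nrow(labels)
  if (n == 0) return(logical(0))

  if (!design$missing_as_wildcard) {
    complete <- rowSums(is.na(sh)) == 0 & rowSums(is.na(di)) == 0
    h0 <- sh[, 1]
    shared_ok <- complete & rowSums(sh == h0, na.rm = TRUE) == ncol(sh)
    distinct_ok <- rowSums(di == h0, na.rm = TRUE) == 0
    ok <- shared_ok & distinct_ok
    if (design$require_pairwise_distinct && ncol(di) > 1) {
      pw <- vapply(seq_len(n), function(i) {
        v <- di[i, ]
        !anyDuplicated(v)
      }, logical(1))
      ok <- ok & pw
    }
    return(ok)
  }

  # wildcard semantics: NA is compatible with anything, but the shared group
  # needs at least one non-missing witness to define the shared label h0
  vapply(seq_len(n), function(i) {
    sv <- sh[i, ]
    dv <- di[i, ]
    known <- sv[!is.na(sv)]
    if (length(known) == 0) return(FALSE)
    if (length(unique(known)) != 1) return(FALSE)
    h0 <- known[1]
    dk <- dv[!is.na(dv)]
    if (any(dk == h0)) return(FALSE)
    if (design$require_pairwise_distinct && anyDuplicated(dk) > 0) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Scan a haplotype panel for regions matching a strain-contrast design
#'
#' Segments the genome jointly over all strains ([segment_joint()]),
#' evaluates the design predicate on every segment, and merges runs of
#' qualifying segments into maximal candidate regions. Book-ended qualifying
#' segments are merged even when their witnessed label assignments differ,
#' since every contained base satisfies the predicate; `merge_gap` allows
#' bridging short non-qualifying or uncovered gaps (default 0: only abutting
#' segments merge).
#'
#' @inheritParams segment_joint
#' @param design A [contrast_design()]; every named strain must be in the
#'   panel. Panel strains named in neither design list are unconstrained.
#' @param merge_gap Maximum gap in bp between qualifying segments that is
#'   still bridged when merging (default 0).
#' @return A list with `regions` (data.frame `chrom`, `start`, `end`,
#'   `length`, `name`, `witness`) and `summary` (one-row data.frame from
#'   [genome_fraction()]).
#' @export
scan_contrast <- function(panel, design, genome, merge_gap = 0) {
  stopifnot(inherits(design, "contrast_design"))
  if (!is.numeric(merge_gap) || merge_gap < 0) {
    stopf("`merge_gap` must be a non-negative number of bp")
  }
  absent <- setdiff(c(design$shared, design$distinct), unique(panel$strain))
  if (length(absent) > 0) {
    stopf("design names strain(s) absent from the panel: %s",
          paste(absent, collapse = ", "))
  }
  js <- segment_joint(panel, genome)
  ok <- match_pattern_matrix(js$labels, design)

  seg <- js$segments[ok, , drop = FALSE]
  lab <- js$labels[ok, , drop = FALSE]
  regions <- merge_qualifying(seg, lab, design, genome, merge_gap)
  list(regions = regions, summary = genome_fraction(regions, genome))
}

merge_qualifying <- function(seg, lab, design, genome, merge_gap) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      name = character(), witness = character(),
                      stringsAsFactors = FALSE)
  if (nrow(seg) == 0) return(empty)
  ord <- order(match(seg$chrom, genome$chrom), seg$start)
  seg <- seg[ord, , drop = FALSE]
  lab <- lab[ord, , drop = FALSE]
  new_run <- c(TRUE, seg$chrom[-1] != seg$chrom[-nrow(seg)] |
                 seg$start[-1] - seg$end[-nrow(seg)] > merge_gap)
  run <- cumsum(new_run)
  first <- which(new_run)
  witness <- vapply(first, function(i) {
    sl <- lab[i, design$shared[1]]
    dl <- lab[i, design$distinct]
    paste(c(sprintf("shared=%s", sl),
            sprintf("%s=%s", design$distinct, dl)), collapse = ";")
  }, character(1))
  regions <- data.frame(
    chrom = seg$chrom[first],
    start = seg$start[first],
    end = tapply(seg$end, run, max)[as.character(seq_along(first))],
    stringsAsFactors = FALSE
  )
  regions$length <- regions$end - regions$start
  regions$name <- sprintf("region_%04d", seq_len(nrow(regions)))
  regions$witness <- witness
  rownames(regions) <- NULL
  regions
}

#' Genome-fraction summary of a region set
#'
#' Computes the total qualifying span and its fraction of the genome — the
#' headline statistic of a contrast scan (e.g. "0.207% of the genome,
#' ~5.45 Mb"). Regions must be disjoint and within genome bounds.
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end`.
#' @param genome Genome build data.frame.
#' @return A one-row data.frame with columns `regions`, `total_bp`,
#'   `genome_bp`, `fraction`, `percent`.
#' @export
genome_fraction <- function(regions, genome) {
  validate_regions(regions, genome = genome, require_disjoint = TRUE)
  total <- if (nrow(regions) == 0) 0 else
    sum(as.double(regions$end) - as.double(regions$start))
  gl <- genome_length(genome)
  data.frame(regions = nrow(regions), total_bp = total, genome_bp = gl,
             fraction = total / gl, percent = 100 * total / gl)
}
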