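#' Intersect candidate regions with gene annotations
#'
#' A gene overlaps a region iff their 0-based half-open intervals share at
#' least one base; strand is ignored. Each region's genes are listed sorted
#' by gene start. `flank` symmetrically extends each region before the
#' overlap test (clipped at 0), for users who want promoter-proximal genes
#' counted; the default of 0 matches a strict intersection.
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end` (plus any
#'   others, which are carried through).
#' @param genes Gene data.frame from [read_genes()] or [simulate_genes()].
#' @param flank Non-negative bp extension applied to both region ends before
#'   intersection (default 0).
#' @return The `regions` data.frame with two added columns: `n_genes` and
#'   `genes` (a list column of character vectors of gene names).
#' @export
intersect_genes <- function(regions, genes, flank = 0) {
  validate_regions(regions, require_disjoint = FALSE)
  assert_columns(genes, c("name", "chrom", "start", "end"), "genes")
  if (!is.numeric(flank) || length(flank) != 1 || flank < 0) {
    stopf("`flank` must be a single non-negative number of bp")
  }
  out <- regions
  if (nrow(regions) == 0) {
    out$n_genes <- integer(0)
    out$genes <- list()
    return(out)
  }
  hits_per_region <- rep(list(character(0)), nrow(regions))
  if (nrow(genes) > 0) {
    # half-open [s, e) to 1-based closed [s + 1, e] for IRanges
    q <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(pmax(regions$start - flank, 0) + 1,
                       regions$end + flank)
    )
    s <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1, genes$end)
    )
    ov <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh)) {
      g <- sh[qh == i]
      g <- g[order(genes$start[g], genes$name[g])]
      hits_per_region[[i]] <- genes$name[g]
    }
  }
  out$n_genes <- lengths(hits_per_region)
  out$genes <- hits_per_region
  out
}

#' Classify annotated regions into functional categories
#'
#' A region overlapping no gene is a `gene_desert`. Otherwise its category
#' is the highest-precedence category among its overlapped genes; genes
#' missing from the map default to `unknown_function`, so an incomplete
#' curation degrades gracefully rather than erroring.
#'
#' @param annotated Output of [intersect_genes()].
#' @param category_map Data.frame with columns `gene`, `category` (see
#'   [read_category_map()]), or a named character vector.
#' @param precedence Order in which gene-level categories win when a region
#'   overlaps genes of several; defaults to relevance to a tumor phenotype:
#'   cancer, then DNA repair, then immune, then non-neoplastic, then unknown
#'   function.
#' @return `annotated` with an added `category` column.
#' @export
classify_regions <- function(annotated, category_map,
                             precedence = GENE_CATEGORIES) {
  assert_columns(annotated, c("n_genes", "genes"), "annotated")
  if (is.data.frame(category_map)) {
    assert_columns(category_map, c("gene", "category"), "category_map")
    map <- stats::setNames(category_map$category, category_map$gene)
  } else {
    map <- category_map
  }
  if (!setequal(precedence, GENE_CATEGORIES)) {
    stopf("`precedence` must be a permutation of: %s",
          paste(GENE_CATEGORIES, collapse = ", "))
  }
  bad <- setdiff(unique(unname(map)), GENE_CATEGORIES)
  if (length(bad) > 0) {
    stopf("unknown gene category token(s): %s", paste(bad, collapse = ", "))
  }
  annotated$category <- vapply(annotated$genes, function(gs) {
    if (length(gs) == 0) return("gene_desert")
    cats <- unname(map[gs])
    cats[is.na(cats)] <- "unknown_function"
    precedence[min(match(cats, precedence))]
  }, character(1))
  annotated
}

#' Annotate and classify candidate regions in one step
#'
#' Convenience wrapper: [intersect_genes()] then [classify_regions()].
#'
#' @inheritParams intersect_genes
#' @inheritParams classify_regions
#' @export
annotate_regions <- function(regions, genes, category_map, flank = 0,
                             precedence = GENE_CATEGORIES) {
  classify_regions(intersect_genes(regions, genes, flank = flank),
                   category_map, precedence = precedence)
}

#' Summarise region categories
#'
#' Tabulates classified regions over the six region categories (the five
#' gene-level ones plus `gene_desert`). With `drop_uninformative = TRUE`,
#' `unknown_function` and `gene_desert` regions are removed before
#' proportions are computed — the "reanalysis after removing deserts and
#' unknowns" view of the same data. The dropped variant is therefore always
#' the restriction-and-renormalisation of the full one.
#'
#' @param annotated Output of [classify_regions()] (needs a `category`
#'   column), or a bare character vector of categories.
#' @param drop_uninformative Remove `unknown_function` and `gene_desert`
#'   before computing proportions.
#' @return A data.frame with columns `category`, `count`, `proportion`, and
#'   attributes `drop_uninformative` (flag) and `total` (regions counted).
#'   When every region is dropped, proportions are `NA` and the `total`
#'   attribute is 0.
#' @export
summarize_categories <- function(annotated, drop_uninformative = FALSE) {
  cats <- if (is.character(annotated)) annotated else {
    assert_columns(annotated, "category", "annotated")
    annotated$category
  }
  bad <- setdiff(unique(cats), REGION_CATEGORIES)
  if (length(bad) > 0) {
    stopf("unknown region category token(s): %s", paste(bad, collapse = ", "))
  }
  keep <- if (drop_uninformative) {
    setdiff(REGION_CATEGORIES, c("unknown_function", "gene_desert"))
  } else {
    REGION_CATEGORIES
  }
  cats <- cats[cats %in% keep]
  count <- as.integer(table(factor(cats, levels = keep)))
  total <- sum(count)
  out <- data.frame(category = keep, count = count,
                    proportion = if (total > 0) count / total else
                      rep(NA_real_, length(count)),
                    stringsAsFactors = FALSE)
  attr(out, "drop_uninformative") <- drop_uninformative
  attr(out, "total") <- total
  out
}
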