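#' Read a per-strain haplotype block table
#'
#' Reads a tab-separated table of haplotype blocks of the kind exported from
#' genome-wide strain haplotype resources (e.g. the Mouse Phylogeny Viewer),
#' one row per block. The file must carry a header line naming the columns
#' `strain`, `chrom`, `start`, `end`, `haplotype`. Coordinates are 0-based
#' half-open; haplotype labels are opaque strings compared by exact equality.
#'
#' Blocks are returned sorted by strain, chromosome and start. Within a
#' strain and chromosome, overlapping blocks are rejected; gaps between
#' blocks are legitimate missing data.
#'
#' @param path Path to a tab-separated block table.
#' @param genome Optional genome build (`data.frame` with columns `chrom`,
#'   `length`) used for bounds checking.
#' @param strict When `TRUE` (default) and `genome` is supplied, chromosome
#'   names absent from the build are an error; chromosome names are matched
#'   verbatim, with no "chr" normalisation.
#' @return A data.frame with columns `strain`, `chrom`, `start`, `end`,
#'   `haplotype` — the haplotype panel format consumed by [segment_joint()]
#'   and [scan_contrast()].
#' @export
read_haplotype_table <- function(path, genome = NULL, strict = TRUE) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) stopf("'%s' is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  required <- c("strain", "chrom", "start", "end", "haplotype")
  if (!all(required %in% header)) {
    stopf("'%s' header must name columns: %s", path,
          paste(required, collapse = ", "))
  }
  col <- match(required, header)
  body <- fields[-1]
  nfield <- lengths(body)
  bad <- which(nfield < length(header))
  if (length(bad) > 0) {
    stopf("malformed row at line %d of '%s': expected %d fields, found %d",
          bad[1] + 1L, path, length(header), nfield[bad[1]])
  }
  get <- function(i) vapply(body, `[[`, character(1), col[i])
  start <- suppressWarnings(as.numeric(get(3)))
  end <- suppressWarnings(as.numeric(get(4)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stopf("non-numeric coordinate at line %d of '%s'", bad[1] + 1L, path)
  }
  panel <- data.frame(strain = get(1), chrom = get(2), start = start,
                      end = end, haplotype = get(5),
                      stringsAsFactors = FALSE)
  panel <- panel[order(panel$strain, panel$chrom, panel$start), ,
                 drop = FALSE]
  rownames(panel) <- NULL
  validate_panel(panel, genome = genome, strict = strict)
  panel
}

#' Write a haplotype panel to a tab-separated block table
#'
#' Inverse of [read_haplotype_table()]; the round trip is lossless.
#'
#' @param panel Haplotype panel data.frame.
#' @param path Output path.
#' @export
write_haplotype_table <- function(panel, path) {
  validate_panel(panel)
  cols <- c("strain", "chrom", "start", "end", "haplotype")
  utils::write.table(panel[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes table into a genome build
#'
#' Accepts the standard two-column `chrom.sizes` format
#' (`name<TAB>length`, no header). Chromosome order in the file defines the
#' karyotype order used for output sorting.
#'
#' @param path Path to a chrom.sizes file.
#' @return A data.frame with columns `chrom` and `length`.
#' @export
read_genome <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) stopf("'%s' defines an empty genome", path)
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 2)) {
    stopf("line %d of '%s' lacks a length field",
          which(lengths(fields) < 2)[1], path)
  }
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  if (anyNA(len)) {
    stopf("non-numeric chromosome length at line %d of '%s'",
          which(is.na(len))[1], path)
  }
  genome <- data.frame(chrom = vapply(fields, `[[`, character(1), 1),
                       length = len, stringsAsFactors = FALSE)
  validate_genome(genome)
  genome
}

#' @rdname read_genome
#' @param genome Genome build to write.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  utils::write.table(genome[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene annotations from BED or GFF3
#'
#' All coordinates are converted to the package's internal convention:
#' 0-based half-open. BED files already use it; GFF3 1-based inclusive
#' coordinates are shifted on read. For GFF3 input only features of type
#' `gene` are kept, and the number of skipped features is reported with a
#' message.
#'
#' @param path Path to a BED4/BED6 or GFF3 file.
#' @param format One of `"auto"` (by extension), `"bed"`, `"gff3"`.
#' @return A data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand` (one of `+`, `-`, `*`).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) {
      "gff3"
    } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
      "bed"
    } else {
      stopf("cannot infer format of '%s'; pass format = 'bed' or 'gff3'", path)
    }
  }
  gr <- if (format == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    g <- rtracklayer::import(path, format = "GFF3")
    is_gene <- !is.na(g$type) & as.character(g$type) == "gene"
    if (sum(!is_gene) > 0) {
      message(sprintf("read_genes: skipped %d non-gene feature(s) in '%s'",
                      sum(!is_gene), path))
    }
    g <- g[is_gene]
    # prefer Name, fall back to ID
    nm <- if (!is.null(g$Name)) as.character(g$Name) else NA_character_
    if (!is.null(g$ID)) nm[is.na(nm)] <- as.character(g$ID)[is.na(nm)]
    g$name <- nm
    g
  }
  genes <- data.frame(
    name = if (is.null(gr$name)) NA_character_ else as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (anyNA(genes$name) || any(!nzchar(genes$name))) {
    stopf("'%s' contains gene records without a name", path)
  }
  if (any(genes$start >= genes$end)) {
    stopf("'%s' contains a gene record with start >= end after coordinate conversion",
          path)
  }
  genes
}

#' Read and write candidate regions as BED
#'
#' Regions are written as BED4 (0-based half-open, name column carrying the
#' region id); `read_regions(write_regions(x))` returns the same intervals.
#' When a genome build is supplied, a region running past its chromosome end
#' is refused.
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path Output (or input) path.
#' @param genome Optional genome build for bounds checking.
#' @export
write_regions <- function(regions, path, genome = NULL) {
  validate_regions(regions, genome = genome, require_disjoint = FALSE)
  name <- if ("name" %in% names(regions)) regions$name else
    sprintf("region_%04d", seq_len(nrow(regions)))
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stopf("line %d of '%s' has fewer than 3 BED fields",
          which(lengths(fields) < 3)[1], path)
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  regions <- data.frame(
    chrom = f(1),
    start = as.numeric(f(2)),
    end = as.numeric(f(3)),
    name = if (all(lengths(fields) >= 4)) f(4) else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_regions(regions, require_disjoint = FALSE)
  regions
}

#' Read a gene-to-category map
#'
#' Tab-separated, header `gene<TAB>category`. Categories must be one of the
#' five gene-level tokens: `cancer`, `dna_repair`, `immune`,
#' `non_neoplastic`, `unknown_function` (`gene_desert` is a region-level
#' category assigned when a region overlaps no gene, so it may not appear
#' here).
#'
#' @param path Path to the map.
#' @return A data.frame with columns `gene` and `category`.
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  assert_columns(df, c("gene", "category"), "category map")
  bad <- setdiff(unique(df$category), GENE_CATEGORIES)
  if (length(bad) > 0) {
    stopf("unknown gene category token(s) in '%s': %s", path,
          paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$gene)) {
    stopf("duplicate gene name(s) in category map '%s'", path)
  }
  df
}

#' Read and write mouse cohort tables
#'
#' Tab-separated with header `id genotype time_weeks event diagnosis`;
#' `event` is `TRUE`/`FALSE` (or 1/0), `diagnosis` is a free label with
#' empty, `"."` or `"NA"` meaning no recorded diagnosis. Censored animals
#' carry their last observation time (study-end termination at 35 weeks in
#' the emulated design).
#'
#' @param path Path to the cohort table.
#' @return A data.frame with columns `id`, `genotype`, `time_weeks`,
#'   `event` (logical), `diagnosis` (`NA` when none).
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", "", "."))
  assert_columns(df, c("id", "genotype", "time_weeks", "event"), "cohort")
  if (!"diagnosis" %in% names(df)) df$diagnosis <- NA_character_
  df$diagnosis <- as.character(df$diagnosis)
  if (is.numeric(df$event)) df$event <- df$event != 0
  df$event <- as.logical(df$event)
  df$id <- as.character(df$id)
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[, c("id", "genotype", "time_weeks", "event", "diagnosis")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a summary table as TSV
#'
#' Plain tab-separated output with a header row, used for scan and category
#' summaries.
#'
#' @param summary A data.frame.
#' @param path Output path.
#' @export
write_summary <- function(summary, path) {
  if (!is.data.frame(summary)) stopf("`summary` must be a data.frame")
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}
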