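#' Simulate a panel of mosaic strain genomes
#'
#' Classical laboratory mouse strains descend from a small founder pool, so
#' across most of the genome their variation collapses onto fewer than ten
#' distinct haplotypes. The generator emulates that structure directly at
#' the block level: each chromosome is partitioned into blocks whose lengths
#' are geometric with mean `mean_block_bp` (a memoryless block process — the
#' analysis consumes only block labels, so coalescent realism is not
#' needed), a hidden template track draws a founder label uniformly per
#' block, and each strain in `shared_strains` copies the template's label
#' with probability `shared_prob` per block, otherwise (and always, for the
#' remaining strains) drawing an independent uniform founder label.
#'
#' The same block partition is used for all strains of a chromosome,
#' mirroring panel exports where blocks are reported on a common grid.
#'
#' @param genome Genome build data.frame.
#' @param strains Character vector of strain names.
#' @param n_founders Number of founder haplotype labels (default 8, within
#'   the "fewer than 10" regime of classical strains).
#' @param mean_block_bp Mean block length in bp (default 200 kb, the scale
#'   of classical-strain haplotype blocks).
#' @param shared_strains Strains with elevated template sharing (default
#'   none).
#' @param shared_prob Per-block probability that a shared strain copies the
#'   template label (default 0.9).
#' @param missing_prob Per strain-block probability of dropping the call,
#'   producing a coverage gap (default 0).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return A haplotype panel data.frame (`strain`, `chrom`, `start`, `end`,
#'   `haplotype`).
#' @export
simulate_panel <- function(genome, strains, n_founders = 8,
                           mean_block_bp = 2e5, shared_strains = character(),
                           shared_prob = 0.9, missing_prob = 0,
                           seed = NULL) {
  validate_genome(genome)
  strains <- as.character(strains)
  if (length(strains) < 1 || anyDuplicated(strains)) {
    stopf("`strains` must be unique names, at least one")
  }
  if (!is_count(n_founders) || n_founders < 2) {
    stopf("`n_founders` must be an integer >= 2")
  }
  if (!is.numeric(mean_block_bp) || mean_block_bp < 1) {
    stopf("`mean_block_bp` must be >= 1")
  }
  if (shared_prob < 0 || shared_prob > 1 || missing_prob < 0 ||
      missing_prob > 1) {
    stopf("`shared_prob` and `missing_prob` must lie in [0, 1]")
  }
  if (!all(shared_strains %in% strains)) {
    stopf("`shared_strains` must be a subset of `strains`")
  }
  founders <- sprintf("h%d", seq_len(n_founders))

  with_seed(module_seed(seed, "panel"), {
    per_chrom <- lapply(seq_len(nrow(genome)), function(ci) {
      clen <- genome$length[ci]
      starts <- block_partition(clen, mean_block_bp)
      ends <- c(starts[-1], clen)
      nb <- length(starts)
      template <- sample(founders, nb, replace = TRUE)
      rows <- lapply(strains, function(s) {
        copy <- if (s %in% shared_strains) {
          stats::runif(nb) < shared_prob
        } else {
          rep(FALSE, nb)
        }
        lab <- ifelse(copy, template, sample(founders, nb, replace = TRUE))
        keep <- if (missing_prob > 0) stats::runif(nb) >= missing_prob else
          rep(TRUE, nb)
        data.frame(strain = s, chrom = genome$chrom[ci],
                   start = starts[keep], end = ends[keep],
                   haplotype = lab[keep], stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    panel <- do.call(rbind, per_chrom)
    rownames(panel) <- NULL
    validate_panel(panel, genome = genome)
    panel
  })
}

# Block start positions partitioning [0, clen) with geometric lengths of
# mean `mean_bp` (each length >= 1).
block_partition <- function(clen, mean_bp) {
  p <- min(1, 1 / mean_bp)
  lens <- numeric(0)
  total <- 0
  while (total < clen) {
    k <- max(64, ceiling((clen - total) / mean_bp * 1.5))
    draw <- stats::rgeom(k, p) + 1
    lens <- c(lens, draw)
    total <- total + sum(draw)
  }
  cum <- cumsum(lens)
  starts <- c(0, cum[cum < clen])
  starts
}

#' Plant contrast-qualifying windows into a panel
#'
#' Overwrites labels inside each window so that every base satisfies the
#' design predicate (the shared group receives one planted label, each
#' distinct strain its own different label), and forces the immediately
#' flanking `flank_bp` span to a single label common to all strains — a
#' pattern that can never qualify — so a planted window cannot silently
#' extend into qualifying background. Everything else is untouched.
#'
#' @param panel Haplotype panel data.frame.
#' @param design A [contrast_design()].
#' @param windows Data.frame with columns `chrom`, `start`, `end`; pairwise
#'   disjoint and within genome bounds.
#' @param genome Genome build data.frame.
#' @param flank_bp Width of the scrubbed flank on each side (default
#'   10 kb), clipped at chromosome ends.
#' @return The modified panel.
#' @export
plant_regions <- function(panel, design, windows, genome, flank_bp = 1e4) {
  stopifnot(inherits(design, "contrast_design"))
  validate_panel(panel, genome = genome)
  validate_regions(windows, genome = genome, require_disjoint = TRUE)
  if (!is.numeric(flank_bp) || flank_bp < 0) {
    stopf("`flank_bp` must be non-negative")
  }
  absent <- setdiff(unique(windows$chrom), unique(panel$chrom))
  if (length(absent) > 0) {
    stopf("window on chromosome(s) with no panel coverage: %s",
          paste(absent, collapse = ", "))
  }
  strains <- unique(panel$strain)
  miss <- setdiff(c(design$shared, design$distinct), strains)
  if (length(miss) > 0) {
    stopf("design names strain(s) absent from the panel: %s",
          paste(miss, collapse = ", "))
  }
  # separation of planted windows must leave room for the failing flank
  for (chrom in unique(windows$chrom)) {
    w <- windows[windows$chrom == chrom, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start[-1] - w$end[-nrow(w)] < 2 * flank_bp)) {
      stopf("planted windows on %s are closer than 2 * flank_bp", chrom)
    }
  }

  shared_label <- "planted_shared"
  distinct_labels <- sprintf("planted_distinct_%d",
                             seq_along(design$distinct))
  background_label <- "planted_flank"

  for (i in seq_len(nrow(windows))) {
    chrom <- windows$chrom[i]
    clen <- genome$length[match(chrom, genome$chrom)]
    ws <- windows$start[i]
    we <- windows$end[i]
    fs <- max(0, ws - flank_bp)
    fe <- min(clen, we + flank_bp)
    for (s in strains) {
      lab <- if (s %in% design$shared) {
        shared_label
      } else if (s %in% design$distinct) {
        distinct_labels[match(s, design$distinct)]
      } else {
        background_label
      }
      add <- data.frame(
        strain = s, chrom = chrom,
        start = c(fs, ws, we), end = c(ws, we, fe),
        haplotype = c(background_label, lab, background_label),
        stringsAsFactors = FALSE
      )
      add <- add[add$start < add$end, , drop = FALSE]
      panel <- overwrite_span(panel, s, chrom, fs, fe, add)
    }
  }
  panel <- panel[order(panel$strain, panel$chrom, panel$start), ,
                 drop = FALSE]
  rownames(panel) <- NULL
  validate_panel(panel, genome = genome)
  panel
}

# Replace a strain's blocks on [from, to) of one chromosome with `add`,
# trimming any overlapping existing blocks to the outside of the span.
overwrite_span <- function(panel, strain, chrom, from, to, add) {
  sel <- panel$strain == strain & panel$chrom == chrom
  keep <- panel[!sel, , drop = FALSE]
  blk <- panel[sel, , drop = FALSE]
  pieces <- list()
  for (j in seq_len(nrow(blk))) {
    b <- blk[j, , drop = FALSE]
    if (b$end <= from || b$start >= to) {
      pieces[[length(pieces) + 1]] <- b
      next
    }
    if (b$start < from) {
      left <- b
      left$end <- from
      pieces[[length(pieces) + 1]] <- left
    }
    if (b$end > to) {
      right <- b
      right$start <- to
      pieces[[length(pieces) + 1]] <- right
    }
  }
  out <- rbind(keep, do.call(rbind, pieces), add)
  out
}

#' Simulate a mouse cohort with genotype-specific survival and diagnoses
#'
#' Each animal first draws an outcome from its genotype's diagnosis
#' distribution (probabilities summing to at most 1; the remainder are
#' tumor-free survivors censored at the study horizon). Animals with an
#' event draw a log-normal event time parameterised by its median; times
#' beyond the horizon are censored at the horizon. The defaults reproduce
#' the emulated study design: wild-type (n = 6) and heterozygous (n = 14)
#' littermates of homozygous null animals (n = 5), a 12-week median time to
#' death for nulls with a 40/40/20% split of thymic lymphoma, testicular
#' teratoma and no visible tumor, heterozygotes with 15% sarcoma and 7%
#' tumor-free death, and termination of all survivors at 35 weeks.
#'
#' @param sizes Named integer vector of cohort sizes; names from
#'   `c("wt", "het", "null")`.
#' @param median_weeks Named vector of median event times (weeks) per
#'   genotype, for animals that have an event.
#' @param sigma Log-scale standard deviation of event times (default 0.3).
#' @param event_probs Named list, one element per genotype: a named
#'   probability vector over diagnosis labels (may be empty; sums to <= 1).
#' @param horizon Study end in weeks (default 35); survivors are censored
#'   here.
#' @param seed Integer seed for reproducibility.
#' @return A cohort data.frame (`id`, `genotype`, `time_weeks`, `event`,
#'   `diagnosis`).
#' @export
simulate_cohort <- function(sizes = c(wt = 6, het = 14, null = 5),
                            median_weeks = c(wt = 12, het = 20, null = 12),
                            sigma = 0.3,
                            event_probs = list(
                              wt = c(),
                              het = c(sarcoma = 0.15, none = 0.07),
                              null = c(thymic_lymphoma = 0.4,
                                       testicular_teratoma = 0.4,
                                       none = 0.2)
                            ),
                            horizon = 35, seed = NULL) {
  if (is.null(names(sizes)) || !all(names(sizes) %in% GENOTYPES)) {
    stopf("`sizes` must be named with genotypes from: %s",
          paste(GENOTYPES, collapse = ", "))
  }
  if (any(sizes < 0)) stopf("cohort sizes must be >= 0")
  if (!is.numeric(horizon) || horizon <= 0) stopf("`horizon` must be > 0")
  if (!is.numeric(sigma) || sigma < 0) stopf("`sigma` must be >= 0")

  with_seed(module_seed(seed, "cohort"), {
    rows <- lapply(names(sizes), function(g) {
      n <- sizes[[g]]
      if (n == 0) return(NULL)
      probs <- event_probs[[g]]
      if (is.null(probs)) probs <- c()
      if (length(probs) > 0 && (any(probs < 0) || sum(probs) > 1 + 1e-12)) {
        stopf("diagnosis probabilities for '%s' must be >= 0 and sum to <= 1",
              g)
      }
      med <- median_weeks[[g]]
      outcome <- if (length(probs) == 0) {
        rep("__survivor", n)
      } else {
        sample(c(names(probs), "__survivor"), n, replace = TRUE,
               prob = c(probs, max(0, 1 - sum(probs))))
      }
      has_event <- outcome != "__survivor"
      time <- rep(horizon, n)
      if (any(has_event)) {
        if (is.null(med) || is.na(med) || med <= 0) {
          stopf("`median_weeks` must give a positive median for genotype '%s'",
                g)
        }
        time[has_event] <- stats::rlnorm(sum(has_event),
                                         meanlog = log(med), sdlog = sigma)
      }
      late <- has_event & time >= horizon
      time[late] <- horizon
      has_event[late] <- FALSE
      data.frame(
        id = sprintf("%s_%03d", g, seq_len(n)),
        genotype = g,
        time_weeks = time,
        event = has_event,
        diagnosis = ifelse(has_event, outcome, NA_character_),
        stringsAsFactors = FALSE
      )
    })
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    validate_cohort(cohort)
    cohort
  })
}

#' Simulate non-overlapping gene annotations and a category map
#'
#' Places `n_genes` non-overlapping genes uniformly on the genome (lengths
#' uniform between 0.5x and 1.5x `gene_bp`) and draws each gene's category
#' from `category_mix`.
#'
#' @param genome Genome build data.frame.
#' @param n_genes Number of genes to place.
#' @param category_mix Named probability vector over the five gene-level
#'   categories (default uniform).
#' @param gene_bp Typical gene length in bp (default 10 kb).
#' @param seed Integer seed.
#' @return A list with `genes` (data.frame `name`, `chrom`, `start`, `end`,
#'   `strand`) and `category_map` (data.frame `gene`, `category`).
#' @export
simulate_genes <- function(genome, n_genes,
                           category_mix = stats::setNames(
                             rep(0.2, 5), GENE_CATEGORIES),
                           gene_bp = 1e4, seed = NULL) {
  validate_genome(genome)
  if (!is_count(n_genes)) stopf("`n_genes` must be a non-negative integer")
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% GENE_CATEGORIES) ||
      any(category_mix < 0) || sum(category_mix) <= 0) {
    stopf("`category_mix` must be a non-negative weight vector over: %s",
          paste(GENE_CATEGORIES, collapse = ", "))
  }
  # quick feasibility check before any rejection sampling: the shortest
  # possible gene footprint must fit in the genome
  if (n_genes * 0.5 * gene_bp > sum(as.double(genome$length))) {
    stopf("could not place %d non-overlapping genes on this genome", n_genes)
  }
  with_seed(module_seed(seed, "genes"), {
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
    tries <- 0
    max_tries <- min(2e6, max(1000, 200 * n_genes))
    while (nrow(placed) < n_genes) {
      if (tries >= max_tries) {
        stopf("could not place %d non-overlapping genes on this genome",
              n_genes)
      }
      tries <- tries + 1
      len <- max(1, round(stats::runif(1, 0.5, 1.5) * gene_bp))
      ci <- sample.int(nrow(genome), 1, prob = genome$length)
      if (genome$length[ci] <= len) next
      start <- floor(stats::runif(1, 0, genome$length[ci] - len))
      end <- start + len
      same <- placed[placed$chrom == genome$chrom[ci], , drop = FALSE]
      if (nrow(same) > 0 && any(start < same$end & same$start < end)) next
      placed <- rbind(placed, data.frame(chrom = genome$chrom[ci],
                                         start = start, end = end,
                                         stringsAsFactors = FALSE))
    }
    placed <- placed[order(match(placed$chrom, genome$chrom), placed$start), ,
                     drop = FALSE]
    genes <- data.frame(
      name = sprintf("gene_%04d", seq_len(nrow(placed))),
      chrom = placed$chrom, start = placed$start, end = placed$end,
      strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
      stringsAsFactors = FALSE
    )
    category_map <- data.frame(
      gene = genes$name,
      category = if (n_genes > 0) {
        sample(names(category_mix), n_genes, replace = TRUE,
               prob = category_mix)
      } else {
        character(0)
      },
      stringsAsFactors = FALSE
    )
    list(genes = genes, category_map = category_map)
  })
}
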