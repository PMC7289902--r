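# Independent oracles and randomized-instance generators used across the
# suite. These deliberately re-derive results by brute force (per-base
# evaluation, all-pairs overlap, free-amino-acid mass summation) so they
# share no code path with the implementation they check.

# Brute-force contrast scan: label every base of every strain, evaluate the
# design predicate base by base with plain loops, and collect maximal runs
# of qualifying bases. Only usable on toy genomes.
oracle_scan <- function(panel, design, genome) {
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]
    clen <- genome$length[ci]
    strains <- unique(panel$strain)
    base_lab <- matrix(NA_character_, nrow = clen, ncol = length(strains),
                       dimnames = list(NULL, strains))
    on_chrom <- panel[panel$chrom == chrom, , drop = FALSE]
    for (j in seq_len(nrow(on_chrom))) {
      b <- on_chrom[j, ]
      base_lab[(b$start + 1):b$end, b$strain] <- b$haplotype
    }
    ok <- logical(clen)
    for (i in seq_len(clen)) {
      sh <- base_lab[i, design$shared]
      di <- base_lab[i, design$distinct]
      if (!design$missing_as_wildcard) {
        if (any(is.na(sh)) || any(is.na(di))) next
        if (length(unique(sh)) != 1) next
        if (any(di == sh[1])) next
        if (design$require_pairwise_distinct &&
            length(unique(di)) != length(di)) next
        ok[i] <- TRUE
      } else {
        known <- sh[!is.na(sh)]
        if (length(known) == 0 || length(unique(known)) != 1) next
        dk <- di[!is.na(di)]
        if (any(dk == known[1])) next
        if (design$require_pairwise_distinct &&
            length(unique(dk)) != length(dk)) next
        ok[i] <- TRUE
      }
    }
    if (any(ok)) {
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      qual <- which(r$values)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = starts[qual] - 1, end = ends[qual],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# All-pairs quadratic interval overlap (half-open convention).
oracle_intersect <- function(regions, genes) {
  lapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & regions$start[i] < genes$end
    g <- genes[hit, , drop = FALSE]
    g <- g[order(g$start, g$name), , drop = FALSE]
    g$name
  })
}

# Peptide mass from published free-amino-acid average molecular weights,
# subtracting one water per peptide bond.
FREE_AA_MW <- c(
  A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16, E = 147.13,
  Q = 146.15, G = 75.07, H = 155.16, I = 131.17, L = 131.17, K = 146.19,
  M = 149.21, F = 165.19, P = 115.13, S = 105.09, T = 119.12, W = 204.23,
  Y = 181.19, V = 117.15
)
oracle_peptide_mass <- function(residues) {
  if (nchar(residues) == 0) return(18.02)
  aa <- strsplit(residues, "")[[1]]
  sum(FREE_AA_MW[aa]) - (length(aa) - 1) * 18.0153
}

# Random haplotype panel with per-strain independent block boundaries and
# optional coverage gaps — a rougher structure than simulate_panel's shared
# grid, to stress segmentation.
rand_panel <- function(genome, n_strains, n_labels, mean_block,
                       gap_prob = 0.15) {
  strains <- paste0("s", seq_len(n_strains))
  labels <- paste0("L", seq_len(n_labels))
  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    clen <- genome$length[ci]
    for (s in strains) {
      pos <- 0
      while (pos < clen) {
        len <- min(clen - pos, max(1, stats::rgeom(1, 1 / mean_block) + 1))
        if (stats::runif(1) >= gap_prob) {
          rows[[length(rows) + 1]] <- data.frame(
            strain = s, chrom = genome$chrom[ci], start = pos,
            end = pos + len, haplotype = sample(labels, 1),
            stringsAsFactors = FALSE
          )
        }
        pos <- pos + len
      }
    }
  }
  do.call(rbind, rows)
}

# Random toy genome of total size <= max_bp over 1-2 chromosomes.
rand_genome <- function(max_bp = 3000) {
  k <- sample(1:2, 1)
  data.frame(chrom = paste0("chr", seq_len(k)),
             length = sample(ceiling(max_bp / (2 * k)):floor(max_bp / k), k),
             stringsAsFactors = FALSE)
}

expect_same_regions <- function(got, want) {
  got <- got[order(got$chrom, got$start), c("chrom", "start", "end")]
  want <- want[order(want$chrom, want$start), c("chrom", "start", "end")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}

# Small fixed cohort used in several survival tests: deaths at 6, 12, 12,
# 20 weeks and one animal censored at study end.
hand_cohort <- function() {
  data.frame(time_weeks = c(6, 12, 12, 20, 35),
             event = c(TRUE, TRUE, TRUE, TRUE, FALSE))
}
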