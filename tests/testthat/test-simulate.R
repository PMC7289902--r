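toy_genome <- data.frame(chrom = c("chr1", "chr2"),
                         length = c(60000, 40000))
six <- paste0("s", 1:6)
design6 <- contrast_design(shared = six[1:4], distinct = six[5:6])

test_that("panel simulation is seed-deterministic and satisfies track invariants", {
  p1 <- simulate_panel(toy_genome, six, n_founders = 8,
                       mean_block_bp = 2000, seed = 1)
  p2 <- simulate_panel(toy_genome, six, n_founders = 8,
                       mean_block_bp = 2000, seed = 1)
  expect_identical(p1, p2)
  p3 <- simulate_panel(toy_genome, six, n_founders = 8,
                       mean_block_bp = 2000, seed = 2)
  expect_false(identical(p1, p3))

  # validate_panel enforces sortedness/overlap/bounds; run it explicitly
  expect_silent(haploscan:::validate_panel(p1, genome = toy_genome))
  # every strain covers every chromosome fully when missing_prob = 0
  cov <- aggregate(end - start ~ strain + chrom, data = p1, FUN = sum)
  expect_true(all(cov$`end - start` ==
                    toy_genome$length[match(cov$chrom, toy_genome$chrom)]))
  expect_true(all(grepl("^h[1-8]$", p1$haplotype)))

  gappy <- simulate_panel(toy_genome, six, mean_block_bp = 2000,
                          missing_prob = 0.3, seed = 4)
  cov2 <- sum(gappy$end - gappy$start)
  expect_lt(cov2, sum(p1$end - p1$start))
  expect_silent(haploscan:::validate_panel(gappy, genome = toy_genome))
})

test_that("full template sharing across all strains yields zero qualifying bases", {
  p <- simulate_panel(toy_genome, six, mean_block_bp = 2000,
                      shared_strains = six, shared_prob = 1, seed = 9)
  # all tracks identical
  byst <- split(p[, c("chrom", "start", "end", "haplotype")], p$strain)
  for (s in six[-1]) {
    expect_equal(unname(byst[[s]]), unname(byst[[six[1]]]),
                 ignore_attr = TRUE)
  }
  res <- scan_contrast(p, design6, toy_genome)
  expect_equal(nrow(res$regions), 0)
  expect_equal(res$summary$fraction, 0)
})

test_that("planted windows are recovered exactly by the scan", {
  background <- simulate_panel(toy_genome, six, mean_block_bp = 3000,
                               shared_strains = six, shared_prob = 1,
                               seed = 12)
  windows <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(5000, 30000, 10000),
                        end = c(9000, 31000, 15000))
  planted <- plant_regions(background, design6, windows, toy_genome,
                           flank_bp = 2000)
  res <- scan_contrast(planted, design6, toy_genome)
  expect_same_regions(res$regions, windows)
  expect_equal(res$summary$total_bp, sum(windows$end - windows$start))
  expect_equal(res$summary$fraction,
               sum(windows$end - windows$start) / sum(toy_genome$length))

  expect_error(
    plant_regions(background, design6,
                  data.frame(chrom = "chrZ", start = 0, end = 10),
                  toy_genome),
    "absent|chrZ"
  )
})

test_that("cohort simulation is deterministic and respects the horizon", {
  c1 <- simulate_cohort(seed = 5)
  c2 <- simulate_cohort(seed = 5)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 6 + 14 + 5)
  expect_true(all(c1$time_weeks <= 35))
  expect_true(all(c1$time_weeks[!c1$event] == 35 |
                    c1$event[!c1$event] == FALSE))
  # censored animals carry no diagnosis; events carry one
  expect_true(all(is.na(c1$diagnosis[!c1$event])))
  expect_true(all(!is.na(c1$diagnosis[c1$event])))
  # wild types never have events under the default design
  expect_true(all(!c1$event[c1$genotype == "wt"]))

  # degenerate horizon: every event time exceeds it, so all are censored
  all_cens <- simulate_cohort(sizes = c(null = 20),
                              median_weeks = c(null = 1000),
                              horizon = 35, seed = 6)
  expect_true(all(!all_cens$event))
  expect_equal(km_estimate(all_cens)$surv, 1)
})

test_that("large simulated cohorts recover their generating parameters", {
  big <- simulate_cohort(sizes = c(null = 2000),
                         median_weeks = c(null = 12),
                         event_probs = list(null = c(thymic_lymphoma = 0.4,
                                                     testicular_teratoma = 0.4,
                                                     none = 0.2)),
                         seed = 8)
  km <- km_estimate(big)
  expect_equal(km_median(km), 12, tolerance = 0.5 / 12)
  sp <- tumor_spectrum(big, "null")
  got <- stats::setNames(sp$percent, sp$diagnosis)
  # binomial error at n = 2000 is ~1.1 percentage points (1 SE)
  expect_equal(unname(got["thymic_lymphoma"]), 40, tolerance = 4 / 40)
  expect_equal(unname(got["testicular_teratoma"]), 40, tolerance = 4 / 40)
})

test_that("simulated genes are placed without overlap and drive classification", {
  g <- simulate_genes(toy_genome, 40, gene_bp = 800, seed = 3)
  expect_identical(g, simulate_genes(toy_genome, 40, gene_bp = 800, seed = 3))
  expect_equal(nrow(g$genes), 40)
  expect_equal(g$category_map$gene, g$genes$name)
  for (chrom in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == chrom, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    }
  }
  clen <- toy_genome$length[match(g$genes$chrom, toy_genome$chrom)]
  expect_true(all(g$genes$start >= 0 & g$genes$end <= clen))

  # no genes at all: every region is a desert
  none <- simulate_genes(toy_genome, 0, seed = 3)
  regions <- data.frame(chrom = "chr1", start = c(0, 1000),
                        end = c(500, 2000))
  ann <- annotate_regions(regions, none$genes, none$category_map)
  expect_equal(ann$category, c("gene_desert", "gene_desert"))

  # degenerate category mix: every non-desert region classifies cancer
  allc <- simulate_genes(toy_genome, 30, gene_bp = 2000,
                         category_mix = c(cancer = 1), seed = 13)
  ann2 <- annotate_regions(data.frame(chrom = "chr1", start = 0,
                                      end = 60000),
                           allc$genes, allc$category_map)
  expect_equal(ann2$category, "cancer")

  expect_error(simulate_genes(toy_genome, 1e6, gene_bp = 5000, seed = 1),
               "could not place")
})

test_that("end-to-end: planted regions keep their planted gene categories", {
  background <- simulate_panel(toy_genome, six, mean_block_bp = 3000,
                               shared_strains = six, shared_prob = 1,
                               seed = 21)
  windows <- data.frame(chrom = c("chr1", "chr2"),
                        start = c(10000, 5000), end = c(14000, 8000))
  planted <- plant_regions(background, design6, windows, toy_genome,
                           flank_bp = 2000)
  regions <- scan_contrast(planted, design6, toy_genome)$regions
  expect_same_regions(regions, windows)

  genes <- data.frame(name = c("mod1", "mod2"),
                      chrom = c("chr1", "chr2"),
                      start = c(11000, 6000), end = c(12000, 7000),
                      strand = "+", stringsAsFactors = FALSE)
  cmap <- data.frame(gene = c("mod1", "mod2"),
                     category = c("cancer", "dna_repair"))
  ann <- annotate_regions(regions, genes, cmap)
  expect_equal(ann$category, c("cancer", "dna_repair"))
})
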