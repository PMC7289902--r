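two_strain_panel <- function() {
  data.frame(
    strain = c("s1", "s2", "s2"),
    chrom = "chr1",
    start = c(0, 0, 50),
    end = c(100, 50, 100),
    haplotype = c("A", "X", "Y"),
    stringsAsFactors = FALSE
  )
}

test_that("segment_joint cuts at the union of block boundaries", {
  genome <- data.frame(chrom = "chr1", length = 200)

  one <- data.frame(strain = "s1", chrom = "chr1", start = 0, end = 100,
                    haplotype = "A")
  js <- segment_joint(one, genome)
  expect_equal(js$segments, data.frame(chrom = "chr1", start = 0, end = 100))
  expect_equal(unname(js$labels[1, "s1"]), "A")

  js2 <- segment_joint(two_strain_panel(), genome)
  expect_equal(js2$segments$start, c(0, 50))
  expect_equal(js2$segments$end, c(50, 100))
  expect_equal(unname(js2$labels[, "s1"]), c("A", "A"))
  expect_equal(unname(js2$labels[, "s2"]), c("X", "Y"))

  # uncovered span stays missing; chromosome off the build is an error
  gap <- data.frame(strain = c("s1", "s1"), chrom = "chr1",
                    start = c(0, 150), end = c(50, 200),
                    haplotype = c("A", "B"))
  js3 <- segment_joint(gap, genome)
  expect_equal(js3$segments$start, c(0, 150))
  off <- data.frame(strain = "s1", chrom = "chrX", start = 0, end = 10,
                    haplotype = "A")
  expect_error(segment_joint(off, genome), "absent from the genome")
})

test_that("matches_pattern implements the contrast predicate", {
  d <- contrast_design(shared = paste0("s", 1:4),
                       distinct = c("SJL", "BALB"))
  lab <- c(s1 = "a", s2 = "a", s3 = "a", s4 = "a", SJL = "b", BALB = "c")
  expect_true(matches_pattern(lab, d))

  lab["s3"] <- "z"
  expect_false(matches_pattern(lab, d))
  lab["s3"] <- "a"

  # distinct strain equal to the shared label never qualifies
  lab["SJL"] <- "a"
  expect_false(matches_pattern(lab, d))
  lab["SJL"] <- "b"

  # equal distinct labels: governed by require_pairwise_distinct
  lab["BALB"] <- "b"
  expect_false(matches_pattern(lab, d))
  d_relaxed <- contrast_design(shared = paste0("s", 1:4),
                               distinct = c("SJL", "BALB"),
                               require_pairwise_distinct = FALSE)
  expect_true(matches_pattern(lab, d_relaxed))

  # missing calls disqualify by default, qualify as wildcards when asked
  lab["BALB"] <- NA
  expect_false(matches_pattern(lab, d))
  d_wild <- contrast_design(shared = paste0("s", 1:4),
                            distinct = c("SJL", "BALB"),
                            missing_as_wildcard = TRUE)
  expect_true(matches_pattern(lab, d_wild))

  expect_error(matches_pattern(c(s1 = "a"), d), "lacks strain")
  expect_error(contrast_design("s1", "s1"), "disjoint")
  expect_error(contrast_design(character(), "s1"), "at least one")
})

test_that("scan recovers a planted window exactly and merges book-ended segments", {
  genome <- data.frame(chrom = "chr1", length = 1000)
  d <- contrast_design(shared = c("s1", "s2"), distinct = c("s3", "s4"))
  block <- function(s, from, to, h) {
    data.frame(strain = s, chrom = "chr1", start = from, end = to,
               haplotype = h, stringsAsFactors = FALSE)
  }
  # background all identical ("bg" everywhere) except window [200, 400)
  panel <- rbind(
    block("s1", 0, 200, "bg"), block("s1", 200, 400, "q"),
    block("s1", 400, 1000, "bg"),
    block("s2", 0, 200, "bg"), block("s2", 200, 400, "q"),
    block("s2", 400, 1000, "bg"),
    block("s3", 0, 200, "bg"), block("s3", 200, 400, "d1"),
    block("s3", 400, 1000, "bg"),
    block("s4", 0, 200, "bg"), block("s4", 200, 300, "d2"),
    block("s4", 300, 400, "d3"), block("s4", 400, 1000, "bg")
  )
  res <- scan_contrast(panel, d, genome)
  # s4 changes witness label mid-window; the two qualifying segments must
  # still merge into one region
  expect_equal(nrow(res$regions), 1)
  expect_equal(res$regions$start, 200)
  expect_equal(res$regions$end, 400)
  expect_equal(res$summary$fraction, 200 / 1000)

  # nothing qualifies when the pattern is broken everywhere
  all_same <- panel
  all_same$haplotype <- "bg"
  res0 <- scan_contrast(all_same, d, genome)
  expect_equal(nrow(res0$regions), 0)
  expect_equal(res0$summary$fraction, 0)

  expect_error(scan_contrast(panel, contrast_design("s1", "s9"), genome),
               "absent from the panel")
})

test_that("merge_gap bridges short non-qualifying gaps only when asked", {
  genome <- data.frame(chrom = "chr1", length = 300)
  d <- contrast_design(shared = "s1", distinct = "s2")
  panel <- rbind(
    data.frame(strain = "s1", chrom = "chr1",
               start = c(0, 100, 110), end = c(100, 110, 300),
               haplotype = c("a", "a", "a")),
    data.frame(strain = "s2", chrom = "chr1",
               start = c(0, 100, 110), end = c(100, 110, 300),
               haplotype = c("b", "a", "b"))
  )
  strict <- scan_contrast(panel, d, genome)
  expect_equal(nrow(strict$regions), 2)
  bridged <- scan_contrast(panel, d, genome, merge_gap = 10)
  expect_equal(nrow(bridged$regions), 1)
  expect_equal(c(bridged$regions$start, bridged$regions$end), c(0, 300))
  # note merged length counts only qualifying bases in the strict run
  expect_equal(strict$summary$total_bp, 290)
})

test_that("scan equals the per-base brute-force oracle on random panels", {
  set.seed(101)
  for (i in 1:25) {
    genome <- rand_genome(2500)
    panel <- rand_panel(genome, n_strains = sample(3:6, 1),
                        n_labels = sample(2:8, 1), mean_block = 120)
    strains <- unique(panel$strain)
    d <- contrast_design(shared = strains[1:2],
                         distinct = strains[3:length(strains)],
                         require_pairwise_distinct = sample(c(TRUE, FALSE), 1),
                         missing_as_wildcard = sample(c(TRUE, FALSE), 1))
    got <- scan_contrast(panel, d, genome)$regions
    want <- oracle_scan(panel, d, genome)
    expect_same_regions(got, want)
  }
})

test_that("subdividing a block without changing labels never changes the scan", {
  set.seed(202)
  for (i in 1:15) {
    genome <- rand_genome(2000)
    panel <- rand_panel(genome, 4, 4, mean_block = 150)
    d <- contrast_design(shared = c("s1", "s2"), distinct = c("s3", "s4"))
    before <- scan_contrast(panel, d, genome)$regions

    split <- panel
    for (k in sample(nrow(panel), min(5, nrow(panel)))) {
      b <- split[k, ]
      if (b$end - b$start < 2) next
      cut <- sample((b$start + 1):(b$end - 1), 1)
      split[k, "end"] <- cut
      split <- rbind(split, data.frame(strain = b$strain, chrom = b$chrom,
                                       start = cut, end = b$end,
                                       haplotype = b$haplotype))
    }
    after <- scan_contrast(split, d, genome)$regions
    expect_same_regions(after, before)
  }
})

test_that("shared-group order is irrelevant and growing it is monotone", {
  set.seed(303)
  for (i in 1:10) {
    genome <- rand_genome(2000)
    panel <- rand_panel(genome, 5, 4, mean_block = 100)
    d <- contrast_design(shared = c("s1", "s2", "s3"), distinct = "s4")
    perm <- contrast_design(shared = c("s3", "s1", "s2"), distinct = "s4")
    a <- scan_contrast(panel, d, genome)
    expect_same_regions(scan_contrast(panel, perm, genome)$regions,
                        a$regions)

    # adding s5 to the shared group can only shrink the qualifying set
    wider <- contrast_design(shared = c("s1", "s2", "s3", "s5"),
                             distinct = "s4")
    b <- scan_contrast(panel, wider, genome)
    expect_lte(b$summary$total_bp, a$summary$total_bp)
    for (j in seq_len(nrow(b$regions))) {
      inside <- a$regions$chrom == b$regions$chrom[j] &
        a$regions$start <= b$regions$start[j] &
        a$regions$end >= b$regions$end[j]
      expect_true(any(inside))
    }
  }
})

test_that("genome_fraction sums disjoint regions and rejects overlap", {
  genome <- data.frame(chrom = c("chr1", "chr2"), length = c(600, 400))
  expect_equal(genome_fraction(data.frame(chrom = character(),
                                          start = numeric(),
                                          end = numeric()),
                               genome)$fraction, 0)
  tiling <- data.frame(chrom = c("chr1", "chr2"), start = 0,
                       end = c(600, 400))
  s <- genome_fraction(tiling, genome)
  expect_equal(s$fraction, 1)
  expect_equal(s$percent, 100)

  overlapping <- data.frame(chrom = "chr1", start = c(0, 50),
                            end = c(100, 120))
  expect_error(genome_fraction(overlapping, genome), "overlap")
})
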