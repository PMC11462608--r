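test_that("read_vcf keeps only clean biallelic SNPs and tallies drops", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  m <- read_vcf(vcf)
  expect_s3_class(m, "hap_matrix")
  expect_equal(n_haplotypes(m), 6L)
  expect_equal(n_sites(m), 2L)
  expect_equal(m$sites$pos, c(100L, 200L))
  expect_equal(m$sites$variant_id, c("rs1", "rs2"))
  # hand-tallied ALT counts from the GT fields
  expect_equal(derived_counts(m), c(3L, 2L))
  expect_equal(m$calls[, 1L], c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(m$sites$aa, c("A", "T"))
  expect_true(all(m$sites$polarity == "UNPOLARIZED"))
  log <- attr(m, "filter_log")
  expect_equal(unname(log["multiallelic"]), 1)
  expect_equal(unname(log["non_snp"]), 1)
  expect_equal(unname(log["missing_gt"]), 1)
})

test_that("read_vcf with only a non-biallelic site yields 0 sites, header haplotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  lines <- readLines(write_toy_vcf(withr::local_tempfile(fileext = ".vcf")))
  writeLines(c(lines[1:5], lines[8]), path)  # header + the multiallelic row
  m <- read_vcf(path)
  expect_equal(n_sites(m), 0L)
  expect_equal(n_haplotypes(m), 6L)
})

test_that("read_vcf rejects unphased calls and duplicate positions", {
  bad <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), unphased = TRUE)
  expect_error(read_vcf(bad), "chr4:200")
  dup <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), dup_pos = TRUE)
  expect_error(read_vcf(dup), "duplicate position")
})

test_that("read_vcf honours a region restriction", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  m <- read_vcf(vcf, region = "chr4:150-250")
  expect_equal(m$sites$pos, 200L)
})

test_that("read_panel parses, counts, and rejects malformed panels", {
  p <- write_toy_panel(withr::local_tempfile(fileext = ".panel"))
  panel <- read_panel(p)
  expect_equal(unname(panel_counts(panel, by = "pop")), c(2L, 2L))
  expect_equal(unname(panel_counts(panel, "SP2")), 2L)
  expect_equal(unname(panel_counts(panel, "NOPE")), 0L)

  empty <- withr::local_tempfile(fileext = ".panel")
  writeLines("sample\tpop\tsuper_pop\tgender", empty)
  pe <- read_panel(empty)
  expect_equal(nrow(pe), 0L)
  expect_equal(unname(panel_counts(pe, "AFR")), 0L)

  badcol <- withr::local_tempfile(fileext = ".panel")
  writeLines(c("sample\tpopulation", "S1\tP1"), badcol)
  expect_error(read_panel(badcol), "missing required column")

  dup <- withr::local_tempfile(fileext = ".panel")
  writeLines(c("sample\tpop\tsuper_pop", "S1\tP1\tSP1", "S1\tP2\tSP2"), dup)
  expect_error(read_panel(dup), "duplicated sample")
})

test_that("polarize orients calls by ancestral allele", {
  # site 1: AA==REF (identity); site 2: AA==ALT (flip); site 3: AA missing
  calls <- rbind(c(1L, 1L, 0L), c(0L, 1L, 1L), c(1L, 1L, 0L), c(0L, 0L, 1L),
                 c(1L, 0L, 0L), c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 0L, 0L),
                 c(0L, 0L, 1L), c(0L, 0L, 0L))
  m <- make_hm(calls, aa = c("A", "G", NA))
  expect_equal(derived_counts(m), c(3L, 3L, 4L))
  pm <- polarize(m)
  expect_equal(pm$sites$polarity,
               c("ALT_IS_DERIVED", "REF_IS_DERIVED", "UNPOLARIZED"))
  expect_equal(pm$calls[, 1L], calls[, 1L])
  # derived count 3 of n=10 flips to 7
  expect_equal(derived_counts(pm)[2L], 7L)
  # flip is an involution: re-polarizing restores the ALT coding
  expect_equal(polarize(pm)$calls[, 2L], calls[, 2L])

  dropped <- polarize(m, drop_unpolarized = TRUE)
  expect_equal(n_sites(dropped), 2L)
  expect_equal(unname(attr(dropped, "filter_log")["unpolarized_dropped"]), 1L)
})

test_that("polarize case handling matches the lowercase-AA dialect", {
  calls <- matrix(c(1L, 0L, 1L, 0L), ncol = 1L)
  m <- make_hm(calls, aa = "a")
  expect_equal(polarize(m)$sites$polarity, "ALT_IS_DERIVED")
  expect_equal(polarize(m, strict_uppercase = TRUE)$sites$polarity,
               "UNPOLARIZED")
})

test_that("polarize drops nothing on a 5-site toy with 2 AA-less sites", {
  calls <- matrix(rbinom(20 * 5, 1L, 0.5), 20L, 5L)
  m <- make_hm(calls, aa = c("A", NA, "A", NA, "A"))
  expect_equal(n_sites(polarize(m, drop_unpolarized = TRUE)), 3L)
})

test_that("subset_and_filter subsets samples and applies MAF boundary strictly", {
  set.seed(5)
  n_hap <- 20L
  calls <- matrix(0L, n_hap, 3L)
  calls[1L, 1L] <- 1L          # MAF 1/20 = 0.05 -> dropped at maf_min 0.05
  calls[1:2, 2L] <- 1L         # MAF 2/20 = 0.10 -> retained
  calls[1:10, 3L] <- 1L
  m <- make_hm(calls)
  panel <- data.frame(sample = m$sample_ids, pop = "P1", super_pop = "SP1",
                      stringsAsFactors = FALSE)
  class(panel) <- c("pop_panel", "data.frame")
  f <- subset_and_filter(m, panel, "P1", maf_min = 0.05)
  expect_equal(f$sites$pos, m$sites$pos[2:3])

  # full panel, no filters: identity
  id <- subset_and_filter(m, panel, "P1")
  expect_equal(id$calls, m$calls)
  expect_equal(id$sites, m$sites)

  expect_error(subset_and_filter(m, panel, "ZZZ"), "not in panel")
})

test_that("subset to half the samples drops sites fixed in the subset", {
  calls <- matrix(0L, 8L, 2L)
  calls[1:4, 1L] <- 1L   # polymorphic overall, fixed 1 in pop A / 0 in pop B
  calls[c(1L, 5L), 2L] <- 1L
  m <- make_hm(calls)
  panel <- data.frame(sample = m$sample_ids,
                      pop = rep(c("A", "B"), each = 2L),
                      super_pop = rep(c("A", "B"), each = 2L),
                      stringsAsFactors = FALSE)
  class(panel) <- c("pop_panel", "data.frame")
  sub <- subset_and_filter(m, panel, "A", drop_monomorphic = TRUE)
  expect_equal(n_haplotypes(sub), 4L)
  expect_equal(n_sites(sub), 1L)
  expect_equal(sub$sites$pos, m$sites$pos[2L])
})

test_that("write_fixture round-trips through read_vcf/read_panel bit-exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- simulate_neutral(20L, 8, 5e4, aa_flip_frac = 0.4)
    td <- withr::local_tempdir()
    paths <- write_fixture(m, NULL, td)
    m2 <- polarize(read_vcf(paths$vcf))
    expect_identical(m2$calls, m$calls)
    expect_identical(m2$sites$pos, m$sites$pos)
    expect_identical(m2$sites$polarity, m$sites$polarity)
    expect_identical(m2$sites$aa, m$sites$aa)
    expect_identical(m2$sample_ids, m$sample_ids)
    panel <- read_panel(paths$panel)
    expect_identical(panel$sample, m$sample_ids)
  }
})
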