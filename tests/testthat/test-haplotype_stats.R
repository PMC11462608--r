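test_that("ehh_curve matches the hand-worked group partitions", {
  # 8 haplotypes; derived carriers are rows 1-4
  core_col <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)

  # identical carriers: EHH stays 1
  right1 <- matrix(0L, 8L, 3L)
  m1 <- make_hm(cbind(core_col, right1))
  cv1 <- ehh_curve(m1, 1L, "DERIVED", "RIGHT", cutoff = 0)
  expect_equal(cv1$points$ehh, rep(1, 4L))

  # carriers split 2+2 at the first outward SNP: EHH = (1+1)/6
  split22 <- matrix(c(0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), ncol = 1L)
  m2 <- make_hm(cbind(core_col, split22))
  cv2 <- ehh_curve(m2, 1L, "DERIVED", "RIGHT", cutoff = 0)
  expect_equal(cv2$points$ehh[2L], 1 / 3)

  # all four carriers distinct over two SNPs: EHH hits 0 and the curve ends
  distinct <- cbind(c(0L, 0L, 1L, 1L, rep(0L, 4L)),
                    c(0L, 1L, 0L, 1L, rep(0L, 4L)))
  m3 <- make_hm(cbind(core_col, distinct, 0L))
  cv3 <- ehh_curve(m3, 1L, "DERIVED", "RIGHT", cutoff = 0.05)
  expect_equal(utils::tail(cv3$points$ehh, 1L), 0)
  expect_false(cv3$edge)
  expect_equal(nrow(cv3$points), 3L)  # truncated before the 4th column

  expect_error(ehh_curve(m1, 2L, "DERIVED", "RIGHT"), "fewer than 2")
})

test_that("every curve starts at 1 and is monotone non-increasing", {
  set.seed(31)
  for (r in 1:20) {
    m <- random_hm(2L * sample(4:10, 1L), sample(10:30, 1L))
    core <- sample(2:(n_sites(m) - 1L), 1L)
    for (cl in c("DERIVED", "ANCESTRAL")) {
      if (sum(m$calls[, core] == (cl == "DERIVED")) < 2L) next
      for (sd in c("LEFT", "RIGHT")) {
        p <- ehh_curve(m, core, cl, sd, cutoff = 0,
                       max_extend_bp = 1e9, max_gap_bp = 1e9)$points
        expect_equal(p$ehh[1L], 1)
        expect_true(all(diff(p$ehh) <= 1e-12))
      }
    }
  }
})

test_that("ehh_curve agrees with the brute-force pair-identity oracle", {
  set.seed(32)
  for (r in 1:25) {
    m <- random_hm(2L * sample(4:10, 1L), sample(12:40, 1L))
    core <- sample(4:(n_sites(m) - 4L), 1L)
    for (want in 0:1) {
      if (sum(m$calls[, core] == want) < 2L) next
      cl <- if (want == 1L) "DERIVED" else "ANCESTRAL"
      for (sd in c("LEFT", "RIGHT")) {
        p <- ehh_curve(m, core, cl, sd, cutoff = 0, max_extend_bp = 1e9,
                       max_gap_bp = 1e9)$points
        for (k in seq_len(min(nrow(p) - 1L, 3L))) {
          expect_equal(p$ehh[k + 1L], brute_ehh(m, core, want, sd, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("integrate_ihh computes (gap-damped) trapezoids", {
  mk_curve <- function(d, e) {
    structure(list(points = data.frame(distance = d, ehh = e)),
              class = "ehh_curve")
  }
  expect_equal(integrate_ihh(mk_curve(c(0, 1000), c(1, 0.5))), 750)
  expect_equal(integrate_ihh(mk_curve(c(0, 5000, 10000), c(1, 1, 1))), 10000)
  # one 40 kb segment with gap_scale 20 kb: its area is halved
  expect_equal(integrate_ihh(mk_curve(c(0, 40000), c(1, 1)),
                             gap_scale_bp = 20000), 20000)
  expect_equal(integrate_ihh(mk_curve(0, 1)), 0)
})

test_that("curves crossing a max_gap_bp gap are flagged and iHS skips them", {
  core_col <- rep(c(1L, 0L), each = 4L)
  m <- make_hm(cbind(core_col, core_col, core_col),
               pos = c(1000L, 2000L, 500000L))
  cv <- ehh_curve(m, 1L, "DERIVED", "RIGHT", max_gap_bp = 2e5)
  expect_true(cv$gap_aborted)
  s <- ihs_scan(m, maf_min = 0, max_gap_bp = 2e5)
  expect_true("GAP_SKIPPED" %in% s$status)
})

test_that("mirror construction gives unstd = 0 for iHS and nSL", {
  set.seed(33)
  half <- matrix(rbinom(4L * 11L, 1L, 0.5), 4L, 11L)
  calls <- rbind(half, half)          # identical carrier sets up to relabeling
  calls[1:4, 6L] <- 1L                # core: rows 1-4 derived
  calls[5:8, 6L] <- 0L
  m <- make_hm(calls)
  s <- ihs_scan(m, maf_min = 0, cutoff = 0, edge_ok = TRUE)
  expect_equal(s$unstd[6L], 0)
  ns <- nsl_scan(m, maf_min = 0)
  expect_equal(ns$unstd[6L], 0)
})

test_that("swapping ancestral/derived labels at the core negates unstd", {
  set.seed(34)
  for (r in 1:5) {
    m <- random_hm(16L, 21L)
    core <- 11L
    if (min(sum(m$calls[, core]), 16L - sum(m$calls[, core])) < 3L) next
    swapped <- m
    swapped$calls[, core] <- 1L - swapped$calls[, core]
    s1 <- ihs_scan(m, maf_min = 0, cutoff = 0, edge_ok = TRUE)
    s2 <- ihs_scan(swapped, maf_min = 0, cutoff = 0, edge_ok = TRUE)
    expect_equal(s1$unstd[core], -s2$unstd[core], tolerance = 1e-12)
    n1 <- nsl_scan(m, maf_min = 0)
    n2 <- nsl_scan(swapped, maf_min = 0)
    expect_equal(n1$unstd[core], -n2$unstd[core], tolerance = 1e-12)
  }
})

test_that("nSL pair lengths match the direct pair walk", {
  # 2 derived haplotypes identical across all 11 SNPs, core central
  calls <- matrix(rbinom(6L * 11L, 1L, 0.5), 6L, 11L)
  calls[1L, ] <- calls[2L, ]          # the derived pair
  calls[, 6L] <- c(1L, 1L, 0L, 0L, 0L, 0L)
  m <- make_hm(calls)
  ns <- nsl_scan(m, maf_min = 0, max_extend_snps = 5L)
  expect_equal(ns$sl_d[6L], 11)

  # derived pair differing at both core-adjacent SNPs: L = 1
  calls2 <- calls
  calls2[1L, 5L] <- 1L - calls2[2L, 5L]
  calls2[1L, 7L] <- 1L - calls2[2L, 7L]
  m2 <- make_hm(calls2)
  ns2 <- nsl_scan(m2, maf_min = 0, max_extend_snps = 5L)
  expect_equal(ns2$sl_d[6L], 1)
})

test_that("cores failing the MAF floor are filtered, boundary strict", {
  calls <- matrix(rbinom(50L * 5L, 1L, 0.5), 50L, 5L)
  calls[, 3L] <- c(rep(1L, 2L), rep(0L, 48L))  # MAF 0.04
  m <- make_hm(calls)
  s <- ihs_scan(m, maf_min = 0.05)
  expect_equal(s$status[3L], "MAF_FILTERED")
  expect_true(is.na(s$unstd[3L]))
})

test_that("standardization centres and scales each populated bin", {
  scores <- data.frame(
    variant_id = c("a", "b", "c"), pos = 1:3,
    derived_freq = c(0.505, 0.505, 0.995),
    unstd = c(1, 3, 2), std = NA_real_,
    status = "OK", stringsAsFactors = FALSE
  )
  st <- standardize_scores(scores, n_bins = 100L)
  expect_equal(st$scores$std[1:2], c(-1, 1))       # mean 2, population sd 1
  expect_true(is.na(st$scores$std[3L]))            # singleton bin undefined
  expect_equal(st$table$count[51L], 2L)

  set.seed(35)
  big <- data.frame(
    variant_id = paste0("v", 1:400), pos = 1:400,
    derived_freq = runif(400), unstd = rnorm(400), std = NA_real_,
    status = "OK", stringsAsFactors = FALSE
  )
  tb <- standardize_scores(big, n_bins = 10L)
  for (b in which(tb$table$count >= 2L)) {
    v <- tb$scores$std[ceiling(tb$scores$derived_freq * 10L) == b]
    v <- v[!is.na(v)]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(v^2)), 1, tolerance = 1e-9)
  }
  expect_error(standardize_scores(big[1L, ]), "at least 2")
})

test_that("unpolarized input is rejected by the haplotype scans", {
  m <- make_hm(matrix(rbinom(20L, 1L, 0.5), 4L, 5L), aa = rep(NA, 5L),
               polarity = rep("UNPOLARIZED", 5L))
  expect_error(ihs_scan(m), "unpolarized")
  expect_error(nsl_scan(m), "unpolarized")
})
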