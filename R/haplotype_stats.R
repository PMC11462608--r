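#' Extended haplotype homozygosity decay from a core SNP
#'
#' EHH at distance d from a core allele is the probability that two random
#' haplotypes carrying that allele are identical over the whole interval
#' from the core out to d. It is computed by partitioning the carriers into
#' identity groups SNP by SNP outward:
#' \deqn{EHH = \sum_g \binom{c_g}{2} / \binom{n_{class}}{2}}
#' where `c_g` are the group sizes. The curve starts at (0, 1), is
#' non-increasing, and is truncated at the first point below `cutoff`, at
#' `max_extend_bp`, or at the end of the data (flagged `edge`). A physical
#' gap larger than `max_gap_bp` between adjacent SNPs aborts the curve
#' (flagged `gap_aborted`).
#'
#' @param m a polarized [hap_matrix()].
#' @param core site index of the core SNP (must be polymorphic).
#' @param allele_class `"DERIVED"` (carriers of 1) or `"ANCESTRAL"` (0).
#' @param side `"LEFT"` or `"RIGHT"` of the core.
#' @param cutoff stop once EHH drops below this (default 0.05).
#' @param max_extend_bp maximum physical extension (default 1e6).
#' @param max_gap_bp abort on inter-SNP gaps beyond this (default 2e5).
#' @return An object of class `ehh_curve`: list with `points` (data.frame
#'   `distance`, `ehh`, the first row always (0, 1)), `core_index`, `side`,
#'   `allele_class`, `gap_aborted`, `edge`.
#' @export
ehh_curve <- function(m, core, allele_class = c("DERIVED", "ANCESTRAL"),
                      side = c("LEFT", "RIGHT"), cutoff = 0.05,
                      max_extend_bp = 1e6, max_gap_bp = 2e5) {
  allele_class <- match.arg(allele_class)
  side <- match.arg(side)
  want <- if (allele_class == "DERIVED") 1L else 0L
  rows <- which(m$calls[, core] == want)
  n_class <- length(rows)
  if (n_class < 2L) stop("allele class has fewer than 2 carriers")

  pos <- m$sites$pos
  idx_seq <- if (side == "RIGHT") {
    seq_len(n_sites(m))[-seq_len(core)]
  } else {
    rev(seq_len(core - 1L))
  }
  pairs_total <- n_class * (n_class - 1) / 2
  g <- rep(1L, n_class)
  dist <- 0
  ehh <- 1
  gap_aborted <- FALSE
  edge <- TRUE  # flipped off if we stop for cutoff/extension/gap
  prev_pos <- pos[core]
  for (idx in idx_seq) {
    gap <- abs(pos[idx] - prev_pos)
    if (gap > max_gap_bp) {
      gap_aborted <- TRUE
      edge <- FALSE
      break
    }
    d <- abs(pos[idx] - pos[core])
    if (d > max_extend_bp) {
      edge <- FALSE
      break
    }
    key <- g * 2L + m$calls[rows, idx]
    g <- match(key, unique(key))
    cg <- tabulate(g)
    e <- sum(cg * (cg - 1) / 2) / pairs_total
    dist <- c(dist, d)
    ehh <- c(ehh, e)
    prev_pos <- pos[idx]
    if (e < cutoff) {
      edge <- FALSE
      break
    }
  }
  structure(
    list(points = data.frame(distance = dist, ehh = ehh),
         core_index = core, side = side, allele_class = allele_class,
         gap_aborted = gap_aborted, edge = edge, cutoff = cutoff),
    class = "ehh_curve"
  )
}

#' Integrate an EHH curve (iHH)
#'
#' Trapezoidal area under the (distance, ehh) curve from the core to its
#' truncation point. A segment spanning a physical gap `g > gap_scale_bp`
#' contributes its trapezoid area scaled by `gap_scale_bp / g`, damping the
#' influence of sparse stretches.
#'
#' @param curve an [ehh_curve()].
#' @param gap_scale_bp gap damping scale (default 20000).
#' @return the integrated homozygosity (bp units).
#' @export
integrate_ihh <- function(curve, gap_scale_bp = 2e4) {
  p <- curve$points
  if (nrow(p) < 2L) return(0)
  d <- p$distance
  e <- p$ehh
  seg <- diff(d)
  area <- (e[-length(e)] + e[-1L]) / 2 * seg
  damp <- seg > gap_scale_bp
  area[damp] <- area[damp] * gap_scale_bp / seg[damp]
  sum(area)
}

## Unnormalized per-step EHH pair fractions in SNP units (for nSL):
## element k is the fraction of carrier pairs identical over the first k
## SNPs outward. No cutoff, no gap handling; capped at max_steps/data end.
ehh_snp_steps <- function(m, rows, core, side, max_steps) {
  idx_seq <- if (side == "RIGHT") {
    seq_len(n_sites(m))[-seq_len(core)]
  } else {
    rev(seq_len(core - 1L))
  }
  if (length(idx_seq) > max_steps) idx_seq <- idx_seq[seq_len(max_steps)]
  n_class <- length(rows)
  pairs_total <- n_class * (n_class - 1) / 2
  g <- rep(1L, n_class)
  out <- numeric(length(idx_seq))
  for (k in seq_along(idx_seq)) {
    key <- g * 2L + m$calls[rows, idx_seq[k]]
    g <- match(key, unique(key))
    cg <- tabulate(g)
    out[k] <- sum(cg * (cg - 1) / 2) / pairs_total
    if (out[k] == 0) {
      out <- out[seq_len(k)]  # all later terms are 0 too
      break
    }
  }
  out
}

check_polarized <- function(m) {
  if (any(m$sites$polarity == "UNPOLARIZED")) {
    stop("matrix contains unpolarized sites; run polarize(drop_unpolarized = TRUE)")
  }
}

#' iHS scan over all eligible core SNPs
#'
#' For each core SNP passing the minor-allele-frequency floor, integrates
#' EHH decay separately over the ancestral-allele and derived-allele
#' carriers (left + right of the core) and reports the unstandardized score
#' \deqn{uiHS = \ln(iHH_A / iHH_D)}
#' so that long derived haplotypes (a sweep on the derived allele) give
#' negative values. Cores whose EHH is still above `cutoff` when the data
#' end are excluded (`EDGE_TRUNCATED`); cores whose curves hit a physical
#' gap beyond `max_gap_bp` are excluded (`GAP_SKIPPED`). Standardization is
#' a separate step: [standardize_scores()].
#'
#' Defaults follow the conventions of common haplotype-scan software:
#' cutoff 0.05, extension cap 1 Mb, gap abort 200 kb, gap damping 20 kb,
#' MAF floor 5%.
#'
#' @param m a fully polarized [hap_matrix()] (see [polarize()]).
#' @param maf_min minor-allele-frequency floor; cores with MAF not
#'   strictly above it are skipped (`MAF_FILTERED`).
#' @param cutoff,max_extend_bp,max_gap_bp see [ehh_curve()].
#' @param gap_scale_bp see [integrate_ihh()].
#' @param edge_ok if `TRUE`, cores whose EHH is still above `cutoff` at the
#'   end of the data are scored anyway, with the integral truncated there
#'   (the `--trunc-ok` convention). Needed for non-recombining simulated
#'   loci, where EHH barely decays; default `FALSE` mirrors the usual
#'   tool behaviour on real data.
#' @return data.frame with one row per site: `variant_id, pos, derived_freq,
#'   ihh_a, ihh_d, unstd, std, status`; `std` is `NA` until
#'   [standardize_scores()].
#' @export
ihs_scan <- function(m, maf_min = 0.05, cutoff = 0.05, max_extend_bp = 1e6,
                     max_gap_bp = 2e5, gap_scale_bp = 2e4, edge_ok = FALSE) {
  check_polarized(m)
  n <- n_haplotypes(m)
  dc <- derived_counts(m)
  res <- data.frame(
    variant_id = m$sites$variant_id, pos = m$sites$pos,
    derived_freq = dc / n,
    ihh_a = NA_real_, ihh_d = NA_real_, unstd = NA_real_, std = NA_real_,
    status = "MAF_FILTERED", stringsAsFactors = FALSE
  )
  maf <- pmin(dc, n - dc) / n
  for (j in which(maf > maf_min & dc >= 2L & (n - dc) >= 2L)) {
    curves <- list(
      ehh_curve(m, j, "ANCESTRAL", "LEFT", cutoff, max_extend_bp, max_gap_bp),
      ehh_curve(m, j, "ANCESTRAL", "RIGHT", cutoff, max_extend_bp, max_gap_bp),
      ehh_curve(m, j, "DERIVED", "LEFT", cutoff, max_extend_bp, max_gap_bp),
      ehh_curve(m, j, "DERIVED", "RIGHT", cutoff, max_extend_bp, max_gap_bp)
    )
    if (any(vapply(curves, `[[`, logical(1), "gap_aborted"))) {
      res$status[j] <- "GAP_SKIPPED"
      next
    }
    if (!edge_ok && any(vapply(curves, `[[`, logical(1), "edge"))) {
      res$status[j] <- "EDGE_TRUNCATED"
      next
    }
    ihh <- vapply(curves, integrate_ihh, numeric(1), gap_scale_bp = gap_scale_bp)
    ihh_a <- ihh[1L] + ihh[2L]
    ihh_d <- ihh[3L] + ihh[4L]
    res$ihh_a[j] <- ihh_a
    res$ihh_d[j] <- ihh_d
    if (ihh_a > 0 && ihh_d > 0) {
      res$unstd[j] <- log(ihh_a / ihh_d)
      res$status[j] <- "OK"
    } else {
      res$status[j] <- "EDGE_TRUNCATED"
    }
  }
  res
}

#' nSL scan over all eligible core SNPs
#'
#' The nSL statistic measures haplotype sharing in units of segregating
#' sites rather than physical distance. For a pair of same-class haplotypes,
#' `L` is the number of SNPs in the maximal interval containing the core over
#' which the pair is identical (at most `max_extend_snps` SNPs per side);
#' `SL_class` is the mean `L` over pairs, and the unstandardized score is
#' \deqn{unSL = \ln(SL_A / SL_D).}
#' The pair mean is computed without enumerating pairs, via the identity
#' `E[L] = 1 + sum_k EHH_left(k) + sum_k EHH_right(k)` in SNP steps (the
#' expectation of a non-negative integer is the sum of its tail
#' probabilities).
#'
#' @param m a fully polarized [hap_matrix()].
#' @param maf_min minor-allele-frequency floor (strict `>`).
#' @param max_extend_snps cap on extension, in SNPs per side (default 100).
#' @return data.frame as in [ihs_scan()] with columns `sl_a`, `sl_d` in
#'   place of `ihh_a`, `ihh_d`.
#' @export
nsl_scan <- function(m, maf_min = 0.05, max_extend_snps = 100L) {
  check_polarized(m)
  n <- n_haplotypes(m)
  dc <- derived_counts(m)
  res <- data.frame(
    variant_id = m$sites$variant_id, pos = m$sites$pos,
    derived_freq = dc / n,
    sl_a = NA_real_, sl_d = NA_real_, unstd = NA_real_, std = NA_real_,
    status = "MAF_FILTERED", stringsAsFactors = FALSE
  )
  maf <- pmin(dc, n - dc) / n
  for (j in which(maf > maf_min & dc >= 2L & (n - dc) >= 2L)) {
    rows_d <- which(m$calls[, j] == 1L)
    rows_a <- which(m$calls[, j] == 0L)
    sl_d <- 1 + sum(ehh_snp_steps(m, rows_d, j, "LEFT", max_extend_snps)) +
      sum(ehh_snp_steps(m, rows_d, j, "RIGHT", max_extend_snps))
    sl_a <- 1 + sum(ehh_snp_steps(m, rows_a, j, "LEFT", max_extend_snps)) +
      sum(ehh_snp_steps(m, rows_a, j, "RIGHT", max_extend_snps))
    res$sl_a[j] <- sl_a
    res$sl_d[j] <- sl_d
    res$unstd[j] <- log(sl_a / sl_d)
    res$status[j] <- "OK"
  }
  res
}

#' Standardize haplotype scores within derived-frequency bins
#'
#' Bins the `OK` scores by derived allele frequency into `n_bins` equal-width
#' bins on (0, 1) and z-scores the unstandardized values within each bin
#' (population standard deviation, denominator = bin count). Bins with fewer
#' than 2 scores or zero spread leave `std` undefined. Standardization makes
#' scores comparable across frequencies, since unstandardized iHS/nSL drift
#' with allele frequency even under neutrality.
#'
#' @param scores output of [ihs_scan()] or [nsl_scan()].
#' @param n_bins number of frequency bins (default 100).
#' @return list with `scores` (input with `std` filled where defined) and
#'   `table`, a data.frame with per-bin `bin, freq_lo, freq_hi, mean, sd,
#'   count`.
#' @export
standardize_scores <- function(scores, n_bins = 100L) {
  ok <- which(scores$status == "OK" & !is.na(scores$unstd))
  if (length(ok) < 2L) stop("need at least 2 OK scores to standardize")
  f <- scores$derived_freq[ok]
  bin <- pmin(pmax(ceiling(f * n_bins), 1L), n_bins)
  tab <- data.frame(bin = seq_len(n_bins),
                    freq_lo = (seq_len(n_bins) - 1L) / n_bins,
                    freq_hi = seq_len(n_bins) / n_bins,
                    mean = NA_real_, sd = NA_real_, count = 0L)
  for (b in unique(bin)) {
    v <- scores$unstd[ok[bin == b]]
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    tab$mean[b] <- mu
    tab$sd[b] <- sdv
    tab$count[b] <- length(v)
    if (length(v) >= 2L && sdv > 0) {
      scores$std[ok[bin == b]] <- (v - mu) / sdv
    }
  }
  list(scores = scores, table = tab)
}
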