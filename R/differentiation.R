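#' Hudson's FST for one site
#'
#' The Hudson estimator with finite-sample correction, reported as the
#' (numerator, denominator) pair so windows can be aggregated as a ratio of
#' averages:
#' \deqn{N = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} - \frac{p_2(1-p_2)}{n_2 - 1}}
#' \deqn{D = p_1(1-p_2) + p_2(1-p_1), \qquad F_{ST} = N / D}
#' Negative values (sampling noise at low differentiation) are reported as
#' is; clamping happens only inside [pbs_from_fst()].
#'
#' @param p1,p2 derived (or ALT) allele frequencies in the two populations.
#' @param n1,n2 haplotype sample sizes (`>= 2`).
#' @return list with `numerator`, `denominator`, `fst` (`NA` when the
#'   denominator is zero, i.e. both populations fixed).
#' @export
hudson_fst_site <- function(p1, n1, p2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den,
       fst = ifelse(den == 0, NA_real_, num / den))
}

#' Windowed FST as a ratio of averages
#'
#' Aggregates per-site Hudson components across a window as
#' `sum(numerators) / sum(denominators)` — the ratio-of-averages estimator,
#' which is far less biased than averaging per-site ratios.
#'
#' @param num,den vectors of per-site numerators and denominators
#'   (from [hudson_fst_site()]).
#' @return scalar FST; `NA` when every denominator is zero.
#' @export
fst_window <- function(num, den) {
  keep <- den != 0
  if (!any(keep)) return(NA_real_)
  sum(num[keep]) / sum(den[keep])
}

#' Population branch statistic from three pairwise FST values
#'
#' Converts pairwise FST to branch lengths `T = -ln(1 - FST)` and reads off
#' the length of the focal population's branch on the three-population tree:
#' \deqn{PBS_A = (T_{AB} + T_{AC} - T_{BC}) / 2.}
#' FST is clamped to `[0, 1 - clamp_eps]` before the log so fixed
#' differences stay finite; the algebraic identity
#' `PBS_A + PBS_B = T_AB` holds exactly.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise FST between focal A and references
#'   B, C (vectorized).
#' @param clamp_eps upper clamp distance from 1 (default 1e-8).
#' @return list with `t_ab`, `t_ac`, `t_bc`, `pbs` (NA propagates).
#' @export
pbs_from_fst <- function(fst_ab, fst_ac, fst_bc, clamp_eps = 1e-8) {
  tr <- function(f) -log(1 - pmin(pmax(f, 0), 1 - clamp_eps))
  t_ab <- tr(fst_ab)
  t_ac <- tr(fst_ac)
  t_bc <- tr(fst_bc)
  list(t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
       pbs = (t_ab + t_ac - t_bc) / 2)
}

#' Per-site PBS scan for a focal population against two references
#'
#' For every site polymorphic in the pooled three populations, computes the
#' three pairwise Hudson FST values and the focal population's branch
#' statistic. Sites monomorphic in the pool, or with an undefined FST in any
#' pair, are skipped (count in `attr(, "filter_log")`).
#'
#' @param m a [hap_matrix()] containing all three populations.
#' @param panel a [read_panel()] result.
#' @param focal,ref1,ref2 population or superpopulation codes; must resolve
#'   to disjoint sample sets.
#' @return data.frame with `variant_id, pos, p_focal, p_ref1, p_ref2,
#'   fst_ab, fst_ac, fst_bc, pbs`.
#' @export
pbs_scan <- function(m, panel, focal, ref1, ref2) {
  ids <- lapply(c(focal, ref1, ref2), resolve_pop, panel = panel)
  if (length(unique(unlist(ids))) != length(unlist(ids))) {
    stop("populations overlap: ", focal, ", ", ref1, ", ", ref2)
  }
  sub <- lapply(ids, function(s) sample_subset(m, s))
  ns <- vapply(sub, n_haplotypes, integer(1))
  dc <- vapply(sub, derived_counts, integer(n_sites(m)))
  if (n_sites(m) == 1L) dc <- matrix(dc, nrow = 1L)
  p <- sweep(dc, 2L, ns, "/")

  pooled <- rowSums(dc)
  poly <- pooled > 0L & pooled < sum(ns)

  ab <- hudson_fst_site(p[, 1L], ns[1L], p[, 2L], ns[2L])
  ac <- hudson_fst_site(p[, 1L], ns[1L], p[, 3L], ns[3L])
  bc <- hudson_fst_site(p[, 2L], ns[2L], p[, 3L], ns[3L])
  defined <- poly & !is.na(ab$fst) & !is.na(ac$fst) & !is.na(bc$fst)

  pb <- pbs_from_fst(ab$fst[defined], ac$fst[defined], bc$fst[defined])
  out <- data.frame(
    variant_id = m$sites$variant_id[defined],
    pos = m$sites$pos[defined],
    p_focal = p[defined, 1L], p_ref1 = p[defined, 2L],
    p_ref2 = p[defined, 3L],
    fst_ab = ab$fst[defined], fst_ac = ac$fst[defined],
    fst_bc = bc$fst[defined],
    pbs = pb$pbs,
    stringsAsFactors = FALSE
  )
  attr(out, "filter_log") <- c(skipped = sum(!defined))
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' From phased haplotype frequencies: `D = p_ij - p_i p_j` and
#' \deqn{r^2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j)).}
#'
#' @param m a [hap_matrix()].
#' @param site_i,site_j site indices; both must be polymorphic.
#' @return scalar in `[0, 1]`.
#' @export
ld_r2 <- function(m, site_i, site_j) {
  n <- n_haplotypes(m)
  a <- m$calls[, site_i]
  b <- m$calls[, site_j]
  pi_ <- mean(a)
  pj <- mean(b)
  if (pi_ %in% c(0, 1) || pj %in% c(0, 1)) {
    stop("ld_r2 requires both sites polymorphic")
  }
  pij <- mean(a == 1L & b == 1L)
  d <- pij - pi_ * pj
  d^2 / (pi_ * (1 - pi_) * pj * (1 - pj))
}
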