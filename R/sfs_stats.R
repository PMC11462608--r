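#' Constants for Tajima's D
#'
#' The sample-size-dependent constants of Tajima's variance normalization.
#' With `n` haplotypes:
#' \deqn{a_1 = \sum_{i=1}^{n-1} 1/i, \quad a_2 = \sum_{i=1}^{n-1} 1/i^2}
#' \deqn{b_1 = (n+1)/(3(n-1)), \quad b_2 = 2(n^2+n+3)/(9n(n-1))}
#' \deqn{c_1 = b_1 - 1/a_1, \quad c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2}
#' \deqn{e_1 = c_1/a_1, \quad e_2 = c_2/(a_1^2 + a_2)}
#'
#' @param n haplotype sample size, `n >= 4` (the variance terms are unstable
#'   below that).
#' @return list with elements `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 4L) stop("tajima_constants requires n >= 4, got ", n)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Site-frequency-spectrum statistics for one window
#'
#' Computes, from the derived-allele counts `x_j` of the `S` segregating
#' sites among `n` haplotypes:
#' \deqn{\theta_\pi = \sum_j x_j (n - x_j) / \binom{n}{2}}
#' \deqn{\theta_W = S / a_1}
#' \deqn{D = (\theta_\pi - \theta_W) / \sqrt{e_1 S + e_2 S (S-1)}}
#' \deqn{\theta_H = \sum_{j \,\mathrm{polarized}} 2 x_j^2 / (n(n-1)), \quad
#'       H = \theta_\pi^{\mathrm{(polarized)}} - \theta_H}
#'
#' Tajima's D is frequency-folded and uses *all* biallelic sites (derived or
#' ALT counts interchangeably); Fay and Wu's H requires ancestral/derived
#' orientation and uses only polarized sites. `D` is `NA` when `S = 0`;
#' `H` is `NA` when the window holds no polarized site.
#'
#' @param m a [hap_matrix()] restricted to the window of interest.
#' @param require_polarized if `TRUE`, error unless every site is polarized.
#' @return list with `S`, `pi`, `theta_w`, `theta_h`, `tajima_d`, `faywu_h`,
#'   `n_polarized_sites`, `n` (haplotypes).
#' @export
window_sfs_stats <- function(m, require_polarized = FALSE) {
  n <- n_haplotypes(m)
  if (n < 4L) stop("window_sfs_stats requires >= 4 haplotypes")
  pol <- m$sites$polarity != "UNPOLARIZED"
  if (require_polarized && !all(pol)) {
    stop("matrix contains unpolarized sites")
  }
  x <- derived_counts(m)
  seg <- x > 0L & x < n
  xs <- x[seg]
  S <- length(xs)
  nc2 <- n * (n - 1) / 2
  pi <- sum(xs * (n - xs)) / nc2

  k <- tajima_constants(n)
  theta_w <- S / k$a1
  tajima_d <- if (S == 0L) NA_real_ else {
    (pi - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }

  xp <- x[seg & pol]
  n_pol <- sum(pol)
  if (n_pol == 0L) {
    theta_h <- NA_real_
    faywu_h <- NA_real_
  } else {
    theta_h <- sum(2 * xp^2) / (n * (n - 1))
    pi_pol <- sum(xp * (n - xp)) / nc2
    faywu_h <- pi_pol - theta_h
  }
  list(S = S, pi = pi, theta_w = theta_w, theta_h = theta_h,
       tajima_d = tajima_d, faywu_h = faywu_h,
       n_polarized_sites = n_pol, n = n)
}

#' Sliding-window SFS scan
#'
#' Tiles the span of the data with half-open windows `[start, start + window_bp)`
#' advancing by `step_bp`, anchored at `floor(min_pos / step_bp) * step_bp`,
#' and computes [window_sfs_stats()] in each. Windows with fewer than
#' `min_snps` sites report their `S` and `pi` but have `NA` D and H (too few
#' sites to normalize meaningfully).
#'
#' @param m a [hap_matrix()].
#' @param window_bp window length in bp (default 5000).
#' @param step_bp step in bp (default 1000); `window_bp >= step_bp >= 1`.
#' @param min_snps minimum sites for D/H to be reported (default 3).
#' @return data.frame with columns `chrom, start, end, n_snps, S, pi,
#'   pi_per_bp, theta_w, tajima_d, faywu_h`, ordered by `start`. `start` is
#'   1-based; `end = start + window_bp` is exclusive.
#' @export
sliding_scan <- function(m, window_bp = 5000L, step_bp = 1000L,
                         min_snps = 3L) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  if (n_sites(m) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0), S = integer(0),
                      pi = numeric(0), pi_per_bp = numeric(0),
                      theta_w = numeric(0), tajima_d = numeric(0),
                      faywu_h = numeric(0)))
  }
  pos <- m$sites$pos
  chrom <- m$sites$chrom[1L]
  first <- (min(pos) %/% step_bp) * step_bp
  starts <- seq.int(first, max(pos), by = step_bp)
  rows <- lapply(starts, function(s) {
    in_w <- pos >= s & pos < s + window_bp
    wm <- site_subset(m, in_w)
    st <- window_sfs_stats(wm)
    if (sum(in_w) < min_snps) {
      st$tajima_d <- NA_real_
      st$faywu_h <- NA_real_
    }
    data.frame(chrom = chrom, start = s, end = s + window_bp,
               n_snps = sum(in_w), S = st$S, pi = st$pi,
               pi_per_bp = st$pi / window_bp, theta_w = st$theta_w,
               tajima_d = st$tajima_d, faywu_h = st$faywu_h)
  })
  do.call(rbind, rows)
}
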