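#' Simulate a neutral coalescent haplotype sample
#'
#' Standard Kingman coalescent under the infinite-sites model, without
#' recombination. While `k` lineages remain, an exponential waiting time
#' with rate `k(k-1)/2` (in units of 2N generations) is drawn and a uniform
#' pair merges. Mutations are Poisson with mean `theta/2` times the total
#' branch length, each landing on a branch with probability proportional to
#' its length; carriers are the leaves below it. Expected segregating sites:
#' `E[S] = theta * a1(n)`. Positions are drawn uniformly on `[1, length_bp]`
#' without collision, sorted. The emitted matrix is polarized (1 = derived);
#' the ancestral allele equals REF except at a fraction `aa_flip_frac` of
#' sites, where the fixture deliberately encodes the derived allele as REF
#' (exercising [polarize()]).
#'
#' Determinism: driven entirely by R's RNG — `set.seed()` before calling.
#'
#' @param n number of haplotypes (even, `>= 2`).
#' @param theta scaled mutation rate (theta = 4N mu per locus).
#' @param length_bp locus length in bp (default 1e5).
#' @param chrom chromosome label (default `"sim1"`).
#' @param aa_flip_frac fraction of sites written with swapped REF/ancestral
#'   orientation (default 0).
#' @return a polarized [hap_matrix()]; `attr(, "locus_bp")` records the
#'   locus length.
#' @export
simulate_neutral <- function(n, theta, length_bp = 1e5L, chrom = "sim1",
                             aa_flip_frac = 0) {
  stopifnot(n >= 2L, n %% 2L == 0L, theta >= 0, length_bp >= 2L)
  # coalesce: track active lineages, their leaf sets and birth times
  leafsets <- as.list(seq_len(n))
  birth <- numeric(n)
  active <- seq_len(n)
  branches <- list()   # each: list(leaves, len)
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample(k, 2L)
    i <- active[pair[1L]]; j <- active[pair[2L]]
    branches[[length(branches) + 1L]] <- list(leaves = leafsets[[i]],
                                              len = t - birth[i])
    branches[[length(branches) + 1L]] <- list(leaves = leafsets[[j]],
                                              len = t - birth[j])
    new_id <- length(leafsets) + 1L
    leafsets[[new_id]] <- c(leafsets[[i]], leafsets[[j]])
    birth[new_id] <- t
    active <- c(active[-pair], new_id)
  }
  lens <- vapply(branches, `[[`, numeric(1), "len")
  total_len <- sum(lens)
  S <- stats::rpois(1L, theta / 2 * total_len)
  S <- min(S, length_bp)  # infinite-sites needs distinct positions
  if (S > 0L) {
    hit <- sample.int(length(branches), S, replace = TRUE, prob = lens)
    pos <- sort(sample.int(length_bp, S))
    calls <- matrix(0L, nrow = n, ncol = S)
    for (s in seq_len(S)) calls[branches[[hit[s]]]$leaves, s] <- 1L
  } else {
    pos <- integer(0)
    calls <- matrix(0L, nrow = n, ncol = 0L)
  }
  m <- build_sim_matrix(calls, pos, chrom, aa_flip_frac)
  attr(m, "locus_bp") <- as.integer(length_bp)
  m
}

## Shared site-table builder for the simulators. The matrix is
## derived-coded; flipped sites record the derived allele as REF.
build_sim_matrix <- function(calls, pos, chrom, aa_flip_frac = 0,
                             sample_prefix = "sim_ind") {
  n <- nrow(calls)
  S <- ncol(calls)
  flip <- if (S > 0L && aa_flip_frac > 0) {
    stats::runif(S) < aa_flip_frac
  } else {
    rep(FALSE, S)
  }
  sites <- data.frame(
    chrom = rep(chrom, S), pos = as.integer(pos),
    variant_id = if (S) paste0("sim_", pos) else character(0),
    ref = ifelse(flip, "G", "A"), alt = ifelse(flip, "A", "G"),
    aa = rep("A", S),
    polarity = ifelse(flip, "REF_IS_DERIVED", "ALT_IS_DERIVED"),
    stringsAsFactors = FALSE
  )
  hap_matrix(calls, sites, paste0(sample_prefix, seq_len(n / 2L)))
}

#' Simulate structured populations under the Balding-Nichols model
#'
#' Unlinked sites. Per site, an ancestral frequency `p` is drawn uniformly
#' on `p_anc_range`; each population `k` then draws its own frequency
#' \deqn{p_k \sim Beta(p(1-F_k)/F_k,\; (1-p)(1-F_k)/F_k)}
#' (with `p_k = p` exactly when `F_k = 0`), and haplotype alleles are
#' Bernoulli(`p_k`). `E[(p_1-p_2)^2] = 2 F p(1-p)` for equal drift, so the
#' Hudson ratio-of-averages estimator recovers `F`. Sites monomorphic in
#' the pooled sample are dropped.
#'
#' @param n_pops number of populations.
#' @param F drift parameter per population (scalar recycled, each in `[0,1)`).
#' @param diploids_per_pop diploid sample size per population (scalar
#'   recycled).
#' @param n_sites number of sites to attempt (pooled-monomorphic dropped).
#' @param p_anc_range range of the ancestral frequency law (default
#'   `c(0.05, 0.95)`).
#' @param chrom chromosome label.
#' @param spacing_bp mean inter-site spacing used to lay out positions
#'   (sites are unlinked; positions are bookkeeping).
#' @return list with `matrix` (a [hap_matrix()], 1 = derived) and `panel`
#'   (a `pop_panel` with codes `POP1..POPk`, superpopulation equal to the
#'   population).
#' @export
simulate_structured <- function(n_pops, F, diploids_per_pop, n_sites,
                                p_anc_range = c(0.05, 0.95), chrom = "sim1",
                                spacing_bp = 100L) {
  F <- rep_len(F, n_pops)
  diploids <- rep_len(as.integer(diploids_per_pop), n_pops)
  stopifnot(all(F >= 0), all(F < 1), all(diploids >= 1), n_sites >= 1)
  n_hap_pop <- 2L * diploids
  n <- sum(n_hap_pop)

  p_anc <- stats::runif(n_sites, p_anc_range[1L], p_anc_range[2L])
  calls <- matrix(0L, nrow = n, ncol = n_sites)
  row0 <- c(0L, cumsum(n_hap_pop))
  for (k in seq_len(n_pops)) {
    if (F[k] == 0) {
      pk <- p_anc
    } else {
      shape_scale <- (1 - F[k]) / F[k]
      pk <- stats::rbeta(n_sites, p_anc * shape_scale,
                         (1 - p_anc) * shape_scale)
    }
    rows <- (row0[k] + 1L):row0[k + 1L]
    calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * n_sites, 1L, rep(pk, each = length(rows))),
      nrow = length(rows))
  }
  dc <- colSums(calls)
  keep <- dc > 0L & dc < n
  calls <- calls[, keep, drop = FALSE]
  S <- ncol(calls)
  pos <- sort(sample.int(n_sites * spacing_bp, S))

  pop_codes <- paste0("POP", seq_len(n_pops))
  sample_pop <- rep(pop_codes, times = diploids)
  panel <- data.frame(
    sample = paste0(tolower(sample_pop), "_s",
                    unlist(lapply(diploids, seq_len))),
    pop = sample_pop, super_pop = sample_pop, gender = "unknown",
    stringsAsFactors = FALSE
  )
  class(panel) <- c("pop_panel", "data.frame")

  m <- build_sim_matrix(calls, pos, chrom)
  m$sample_ids <- panel$sample
  attr(m, "locus_bp") <- as.integer(n_sites * spacing_bp)
  list(matrix = m, panel = panel)
}

#' Inject a hard selective sweep into a haplotype matrix
#'
#' Emulates the haplotype signature of a recent hard sweep by brute force:
#' `round(p_s * n)` haplotypes are designated derived carriers at a new
#' focal SNP, and their alleles over `span_bp` centred on the focal position
#' are overwritten with one shared template haplotype (a star-like
#' genealogy). Non-carriers are untouched. This gives exact control of the
#' derived frequency and of the shared-haplotype length — the two quantities
#' the haplotype statistics respond to.
#'
#' @param m a polarized [hap_matrix()] (the neutral background).
#' @param focal_pos physical position for the injected SNP (nudged up by 1
#'   if occupied).
#' @param p_s derived allele frequency of the sweep, in (0, 1).
#' @param span_bp length of the shared haplotype; `[focal_pos - span_bp/2,
#'   focal_pos + span_bp/2]` must lie inside the locus.
#' @return a [hap_matrix()] with the focal SNP added;
#'   `attr(, "sweep_carriers")` and `attr(, "sweep_pos")` record the truth.
#' @export
inject_sweep <- function(m, focal_pos, p_s, span_bp) {
  stopifnot(p_s > 0, p_s < 1, span_bp > 0)
  focal_pos <- as.integer(focal_pos)
  locus_bp <- attr(m, "locus_bp")
  if (is.null(locus_bp)) locus_bp <- max(m$sites$pos)
  lo <- focal_pos - span_bp / 2
  hi <- focal_pos + span_bp / 2
  if (lo < 1 || hi > locus_bp) {
    stop("sweep span [", lo, ", ", hi, "] exceeds locus [1, ", locus_bp, "]")
  }
  n <- n_haplotypes(m)
  n_car <- round(p_s * n)
  if (n_car < 2L || n_car > n - 2L) stop("p_s leaves fewer than 2 haplotypes in a class")
  carriers <- sample(n, n_car)

  in_span <- m$sites$pos >= lo & m$sites$pos <= hi
  calls <- m$calls
  if (any(in_span)) {
    template <- calls[carriers[1L], in_span]
    calls[carriers, in_span] <- matrix(template, nrow = n_car,
                                       ncol = sum(in_span), byrow = TRUE)
  }

  while (focal_pos %in% m$sites$pos) focal_pos <- focal_pos + 1L
  focal_col <- integer(n)
  focal_col[carriers] <- 1L
  focal_site <- data.frame(
    chrom = m$sites$chrom[1L], pos = as.integer(focal_pos),
    variant_id = paste0("sweep_", focal_pos), ref = "A", alt = "G",
    aa = "A", polarity = "ALT_IS_DERIVED", stringsAsFactors = FALSE
  )
  calls <- cbind(calls, focal_col, deparse.level = 0L)
  sites <- rbind(m$sites, focal_site)
  ord <- order(sites$pos)
  out <- hap_matrix(calls[, ord, drop = FALSE],
                    sites[ord, , drop = FALSE], m$sample_ids)
  attr(out, "locus_bp") <- locus_bp
  attr(out, "sweep_carriers") <- sort(carriers)
  attr(out, "sweep_pos") <- as.integer(focal_pos)
  out
}

#' Write a haplotype matrix and panel as VCF + panel fixture files
#'
#' Emits a VCF 4.2 file with phased GT calls and an `AA=` INFO tag per site
#' (1000 Genomes dialect), plus a tab-separated panel file. Sites whose
#' polarity is `REF_IS_DERIVED` are written with the derived allele as REF,
#' so [read_vcf()] followed by [polarize()] round-trips the matrix
#' bit-exactly.
#'
#' @param m a polarized [hap_matrix()].
#' @param panel a `pop_panel` covering the matrix samples (or `NULL` to
#'   write a single-population panel `SIM/SIM`).
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix (default `"fixture"`).
#' @return list with `vcf` and `panel` paths.
#' @export
write_fixture <- function(m, panel = NULL, out_dir, prefix = "fixture") {
  if (any(m$sites$polarity == "UNPOLARIZED")) {
    stop("write_fixture requires a polarized matrix")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(panel)) {
    panel <- data.frame(sample = m$sample_ids, pop = "SIM",
                        super_pop = "SIM", gender = "unknown",
                        stringsAsFactors = FALSE)
  }
  vcf_path <- file.path(out_dir, paste0(prefix, ".vcf"))
  panel_path <- file.path(out_dir, paste0(prefix, ".panel"))

  chrom <- if (n_sites(m) > 0L) m$sites$chrom[1L] else "sim1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan_synthetic",
    paste0("##contig=<ID=", chrom, ">"),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$sample_ids), collapse = "\t")
  )
  body <- character(n_sites(m))
  n_samp <- length(m$sample_ids)
  for (j in seq_len(n_sites(m))) {
    calls <- m$calls[, j]
    if (m$sites$polarity[j] == "REF_IS_DERIVED") calls <- 1L - calls
    gt <- paste(calls[seq(1L, 2L * n_samp, by = 2L)],
                calls[seq(2L, 2L * n_samp, by = 2L)], sep = "|")
    body[j] <- paste(c(m$sites$chrom[j], m$sites$pos[j],
                       m$sites$variant_id[j], m$sites$ref[j],
                       m$sites$alt[j], ".", "PASS",
                       paste0("AA=", m$sites$aa[j]), "GT", gt),
                     collapse = "\t")
  }
  writeLines(c(header, body), vcf_path)
  utils::write.table(panel, panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcf_path, panel = panel_path)
}
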