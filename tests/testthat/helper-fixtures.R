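# Shared fixture builders and brute-force oracles.

# Handmade hap_matrix: calls is n_hap x n_sites; metadata defaulted.
make_hm <- function(calls, pos = NULL, aa = NULL, polarity = NULL,
                    chrom = "chr4", ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  S <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  if (is.null(ref)) ref <- rep("A", S)
  if (is.null(alt)) alt <- rep("G", S)
  if (is.null(aa)) aa <- ref
  if (is.null(polarity)) {
    polarity <- ifelse(is.na(aa), "UNPOLARIZED",
                ifelse(aa == ref, "ALT_IS_DERIVED",
                ifelse(aa == alt, "REF_IS_DERIVED", "UNPOLARIZED")))
  }
  sites <- data.frame(chrom = rep(chrom, S), pos = as.integer(pos),
                      variant_id = if (S) paste0("v", pos) else character(0),
                      ref = ref, alt = alt,
                      aa = aa, polarity = polarity, stringsAsFactors = FALSE)
  hap_matrix(calls, sites, paste0("s", seq_len(nrow(calls) / 2L)))
}

# Random polymorphic matrix for property loops.
random_hm <- function(n_hap, n_sites, p = 0.5) {
  calls <- matrix(rbinom(n_hap * n_sites, 1L, p), n_hap, n_sites)
  make_hm(calls, pos = sort(sample.int(n_sites * 50L, n_sites)))
}

# Oracle: mean pairwise Hamming distance / C(n,2).
brute_pi <- function(calls) {
  n <- nrow(calls)
  tot <- 0
  for (a in seq_len(n)) for (b in seq_len(a - 1L)) {
    tot <- tot + sum(calls[a, ] != calls[b, ])
  }
  tot / (n * (n - 1) / 2)
}

# Oracle: fraction of carrier pairs identical over the k SNPs flanking core.
brute_ehh <- function(m, core, want, side, k) {
  rows <- which(m$calls[, core] == want)
  idx <- if (side == "RIGHT") (core + 1L):(core + k) else (core - 1L):(core - k)
  cnt <- 0L
  tot <- 0L
  for (a in seq_along(rows)) for (b in seq_len(a - 1L)) {
    tot <- tot + 1L
    if (all(m$calls[rows[a], idx] == m$calls[rows[b], idx])) cnt <- cnt + 1L
  }
  cnt / tot
}

# A small hand-written VCF exercising the read_vcf filters:
# 2 good biallelic SNPs, 1 multiallelic, 1 indel, 1 missing-GT site.
write_toy_vcf <- function(path, unphased = FALSE, dup_pos = FALSE) {
  gt2 <- if (unphased) "0/1" else "0|1"
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr4>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr4", "100", "rs1", "A", "G", ".", "PASS", "AA=A", "GT",
            "0|1", "1|1", "0|0"), collapse = "\t"),
    paste(c("chr4", "200", "rs2", "C", "T", ".", "PASS", "AA=T", "GT",
            gt2, "0|0", "1|0"), collapse = "\t"),
    paste(c("chr4", "300", "rs3", "G", "A,T", ".", "PASS", "AA=G", "GT",
            "0|1", "2|0", "0|0"), collapse = "\t"),
    paste(c("chr4", "400", "rs4", "AT", "A", ".", "PASS", "AA=A", "GT",
            "0|1", "0|0", "0|0"), collapse = "\t"),
    paste(c("chr4", if (dup_pos) "100" else "500", "rs5", "T", "C", ".",
            "PASS", "AA=T", "GT", "0|1", if (dup_pos) "0|0" else ".|.",
            "0|0"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

write_toy_panel <- function(path,
                            samples = c("S1", "S2", "S3", "S4"),
                            pops = c("P1", "P1", "P2", "P2"),
                            supers = c("SP1", "SP1", "SP2", "SP2")) {
  writeLines(c("sample\tpop\tsuper_pop\tgender",
               paste(samples, pops, supers, "unknown", sep = "\t")),
             path)
  path
}
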