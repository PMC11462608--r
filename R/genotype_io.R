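#' Read phased haplotypes from a VCF file
#'
#' Loads a VCF 4.x file into a [hap_matrix()]. Only biallelic SNPs
#' (single-base REF and ALT) are retained; multiallelic records, indels and
#' sites with any missing genotype are dropped and counted in the filter
#' log. Genotypes must be phased (`|` separator) — an unphased `/` call is
#' an error, not a filter. The ancestral allele is parsed from the INFO
#' `AA` key (first `|`-delimited token, 1000 Genomes dialect); sites enter
#' the matrix unpolarized and are oriented by [polarize()].
#'
#' @param path path to a VCF file (plain text, or bgzip with a tabix index
#'   when `region` is used on a compressed file).
#' @param region optional `"chrom:start-end"` string restricting the read.
#' @return A [hap_matrix()] with all sites `UNPOLARIZED`. The per-filter
#'   drop counts are attached as `attr(, "filter_log")`.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  param <- VariantAnnotation::ScanVcfParam()
  use_tabix <- !is.null(region) && grepl("\\.gz$", path) &&
    file.exists(paste0(path, ".tbi"))
  if (use_tabix) {
    reg <- parse_region(region)
    param <- VariantAnnotation::ScanVcfParam(which = GenomicRanges::GRanges(
      reg$chrom, IRanges::IRanges(reg$start, reg$end)))
  }
  vcf <- suppressWarnings(
    VariantAnnotation::readVcf(path, genome = "unknown", param = param))

  chrom <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf)))
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))

  if (!is.null(region) && !use_tabix) {
    reg <- parse_region(region)
    keep_reg <- chrom == reg$chrom & pos >= reg$start & pos <= reg$end
  } else {
    keep_reg <- rep(TRUE, length(pos))
  }

  bases <- c("A", "C", "G", "T")
  is_multi <- n_alt != 1L
  is_snp <- !is_multi & ref %in% bases & !is.na(alt) & alt %in% bases
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  miss <- apply(gt, 1L, function(g) any(g %in% c(".", "./.", ".|.") | grepl("\\.", g)))

  log <- c(
    multiallelic    = sum(is_multi & keep_reg),
    non_snp         = sum(!is_multi & !is_snp & keep_reg),
    missing_gt      = sum(is_snp & miss & keep_reg),
    outside_region  = sum(!keep_reg)
  )
  keep <- keep_reg & is_snp & !miss

  bad_sep <- keep & apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)))
  if (any(bad_sep)) {
    i <- which(bad_sep)[1L]
    stop("unphased genotype ('/' separator) at ", chrom[i], ":", pos[i])
  }

  chrom <- chrom[keep]; pos <- pos[keep]; ids <- ids[keep]
  ref <- ref[keep]; alt <- alt[keep]
  gt <- gt[keep, , drop = FALSE]

  if (length(unique(chrom)) > 1L) {
    stop("VCF spans multiple chromosomes; use `region` to select one")
  }
  if (anyDuplicated(pos)) {
    stop("duplicate position(s): ",
         paste(utils::head(pos[duplicated(pos)], 3L), collapse = ", "))
  }

  aa <- parse_aa(vcf, keep)

  ord <- order(pos)
  samples <- colnames(gt)
  calls <- gt_to_calls(gt[ord, , drop = FALSE])
  sites <- data.frame(
    chrom = chrom[ord], pos = pos[ord],
    variant_id = ifelse(is.na(ids[ord]) | ids[ord] == ".",
                        paste0("var_", pos[ord]), ids[ord]),
    ref = ref[ord], alt = alt[ord], aa = aa[ord],
    polarity = rep("UNPOLARIZED", sum(keep)),
    stringsAsFactors = FALSE
  )
  m <- hap_matrix(calls, sites, samples)
  attr(m, "filter_log") <- log
  m
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end', got: ", region)
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

## INFO AA, first "|"-delimited token; NA when absent or uninformative.
parse_aa <- function(vcf, keep) {
  info <- VariantAnnotation::info(vcf)
  if (!"AA" %in% names(info)) return(rep(NA_character_, sum(keep)))
  aa <- info$AA
  if (methods::is(aa, "List") || is.list(aa)) {
    aa <- vapply(as.list(aa), function(x)
      if (length(x) == 0L) NA_character_ else as.character(x[[1L]]),
      character(1L))
  }
  aa <- as.character(aa)[keep]
  aa <- vapply(strsplit(aa, "|", fixed = TRUE), function(x)
    if (length(x) == 0L) NA_character_ else x[[1L]], character(1L))
  aa[aa %in% c("", ".", "-", "N", "n")] <- NA_character_
  aa
}

## variants x samples phased GT strings -> haplotype x site 0/1 matrix
gt_to_calls <- function(gt) {
  n_var <- nrow(gt); n_samp <- ncol(gt)
  calls <- matrix(0L, nrow = 2L * n_samp, ncol = n_var)
  if (n_var == 0L) return(calls)
  for (j in seq_len(n_var)) {
    parts <- strsplit(gt[j, ], "|", fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens != 2L)) stop("malformed GT at variant row ", j)
    al <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(al) || any(al > 1L | al < 0L)) {
      stop("non-biallelic allele index in GT at variant row ", j)
    }
    calls[, j] <- al
  }
  calls
}

#' Read a sample-to-population panel file
#'
#' Reads a tab-separated panel in the 1000 Genomes integrated-panel dialect:
#' a header line and columns `sample`, `pop`, `super_pop` (extra columns such
#' as `gender` are carried along).
#'
#' @param path path to the panel TSV.
#' @return A data.frame of class `pop_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "pop", "super_pop")
  if (!all(need %in% names(df))) {
    stop("panel is missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$sample)) {
    stop("duplicated sample id(s) in panel: ",
         paste(utils::head(df$sample[duplicated(df$sample)], 3L),
               collapse = ", "))
  }
  class(df) <- c("pop_panel", "data.frame")
  df
}

#' Count panel samples per population
#'
#' @param panel a [read_panel()] result.
#' @param codes optional character vector of codes to count (unknown codes
#'   count 0); default: all codes present.
#' @param by `"super_pop"` or `"pop"`.
#' @return named integer vector of sample counts.
#' @export
panel_counts <- function(panel, codes = NULL, by = c("super_pop", "pop")) {
  by <- match.arg(by)
  tab <- table(panel[[by]])
  if (is.null(codes)) codes <- names(tab)
  out <- integer(length(codes))
  names(out) <- codes
  hit <- codes %in% names(tab)
  out[hit] <- as.integer(tab[codes[hit]])
  out
}

#' Orient alleles as ancestral/derived
#'
#' Uses each site's ancestral-allele annotation to orient the call matrix so
#' that 1 codes the derived allele. When AA equals REF the column is already
#' derived-coded (`ALT_IS_DERIVED`); when AA equals ALT the column's 0/1
#' values are complemented (`REF_IS_DERIVED`). Sites whose AA is missing or
#' matches neither allele are dropped when `drop_unpolarized`, otherwise kept
#' as `UNPOLARIZED` (and excluded from statistics that need polarity).
#'
#' Matching is case-insensitive by default; the 1000 Genomes dialect encodes
#' low-confidence ancestral calls in lowercase, and `strict_uppercase = TRUE`
#' demotes those to missing.
#'
#' @param m a [hap_matrix()] with ALT-coded calls (fresh from [read_vcf()]).
#' @param drop_unpolarized drop sites that cannot be oriented.
#' @param strict_uppercase treat lowercase AA as missing.
#' @return A polarized [hap_matrix()].
#' @export
polarize <- function(m, drop_unpolarized = FALSE, strict_uppercase = FALSE) {
  if (n_sites(m) == 0L) return(m)
  aa <- m$sites$aa
  if (strict_uppercase) aa[!is.na(aa) & aa != toupper(aa)] <- NA_character_
  aa_up <- toupper(aa)
  pol <- rep("UNPOLARIZED", n_sites(m))
  pol[!is.na(aa_up) & aa_up == m$sites$ref] <- "ALT_IS_DERIVED"
  pol[!is.na(aa_up) & aa_up == m$sites$alt] <- "REF_IS_DERIVED"

  calls <- m$calls
  flip <- which(pol == "REF_IS_DERIVED")
  if (length(flip)) calls[, flip] <- 1L - calls[, flip]

  sites <- m$sites
  sites$polarity <- pol
  out <- hap_matrix(calls, sites, m$sample_ids)
  if (drop_unpolarized) {
    keep <- pol != "UNPOLARIZED"
    dropped <- sum(!keep)
    out <- site_subset(out, keep)
    attr(out, "filter_log") <- c(unpolarized_dropped = dropped)
  }
  out
}

#' Subset haplotypes to one population and filter sites
#'
#' Keeps the haplotype rows of samples assigned to `pop` (a population or
#' superpopulation code from the panel), recomputes per-site allele counts on
#' the subset, and applies site filters: monomorphic sites are dropped when
#' `drop_monomorphic`, and sites with minor allele frequency `<= maf_min` are
#' dropped when `maf_min > 0` (strict `>` retained, matching a ">5%" rule).
#'
#' @param m a [hap_matrix()].
#' @param panel a [read_panel()] result.
#' @param pop population or superpopulation code; must exist in the panel.
#' @param maf_min minor-allele-frequency floor in `[0, 0.5)`; 0 disables.
#' @param drop_monomorphic drop sites fixed in the subset.
#' @return A filtered [hap_matrix()] with `attr(, "filter_log")`.
#' @export
subset_and_filter <- function(m, panel, pop, maf_min = 0,
                              drop_monomorphic = FALSE) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  ids <- resolve_pop(panel, pop)
  missing <- setdiff(ids, m$sample_ids)
  if (length(missing)) {
    stop("panel sample(s) not present in matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  out <- sample_subset(m, ids)
  n <- n_haplotypes(out)
  dc <- derived_counts(out)
  keep <- rep(TRUE, n_sites(out))
  mono_dropped <- 0L
  if (drop_monomorphic) {
    mono <- dc == 0L | dc == n
    mono_dropped <- sum(mono)
    keep <- keep & !mono
  }
  maf_dropped <- 0L
  if (maf_min > 0) {
    maf <- pmin(dc, n - dc) / n
    low <- !(maf > maf_min)
    maf_dropped <- sum(keep & low)
    keep <- keep & !low
  }
  out <- site_subset(out, keep)
  attr(out, "filter_log") <- c(monomorphic_dropped = mono_dropped,
                               maf_dropped = maf_dropped)
  out
}

## Resolve a code against pop, then super_pop; error when unknown.
resolve_pop <- function(panel, pop) {
  if (pop %in% panel$pop) return(panel$sample[panel$pop == pop])
  if (pop %in% panel$super_pop) return(panel$sample[panel$super_pop == pop])
  stop("population code not in panel: ", pop)
}
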