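#' Construct a haplotype matrix
#'
#' The central container of the package: a set of phased haplotypes over an
#' ordered run of biallelic SNPs. Rows are haplotypes (two consecutive rows
#' per diploid sample), columns are sites. Calls are strictly 0/1 — missing
#' genotypes are rejected at construction, never imputed.
#'
#' @param calls integer matrix, `n_haplotypes x n_sites`, values in `{0, 1}`.
#'   Column `j` encodes the ALT allele (1) at site `j`, or the derived allele
#'   once the matrix has been polarized (see [polarize()]).
#' @param sites data.frame with one row per site and columns `chrom`, `pos`
#'   (1-based bp, strictly increasing), `variant_id`, `ref`, `alt`, `aa`
#'   (ancestral allele, `NA` allowed) and `polarity` (one of
#'   `"ALT_IS_DERIVED"`, `"REF_IS_DERIVED"`, `"UNPOLARIZED"`).
#' @param sample_ids character vector, one id per *pair* of haplotype rows;
#'   rows `2i - 1` and `2i` belong to sample `i`.
#' @return An object of class `hap_matrix`.
#' @seealso [read_vcf()], [polarize()], [subset_and_filter()]
#' @export
hap_matrix <- function(calls, sites, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- as.data.frame(sites)
  rownames(sites) <- NULL
  dimnames(calls) <- NULL
  validate_sites(sites, n_sites = ncol(calls))
  if (nrow(calls) != 2L * length(sample_ids)) {
    stop("n_haplotypes (", nrow(calls), ") must equal 2 x n_samples (",
         2L * length(sample_ids), ")")
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (ncol(calls) > 0L && (anyNA(calls) || !all(calls == 0L | calls == 1L))) {
    stop("calls must be 0/1 with no missing values")
  }
  structure(
    list(calls = calls, sites = sites, sample_ids = as.character(sample_ids)),
    class = "hap_matrix"
  )
}

POLARITIES <- c("ALT_IS_DERIVED", "REF_IS_DERIVED", "UNPOLARIZED")

validate_sites <- function(sites, n_sites) {
  need <- c("chrom", "pos", "variant_id", "ref", "alt", "aa", "polarity")
  if (!all(need %in% names(sites))) {
    stop("sites is missing columns: ",
         paste(setdiff(need, names(sites)), collapse = ", "))
  }
  if (nrow(sites) != n_sites) stop("sites rows must match ncol(calls)")
  if (n_sites == 0L) return(invisible(sites))
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (length(unique(sites$chrom)) > 1L) {
    stop("a hap_matrix holds a single chromosome")
  }
  if (is.unsorted(sites$pos, strictly = TRUE)) {
    stop("site positions must be strictly increasing (duplicates rejected)")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases)) {
    stop("ref/alt must be single bases in {A,C,G,T}")
  }
  if (any(sites$ref == sites$alt)) stop("ref must differ from alt")
  if (!all(sites$polarity %in% POLARITIES)) {
    stop("unknown polarity value")
  }
  pol <- sites$polarity != "UNPOLARIZED"
  if (any(pol)) {
    ok <- toupper(sites$aa[pol]) == sites$ref[pol] |
      toupper(sites$aa[pol]) == sites$alt[pol]
    if (anyNA(ok) || !all(ok)) {
      stop("polarized sites must have aa equal to ref or alt")
    }
  }
  invisible(sites)
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("<hap_matrix> ", n_haplotypes(x), " haplotypes (",
      length(x$sample_ids), " samples) x ", n_sites(x), " sites",
      sep = "")
  if (n_sites(x) > 0L) {
    cat(" | ", unique(x$sites$chrom), ":", min(x$sites$pos), "-",
        max(x$sites$pos), sep = "")
    np <- sum(x$sites$polarity != "UNPOLARIZED")
    cat(" | ", np, "/", n_sites(x), " polarized", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of haplotypes / sites in a haplotype matrix
#' @param m a [hap_matrix()]
#' @return integer count.
#' @export
n_haplotypes <- function(m) nrow(m$calls)

#' @rdname n_haplotypes
#' @export
n_sites <- function(m) ncol(m$calls)

#' Per-site derived (or ALT) allele counts
#'
#' Column sums of the call matrix: the number of haplotypes carrying the
#' 1-coded allele at each site. After [polarize()] the 1-allele is the
#' derived allele at polarized sites.
#'
#' @param m a [hap_matrix()]
#' @return integer vector of length `n_sites(m)`.
#' @export
derived_counts <- function(m) {
  if (n_sites(m) == 0L) return(integer(0))
  as.integer(colSums(m$calls))
}

## Internal: keep a subset of site columns, preserving order.
site_subset <- function(m, keep) {
  hap_matrix(m$calls[, keep, drop = FALSE],
             m$sites[keep, , drop = FALSE],
             m$sample_ids)
}

## Internal: keep a subset of samples (haplotype row pairs).
sample_subset <- function(m, sample_keep) {
  idx <- which(m$sample_ids %in% sample_keep)
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  hap_matrix(m$calls[rows, , drop = FALSE], m$sites, m$sample_ids[idx])
}
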