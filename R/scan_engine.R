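#' Build a genome-wide empirical distribution
#'
#' Wraps a vector of genome-wide statistic values (NA dropped) together with
#' the tail in which extremeness lives: `LOWER` (more negative is more
#' extreme, e.g. Tajima's D, Fay and Wu's H, pi), `UPPER` (PBS), or
#' `TWO_SIDED_ABS` (standardized iHS/nSL, extremeness by absolute value).
#'
#' @param values numeric vector of genome-wide values.
#' @param tail one of `"LOWER"`, `"UPPER"`, `"TWO_SIDED_ABS"`.
#' @param statistic optional statistic name (bookkeeping).
#' @return object of class `empirical_dist`.
#' @export
empirical_distribution <- function(values,
                                   tail = c("LOWER", "UPPER", "TWO_SIDED_ABS"),
                                   statistic = "statistic") {
  tail <- match.arg(tail)
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empirical distribution needs >= 1 finite value")
  structure(list(statistic = statistic, tail = tail, values = values,
                 N = length(values)),
            class = "empirical_dist")
}

#' @export
print.empirical_dist <- function(x, ...) {
  cat("<empirical_dist> ", x$statistic, ": N = ", x$N, ", tail = ", x$tail,
      "\n", sep = "")
  invisible(x)
}

## Extremeness score: larger = more extreme, uniform across tails.
extremeness <- function(values, tail) {
  switch(tail,
         LOWER = -values,
         UPPER = values,
         TWO_SIDED_ABS = abs(values))
}

#' Empirical p-value against a genome-wide distribution
#'
#' The proportion of genome-wide values as or more extreme than the observed
#' one. Ties count as extreme, so a value belonging to the distribution
#' always has `p >= 1/N`, and the most extreme value scores exactly `1/N`.
#'
#' @param dist an [empirical_distribution()].
#' @param observed finite value(s) on the distribution's scale (vectorized).
#' @return p-value(s) in `[1/N, 1]` for member values.
#' @export
empirical_pvalue <- function(dist, observed) {
  stopifnot(inherits(dist, "empirical_dist"))
  if (any(!is.finite(observed))) stop("observed must be finite")
  ev <- extremeness(dist$values, dist$tail)
  eo <- extremeness(observed, dist$tail)
  vapply(eo, function(x) sum(ev >= x) / dist$N, numeric(1))
}

#' Top-quantile cutoffs of an empirical distribution
#'
#' For each fraction `f`, the threshold is the `ceil(f * N)`-th most extreme
#' value: the least extreme value still inside the top-`f` set, so comparing
#' `as-or-more extreme than threshold` flags (at least, under ties exactly)
#' `ceil(f * N)` values.
#'
#' @param dist an [empirical_distribution()].
#' @param fractions numeric fractions in (0, 1); each must satisfy
#'   `N >= 1/f` so the quantile is resolvable.
#' @return named numeric vector, one threshold per fraction.
#' @export
top_cutoffs <- function(dist, fractions = c(0.05, 0.01)) {
  stopifnot(inherits(dist, "empirical_dist"))
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("fractions must lie strictly in (0, 1)")
  }
  bad <- fractions < 1 / dist$N
  if (any(bad)) {
    stop("N = ", dist$N, " cannot resolve fraction ",
         paste(fractions[bad], collapse = ", "))
  }
  ev <- sort(extremeness(dist$values, dist$tail), decreasing = TRUE)
  out <- vapply(fractions, function(f) {
    k <- ceiling(f * dist$N)
    thr_e <- ev[k]
    # map the extremeness threshold back to the statistic's scale
    switch(dist$tail, LOWER = -thr_e, UPPER = thr_e, TWO_SIDED_ABS = thr_e)
  }, numeric(1))
  names(out) <- paste0("top", fractions * 100, "pct")
  out
}

#' Flag values beyond the top-5% / top-1% cutoffs
#'
#' @param dist an [empirical_distribution()].
#' @param observed values to flag.
#' @return data.frame with `value`, `p`, `top5`, `top1`.
#' @export
flag_outliers <- function(dist, observed) {
  cuts <- top_cutoffs(dist, c(0.05, 0.01))
  eo <- extremeness(observed, dist$tail)
  e5 <- extremeness(cuts[["top5pct"]], dist$tail)
  e1 <- extremeness(cuts[["top1pct"]], dist$tail)
  data.frame(value = observed,
             p = empirical_pvalue(dist, observed),
             top5 = eo >= e5, top1 = eo >= e1)
}

#' Per-population allele frequency report
#'
#' Reports, for each requested variant, the frequency of the requested
#' allele (`REF`, `ALT`, or `DERIVED`) in every superpopulation (and
#' optionally every population) of the panel, with count numerator and
#' denominator. Variants absent from the matrix are reported with `NA`
#' frequency, not dropped.
#'
#' @param m a [hap_matrix()].
#' @param panel a [read_panel()] result.
#' @param variants character vector of variant ids, or integer positions.
#' @param allele `"REF"`, `"ALT"` or `"DERIVED"` (requires polarized sites).
#' @param by `"super_pop"` (default) or `"pop"`.
#' @return data.frame with `variant_id, pos, group, n_allele, n_total, freq`.
#' @export
allele_frequency_report <- function(m, panel, variants,
                                    allele = c("DERIVED", "REF", "ALT"),
                                    by = c("super_pop", "pop")) {
  allele <- match.arg(allele)
  by <- match.arg(by)
  groups <- unique(panel[[by]])
  if (is.numeric(variants)) {
    idx <- match(as.integer(variants), m$sites$pos)
    labels <- paste0("pos_", variants)
  } else {
    idx <- match(variants, m$sites$variant_id)
    labels <- variants
  }
  rows <- list()
  for (v in seq_along(idx)) {
    j <- idx[v]
    for (g in groups) {
      ids <- panel$sample[panel[[by]] == g]
      ids <- intersect(ids, m$sample_ids)
      hap_rows <- as.vector(rbind(2L * match(ids, m$sample_ids) - 1L,
                                  2L * match(ids, m$sample_ids)))
      n_total <- length(hap_rows)
      if (is.na(j) || n_total == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = labels[v], pos = if (is.na(j)) NA_integer_ else m$sites$pos[j],
          group = g, n_allele = NA_integer_, n_total = n_total,
          freq = NA_real_, stringsAsFactors = FALSE)
        next
      }
      calls <- m$calls[hap_rows, j]
      ones <- sum(calls)  # count of the 1-coded (ALT, or derived) allele
      n_allele <- switch(allele,
        DERIVED = {
          if (m$sites$polarity[j] == "UNPOLARIZED") NA_integer_ else ones
        },
        ALT = if (m$sites$polarity[j] == "REF_IS_DERIVED") n_total - ones else ones,
        REF = if (m$sites$polarity[j] == "REF_IS_DERIVED") ones else n_total - ones
      )
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = labels[v], pos = m$sites$pos[j], group = g,
        n_allele = n_allele, n_total = n_total,
        freq = n_allele / n_total, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Join statistic tracks over a region and attach outlier flags
#'
#' Inner-joins two or more statistic tracks (data.frames sharing either a
#' `pos` column for per-variant tracks or `start`/`end` columns for window
#' tracks) restricted to `region`, and optionally attaches empirical
#' p-values and top-5%/1% flags from supplied genome-wide distributions.
#'
#' @param tracks named list of data.frames; each must carry a `chrom`
#'   column and either `pos` or `start`+`end`.
#' @param region `"chrom:start-end"` string.
#' @param dists optional named list of [empirical_distribution()]s; names
#'   must be `"track.column"` identifying the value column to flag.
#' @return merged data.frame, possibly with `<name>.p`, `<name>.top5`,
#'   `<name>.top1` columns appended.
#' @export
region_report <- function(tracks, region, dists = NULL) {
  reg <- parse_region(region)
  keyed <- lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    if (!"chrom" %in% names(tr)) stop("track '", nm, "' lacks a chrom column")
    if (any(tr$chrom != reg$chrom)) {
      tr <- tr[tr$chrom == reg$chrom, , drop = FALSE]
      if (nrow(tracks[[nm]]) > 0L && nrow(tr) == 0L) {
        stop("track '", nm, "' has no rows on chromosome ", reg$chrom)
      }
    }
    if ("pos" %in% names(tr)) {
      tr <- tr[tr$pos >= reg$start & tr$pos <= reg$end, , drop = FALSE]
      key <- c("chrom", "pos")
    } else if (all(c("start", "end") %in% names(tr))) {
      tr <- tr[tr$start < reg$end & tr$end > reg$start, , drop = FALSE]
      key <- c("chrom", "start", "end")
    } else {
      stop("track '", nm, "' needs pos or start/end columns")
    }
    val_cols <- setdiff(names(tr), key)
    names(tr)[match(val_cols, names(tr))] <- paste0(nm, ".", val_cols)
    list(df = tr, key = key)
  })
  keys <- unique(vapply(keyed, function(k) paste(k$key, collapse = ","),
                        character(1)))
  if (length(keys) > 1L) {
    stop("tracks mix per-variant and per-window coordinates")
  }
  out <- Reduce(function(a, b) merge(a, b, by = keyed[[1L]]$key),
                lapply(keyed, `[[`, "df"))
  if (!is.null(dists)) {
    for (nm in names(dists)) {
      if (!nm %in% names(out)) next
      v <- out[[nm]]
      fin <- is.finite(v)
      fl <- flag_outliers(dists[[nm]], v[fin])
      out[[paste0(nm, ".p")]] <- NA_real_
      out[[paste0(nm, ".top5")]] <- NA
      out[[paste0(nm, ".top1")]] <- NA
      out[[paste0(nm, ".p")]][fin] <- fl$p
      out[[paste0(nm, ".top5")]][fin] <- fl$top5
      out[[paste0(nm, ".top1")]][fin] <- fl$top1
    }
  }
  ord <- if ("pos" %in% names(out)) order(out$pos) else order(out$start)
  out[ord, , drop = FALSE]
}

#' Write a statistic track as TSV or BED3+score
#'
#' @param track a data.frame from one of the scan functions.
#' @param path output path.
#' @param format `"tsv"` (all columns) or `"bed"` (BED3 + one score column;
#'   BED is 0-based half-open, so `start - 1` for per-variant tracks).
#' @param score_col column to use as the BED score.
#' @return invisibly, the path.
#' @export
write_track <- function(track, path, format = c("tsv", "bed"),
                        score_col = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(track, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(score_col)) stop("BED export needs score_col")
    if ("pos" %in% names(track)) {
      bed <- data.frame(track$chrom, track$pos - 1L, track$pos,
                        track[[score_col]])
    } else {
      bed <- data.frame(track$chrom, track$start - 1L, track$end - 1L,
                        track[[score_col]])
    }
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
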