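#' Per-phylum summary of ZCC indexes
#'
#' Aggregates a per-genome results table into one row per phylum: sign
#' counts and percentages, mean and SD of the (non-degenerate) ZCC values,
#' the majority-sign group label, and mean GC content / mean SGD split by
#' ZCC sign when those columns are present. Only phyla with strictly more
#' than `min_n` genomes are reported, guarding conclusions against small
#' samples; indexes exactly zero are counted as neither sign and reported
#' in their own column.
#'
#' @param records Results data frame (see [write_results_table()]) with a
#'   `phylum` column; `degenerate` may be missing (treated as all-finite).
#' @param min_n Keep phyla with `n_total > min_n` (default 15).
#' @return A data frame of class `phylum_summary`, one row per phylum,
#'   ordered by decreasing `n_total`: columns `phylum`, `n_total`,
#'   `n_negative`, `n_positive`, `n_zero`, `n_degenerate`, `pct_negative`,
#'   `pct_positive` (percent of total, one decimal), `mean_zcc`, `sd_zcc`,
#'   `group` (`"P-ZCC"`, `"N-ZCC"` or `NA` on a tie), `mean_gc_content`,
#'   `mean_sgd_pos`, `mean_sgd_neg`.
#' @export
summarize_phylum <- function(records, min_n = 15L) {
  if (nrow(records) == 0L)
    return(structure(data.frame(), class = c("phylum_summary", "data.frame")))
  if (is.null(records$degenerate)) records$degenerate <- FALSE
  records$degenerate[is.na(records$degenerate)] <- FALSE
  rows <- lapply(split(records, records$phylum), function(g) {
    ok <- !g$degenerate & !is.na(g$zcc)
    v <- g$zcc[ok]
    n_pos <- sum(v > 0); n_neg <- sum(v < 0); n_zero <- sum(v == 0)
    data.frame(
      phylum = g$phylum[1],
      n_total = nrow(g),
      n_negative = n_neg, n_positive = n_pos, n_zero = n_zero,
      n_degenerate = sum(!ok),
      pct_negative = round(100 * n_neg / nrow(g), 1),
      pct_positive = round(100 * n_pos / nrow(g), 1),
      mean_zcc = if (length(v)) mean(v) else NA_real_,
      sd_zcc = if (length(v) > 1L) stats::sd(v) else NA_real_,
      group = classify_group(n_pos, n_neg),
      mean_gc_content = if (!is.null(g$gc_content))
        mean(g$gc_content, na.rm = TRUE) else NA_real_,
      mean_sgd_pos = mean_or_na(g$sgd_fraction[ok][v > 0]),
      mean_sgd_neg = mean_or_na(g$sgd_fraction[ok][v < 0]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_total > min_n, , drop = FALSE]
  out <- out[order(-out$n_total), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phylum_summary", "data.frame")
  out
}

mean_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v)) mean(v) else NA_real_
}

#' Majority-sign group label for a phylum
#'
#' A phylum is `"P-ZCC"` when more of its genomes have positive than
#' negative ZCC indexes, `"N-ZCC"` in the opposite case; an exact tie is
#' unclassifiable (`NA` with a warning).
#'
#' @param n_positive,n_negative Sign counts over the non-degenerate genomes.
#' @return `"P-ZCC"`, `"N-ZCC"` or `NA_character_`.
#' @export
classify_group <- function(n_positive, n_negative) {
  if (n_positive + n_negative == 0L)
    stop("cannot classify: no genome with a defined ZCC sign", call. = FALSE)
  if (n_positive > n_negative) return("P-ZCC")
  if (n_negative > n_positive) return("N-ZCC")
  warning("sign tie: phylum left unclassified")
  NA_character_
}

#' Tukey-fence outliers
#'
#' Flags values strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, the
#' standard boxplot whisker rule. Quartiles use interpolated order
#' statistics (`stats::quantile` type 7, the mainstream default); the
#' convention is switchable since borderline outliers depend on it.
#'
#' @param values Numeric vector, length >= 4.
#' @param ids Optional identifiers parallel to `values`.
#' @param qtype Quantile type passed to [stats::quantile()].
#' @return A `tukey_fences` object: `q1`, `q3`, `iqr`, `lower`, `upper`,
#'   `outlier_ids`, `outlier_values`, `is_outlier` (logical per input).
#' @examples
#' tukey_outliers(c(1:9, 100))$outlier_values  # 100
#' @export
tukey_outliers <- function(values, ids = NULL, qtype = 7L) {
  values <- as.numeric(values)
  if (sum(!is.na(values)) < 4L)
    stop("need at least 4 values for quartile fences", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE,
                       names = FALSE, type = qtype)
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- q[2] + 1.5 * iqr
  out <- !is.na(values) & (values < lower | values > upper)
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 lower = lower, upper = upper,
                 outlier_ids = ids[out], outlier_values = values[out],
                 is_outlier = out),
            class = "tukey_fences")
}

#' @export
print.tukey_fences <- function(x, ...) {
  cat(sprintf("<tukey_fences> Q1 = %.4g, Q3 = %.4g, fences [%.4g, %.4g]\n",
              x$q1, x$q3, x$lower, x$upper))
  cat(sprintf("  %d outlier(s)%s\n", length(x$outlier_ids),
              if (length(x$outlier_ids))
                paste0(": ", paste(x$outlier_ids, collapse = ", ")) else ""))
  invisible(x)
}

#' DE/PC polymerase cross-tabulation
#'
#' Classifies each genome with known polymerase metadata into the PC group
#' (PolC present, regardless of accompanying DnaE subtypes — the subtypes
#' DnaE1-DnaE3 and DnaEX are united as DnaE) or the DE group (DnaE only),
#' and tabulates counts per phylum in two variants: all matched genomes,
#' and with a supplied outlier list removed (mirroring boxplot-outlier
#' exclusion). Genomes without matching metadata, or with unknown PolC
#' status, are excluded with a warning.
#'
#' @param records Results data frame (needs `genome_id`).
#' @param metadata Data frame from [read_metadata()].
#' @param outlier_ids Genome ids to drop in the second variant.
#' @return A `polymerase_crosstab`: matrices `all` and `no_outliers`
#'   (rows `DE`, `PC`; one column per phylum), plus `n_matched` and
#'   `n_unmatched`.
#' @export
polymerase_crosstab <- function(records, metadata, outlier_ids = character()) {
  m <- match(records$genome_id, metadata$genome_id)
  unmatched <- is.na(m)
  if (any(unmatched))
    warning(sprintf("%d genome(s) without polymerase metadata excluded",
                    sum(unmatched)))
  keep <- !unmatched
  ids <- records$genome_id[keep]
  meta <- metadata[m[keep], , drop = FALSE]
  known <- !is.na(meta$has_polc)
  if (any(!known))
    warning(sprintf("%d genome(s) with unknown PolC status excluded",
                    sum(!known)))
  ids <- ids[known]; meta <- meta[known, , drop = FALSE]
  grp <- factor(ifelse(meta$has_polc, "PC", "DE"), levels = c("DE", "PC"))
  phy <- factor(meta$phylum, levels = sort(unique(meta$phylum)))
  tab_all <- table(grp, phy)
  keep2 <- !ids %in% outlier_ids
  tab_out <- table(grp[keep2], phy[keep2])
  structure(list(all = unclass(as.matrix(tab_all)),
                 no_outliers = unclass(as.matrix(tab_out)),
                 n_matched = length(ids),
                 n_unmatched = sum(unmatched)),
            class = "polymerase_crosstab")
}

#' @export
print.polymerase_crosstab <- function(x, ...) {
  cat(sprintf("<polymerase_crosstab> %d genomes with metadata (%d unmatched)\n",
              x$n_matched, x$n_unmatched))
  cells <- matrix(sprintf("%d/%d", x$all, x$no_outliers),
                  nrow = nrow(x$all), dimnames = dimnames(x$all))
  print(cells, quote = FALSE)
  cat("  (cell = all genomes / outliers removed)\n")
  invisible(x)
}

#' Mean SGD per phylum, split by ZCC sign
#'
#' For each phylum, the mean leading-strand gene fraction of the genomes
#' with positive and with negative ZCC indexes; a sign class with no
#' genomes yields `NA` (some phyla have no positive-ZCC genomes at all).
#'
#' @param records Results data frame with `phylum`, `zcc`, `sgd_fraction`.
#' @return Data frame `phylum`, `mean_sgd_positive`, `mean_sgd_negative`,
#'   `n_positive`, `n_negative`.
#' @export
sgd_by_sign <- function(records) {
  rows <- lapply(split(records, records$phylum), function(g) {
    ok <- !is.na(g$zcc) & !is.na(g$sgd_fraction)
    pos <- g$sgd_fraction[ok & g$zcc > 0]
    neg <- g$sgd_fraction[ok & g$zcc < 0]
    data.frame(phylum = g$phylum[1],
               mean_sgd_positive = mean_or_na(pos),
               mean_sgd_negative = mean_or_na(neg),
               n_positive = length(pos), n_negative = length(neg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
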