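#' Pearson correlation coefficient
#'
#' Hand-rolled Pearson r,
#' \deqn{r = \frac{\sum_i (a_i - \bar a)(b_i - \bar b)}
#'                {\sqrt{\sum_i (a_i - \bar a)^2 \sum_i (b_i - \bar b)^2}},}
#' computed with a one-pass sum formulation (R's long-double accumulating
#' `sum()`), then clamped to `[-1, 1]` to absorb last-ulp overshoot. This is
#' the statistic at the core of the ZCC index and is therefore implemented
#' here rather than delegated; `stats::cor` is used only as an independent
#' cross-check in the test suite.
#'
#' Degeneracy (a track with zero variance) is detected exactly, by constancy
#' of the track, not by a floating-point threshold.
#'
#' @param a,b Numeric vectors of equal length `>= 2`.
#' @param strict When `TRUE`, degenerate input raises an error; otherwise
#'   `NA_real_` is returned.
#' @return The correlation in `[-1, 1]`, or `NA_real_` when degenerate (in
#'   lenient mode).
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson_r <- function(a, b, strict = FALSE) {
  n <- length(a)
  if (length(b) != n) stop("tracks have different lengths", call. = FALSE)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == a[1L]) || all(b == b[1L])) {
    if (strict) stop("degenerate track: zero variance", call. = FALSE)
    return(NA_real_)
  }
  ma <- sum(a) / n; mb <- sum(b) / n
  # centered one-pass sums; centering first keeps the products small
  da <- a - ma; db <- b - mb
  r <- sum(da * db) / sqrt(sum(da * da) * sum(db * db))
  max(-1, min(1, r))
}

new_zcc_result <- function(genome_id, value, n_points, degenerate, track_pair) {
  structure(list(genome_id = genome_id, value = value, n_points = n_points,
                 degenerate = degenerate, track_pair = track_pair),
            class = "zcc_result")
}

#' @export
print.zcc_result <- function(x, ...) {
  lab <- switch(x$track_pair, atgc = "ZCC", rymk = "RY-MK", x$track_pair)
  if (x$degenerate) {
    cat(sprintf("<%s index> %s: undefined (degenerate track), n = %d\n",
                lab, x$genome_id, x$n_points))
  } else {
    cat(sprintf("<%s index> %s: r = %.6f, n = %d\n",
                lab, x$genome_id, x$value, x$n_points))
  }
  invisible(x)
}

#' The Z-curve correlation coefficient (ZCC) index
#'
#' Windowless measure of the correlation between AT and GC compositional
#' bias along a sequence: the Pearson correlation between the AT disparity
#' track \eqn{a_n = A_n - T_n} and the GC disparity track
#' \eqn{b_n = G_n - C_n}, taken over \eqn{n = 1, \ldots, N} (the zero-valued
#' origin point is excluded; for genome-scale N its inclusion would change r
#' negligibly, but the summation index set is fixed to the N sequence
#' positions).
#'
#' A positive index means A-over-T and G-over-C excesses rise and fall
#' together along the chromosome (the purine-asymmetry regime typical of
#' Firmicutes-like genomes); a negative index means they move oppositely
#' (the common G+T-rich leading strand regime).
#'
#' @param seq A [genome_seq()], `zcurve`, or character scalar; `N >= 2`.
#' @param strict Raise on degenerate tracks instead of flagging.
#' @return A `zcc_result` with fields `genome_id`, `value` (`NA` when
#'   `degenerate`), `n_points`, `degenerate`, `track_pair = "atgc"`.
#' @examples
#' zcc_index("AAGGTTCC")$value  # exactly 0
#' zcc_index("AGAGCTCT")$value  # 5/7
#' @export
zcc_index <- function(seq, strict = FALSE) {
  zc <- as_zcurve(seq)
  if (zc$N < 2L) stop("ZCC undefined for N < 2", call. = FALSE)
  d <- disparity_curves(zc)
  idx <- seq.int(2L, zc$N + 1L)  # n = 1..N
  r <- pearson_r(d$at[idx], d$gc[idx], strict = strict)
  new_zcc_result(zc$genome_id, r, zc$N, is.na(r), "atgc")
}

#' The RY-MK correlation index
#'
#' The analogue of [zcc_index()] on the first two Z-curve components:
#' Pearson correlation between the purine-pyrimidine excess \eqn{x_n} and
#' the amino-keto excess \eqn{y_n} over \eqn{n = 1, \ldots, N}. By default
#' `y` carries its defining sign, amino minus keto; `mk_sign = -1` negates
#' it for the keto-over-amino reading.
#'
#' @param seq A [genome_seq()], `zcurve`, or character scalar; `N >= 2`.
#' @param mk_sign `+1` (default, amino - keto) or `-1` (keto - amino).
#' @param strict Raise on degenerate tracks instead of flagging.
#' @return A `zcc_result` with `track_pair = "rymk"`.
#' @export
rymk_index <- function(seq, mk_sign = 1, strict = FALSE) {
  stopifnot(mk_sign %in% c(-1, 1))
  zc <- as_zcurve(seq)
  if (zc$N < 2L) stop("RY-MK index undefined for N < 2", call. = FALSE)
  idx <- seq.int(2L, zc$N + 1L)
  r <- pearson_r(zc$x[idx], mk_sign * zc$y[idx], strict = strict)
  new_zcc_result(zc$genome_id, r, zc$N, is.na(r), "rymk")
}
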