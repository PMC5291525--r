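#' Compute the cumulative Z-curve of a sequence
#'
#' Decomposes a DNA sequence into the three cumulative Z-curve components.
#' With \eqn{A_n, C_n, G_n, T_n} the occurrence numbers of each base among
#' the first \eqn{n} residues,
#' \deqn{x_n = (A_n + G_n) - (C_n + T_n)}
#' \deqn{y_n = (A_n + C_n) - (G_n + T_n)}
#' \deqn{z_n = (A_n + T_n) - (C_n + G_n)}
#' for \eqn{n = 0, 1, \ldots, N}: the purine-pyrimidine, amino-keto and
#' weak-strong hydrogen-bond excesses. All arrays have length `N + 1` with
#' the origin point `x_0 = y_0 = z_0 = 0`, and all arithmetic is integer so
#' the defining identities hold exactly. Ambiguous IUPAC residues advance
#' the position index but touch no base counter, preserving positional
#' alignment with annotations.
#'
#' @param seq A [genome_seq()], or a character scalar which is coerced to one.
#' @return An object of class `zcurve`: a list with `genome_id`, cumulative
#'   counts `A`, `C`, `G`, `T` (integer vectors of length `N + 1`),
#'   components `x`, `y`, `z`, the length `N` and `n_ambiguous`.
#' @examples
#' zc <- compute_zcurve("ACGT")
#' zc$x  # 0 1 0 1 0
#' @seealso [disparity_curves()], [zcc_index()]
#' @export
compute_zcurve <- function(seq) {
  seq <- as_genome_seq(seq)
  N <- seq$N
  if (N == 0L) {
    zero <- integer(1)
    return(structure(list(genome_id = seq$genome_id,
                          A = zero, C = zero, G = zero, T = zero,
                          x = zero, y = zero, z = zero,
                          N = 0L, n_ambiguous = 0L),
                     class = "zcurve"))
  }
  codes <- utf8ToInt(seq$residues)
  isA <- codes == 65L; isC <- codes == 67L
  isG <- codes == 71L; isT <- codes == 84L
  A <- c(0L, cumsum(isA)); C <- c(0L, cumsum(isC))
  G <- c(0L, cumsum(isG)); T <- c(0L, cumsum(isT))
  structure(
    list(genome_id = seq$genome_id,
         A = A, C = C, G = G, T = T,
         x = (A + G) - (C + T),
         y = (A + C) - (G + T),
         z = (A + T) - (C + G),
         N = N,
         n_ambiguous = N - (A[N + 1L] + C[N + 1L] + G[N + 1L] + T[N + 1L])),
    class = "zcurve"
  )
}

as_genome_seq <- function(seq) {
  if (inherits(seq, "genome_seq")) return(seq)
  if (is.character(seq) && length(seq) == 1L) return(genome_seq("seq", seq))
  stop("expected a genome_seq or a single character string", call. = FALSE)
}

#' @export
print.zcurve <- function(x, ...) {
  cat(sprintf("<zcurve> %s: N = %d (%d ambiguous)\n",
              x$genome_id, x$N, x$n_ambiguous))
  cat(sprintf("  endpoint: x_N = %d, y_N = %d, z_N = %d\n",
              x$x[x$N + 1L], x$y[x$N + 1L], x$z[x$N + 1L]))
  invisible(x)
}

#' AT and GC disparity curves
#'
#' Derives the two cumulative disparity tracks from a Z-curve:
#' \deqn{a_n = (x_n + y_n)/2 = A_n - T_n \quad\textrm{(AT disparity)}}
#' \deqn{b_n = (x_n - y_n)/2 = G_n - C_n \quad\textrm{(GC disparity)}}
#' The halving always divides evenly, so both tracks are exact integers.
#'
#' @param zc A `zcurve` from [compute_zcurve()], a [genome_seq()] or a
#'   character scalar (coerced).
#' @return An object of class `disparity_curves`: list with `genome_id`,
#'   `at` and `gc` (integer vectors of length `N + 1`, origin included) and
#'   `N`.
#' @examples
#' disparity_curves("AAGGTTCC")$at  # 0 1 2 2 2 1 0 0 0
#' @export
disparity_curves <- function(zc) {
  zc <- as_zcurve(zc)
  at <- (zc$x + zc$y) %/% 2L
  gc <- (zc$x - zc$y) %/% 2L
  structure(list(genome_id = zc$genome_id, at = at, gc = gc, N = zc$N),
            class = "disparity_curves")
}

as_zcurve <- function(x) {
  if (inherits(x, "zcurve")) return(x)
  compute_zcurve(x)
}

#' @export
print.disparity_curves <- function(x, ...) {
  cat(sprintf("<disparity_curves> %s: N = %d\n", x$genome_id, x$N))
  cat(sprintf("  AT range [%d, %d]; GC range [%d, %d]\n",
              min(x$at), max(x$at), min(x$gc), max(x$gc)))
  invisible(x)
}

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T) over the unambiguous residues only;
#' ambiguity codes are excluded from the denominator.
#'
#' @param zc A `zcurve`, [genome_seq()] or character scalar.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(zc) {
  zc <- as_zcurve(zc)
  i <- zc$N + 1L
  total <- zc$A[i] + zc$C[i] + zc$G[i] + zc$T[i]
  if (total == 0L)
    stop("GC content undefined: sequence has no unambiguous residues",
         call. = FALSE)
  (zc$G[i] + zc$C[i]) / total
}

#' Dump Z-curve and disparity tracks as a table
#'
#' @param zc A `zcurve`.
#' @param path Optional file; when given the table is written as TSV.
#' @return Invisibly (or visibly when `path` is `NULL`), a data frame with
#'   columns `n`, `x`, `y`, `z`, `at`, `gc`.
#' @export
zcurve_table <- function(zc, path = NULL) {
  zc <- as_zcurve(zc)
  d <- disparity_curves(zc)
  out <- data.frame(n = 0:zc$N, x = zc$x, y = zc$y, z = zc$z,
                    at = d$at, gc = d$gc)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
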