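#' Analyze one genome: ZCC, RY-MK, replichores and gene strand bias
#'
#' The package's central entry point. Computes the Z-curve and disparity
#' tracks, the ZCC and RY-MK indexes and GC content; infers (or accepts)
#' the replication origin and terminus; and, when annotations are given,
#' assigns genes to leading/lagging strands and computes the SGD fraction.
#'
#' @param seq A [genome_seq()] or character scalar.
#' @param genes Optional gene data frame ([read_genes()]).
#' @param oric Optional one-row oriC data frame ([read_oric_table()]) or a
#'   0-based ori position.
#' @param ori_source `"auto"` (table when `oric` given, else extrema),
#'   `"table"`, `"extrema"` or `"none"` (skip replichore inference).
#' @param rotate Recompute the indexes on the sequence rotated so that ori
#'   is the first position (disparity curves then start at the origin, the
#'   frame used for origin-anchored plots). Requires an ori source.
#' @param mk_sign Sign convention for the RY-MK index, see [rymk_index()].
#' @return An object of class `zcc_genome` with components `genome_id`, `N`,
#'   `gc_content`, `zcc` and `rymk` (`zcc_result`s), `curves`
#'   (`disparity_curves`, in the analyzed frame), `model`
#'   (`replichore_model` or `NULL`), `sgd` (`sgd_result` or `NULL`),
#'   `rotated` (logical). Methods: `print`, `summary`, `plot`, `coef`,
#'   `as.data.frame`.
#' @examples
#' spec <- skew_spec(N = 50000, seed = 7)
#' g <- generate_genome(spec)
#' fit <- zcc_genome(g$seq)
#' coef(fit)
#' @export
zcc_genome <- function(seq, genes = NULL, oric = NULL,
                       ori_source = c("auto", "table", "extrema", "none"),
                       rotate = FALSE, mk_sign = 1) {
  ori_source <- match.arg(ori_source)
  seq <- as_genome_seq(seq)
  if (ori_source == "auto")
    ori_source <- if (!is.null(oric)) "table" else "extrema"
  if (rotate && ori_source == "none")
    stop("rotate = TRUE requires an ori source ('table' or 'extrema')",
         call. = FALSE)
  zc <- compute_zcurve(seq)
  curves <- disparity_curves(zc)
  model <- NULL
  if (ori_source == "table") {
    if (is.null(oric)) stop("ori_source = 'table' but no oriC given",
                            call. = FALSE)
    model <- build_replichores(oric, N = seq$N, curves = curves,
                               genome_id = seq$genome_id)
  } else if (ori_source == "extrema") {
    model <- tryCatch(
      suppressWarnings(estimate_ori_ter(curves, topology = seq$topology)),
      error = function(e) NULL)
  }
  if (rotate) {
    if (is.null(model)) stop("cannot rotate: no replichore model",
                             call. = FALSE)
    seq <- rotate_to_ori(seq, model)
    if (!is.null(genes)) genes <- rotate_genes(genes, model)
    off <- model$ori
    model <- new_replichore_model(model$genome_id, 0L,
                                  (model$ter - off) %% model$N,
                                  model$N, model$source, model$confidence)
    zc <- compute_zcurve(seq)
    curves <- disparity_curves(zc)
  }
  sgd <- NULL
  if (!is.null(genes) && !is.null(model) && nrow(genes) > 0L) {
    own <- is.null(genes$genome_id) | genes$genome_id == seq$genome_id
    if (any(own)) sgd <- sgd_fraction(genes[own, , drop = FALSE], model)
  }
  structure(list(genome_id = seq$genome_id, N = seq$N,
                 gc_content = gc_content(zc),
                 zcc = zcc_index(zc),
                 rymk = rymk_index(zc, mk_sign = mk_sign),
                 curves = curves, model = model, sgd = sgd,
                 rotated = rotate),
            class = "zcc_genome")
}

#' @export
print.zcc_genome <- function(x, ...) {
  cat(sprintf("<zcc_genome> %s (%d bp%s)\n", x$genome_id, x$N,
              if (x$rotated) ", rotated to ori" else ""))
  zcc <- if (x$zcc$degenerate) "undefined" else sprintf("%.4f", x$zcc$value)
  rymk <- if (x$rymk$degenerate) "undefined" else sprintf("%.4f", x$rymk$value)
  cat(sprintf("  ZCC = %s, RY-MK = %s, GC = %.1f%%\n",
              zcc, rymk, 100 * x$gc_content))
  if (!is.null(x$model))
    cat(sprintf("  ori = %d, ter = %d (%s, confidence %.3f)\n",
                x$model$ori, x$model$ter, x$model$source,
                x$model$confidence))
  if (!is.null(x$sgd))
    cat(sprintf("  SGD: %.1f%% of %d genes on the leading strand\n",
                100 * x$sgd$fraction_leading,
                x$sgd$n_leading + x$sgd$n_lagging))
  invisible(x)
}

#' @export
summary.zcc_genome <- function(object, ...) {
  print(object)
  d <- object$curves
  cat(sprintf("  AT disparity range [%d, %d]; GC disparity range [%d, %d]\n",
              min(d$at), max(d$at), min(d$gc), max(d$gc)))
  invisible(as.data.frame(object))
}

#' @export
coef.zcc_genome <- function(object, ...) {
  c(zcc = object$zcc$value, rymk = object$rymk$value,
    gc_content = object$gc_content,
    sgd_fraction = if (is.null(object$sgd)) NA_real_ else
      object$sgd$fraction_leading)
}

#' @export
as.data.frame.zcc_genome <- function(x, ...) {
  data.frame(genome_id = x$genome_id, N = x$N, gc_content = x$gc_content,
             zcc = x$zcc$value, rymk = x$rymk$value,
             degenerate = x$zcc$degenerate || x$rymk$degenerate,
             ori = if (is.null(x$model)) NA_integer_ else x$model$ori,
             ter = if (is.null(x$model)) NA_integer_ else x$model$ter,
             ori_source = if (is.null(x$model)) NA_character_ else
               x$model$source,
             sgd_fraction = if (is.null(x$sgd)) NA_real_ else
               x$sgd$fraction_leading,
             phylum = NA_character_,
             stringsAsFactors = FALSE)
}

#' Analyze every record of a FASTA file
#'
#' Maps [zcc_genome()] over the records of a FASTA file and binds the
#' one-row results into the per-genome results table. A failing record
#' aborts with a message naming it.
#'
#' @param path FASTA file.
#' @param genes Optional gene annotation file or data frame (rows are
#'   matched to records by `genome_id`).
#' @param oric Optional oriC table file or data frame.
#' @param longest_only Analyze only the longest record (chromosome
#'   selection, see [read_fasta()]).
#' @param ... Further arguments to [zcc_genome()].
#' @return Results data frame, one row per analyzed record, in file order.
#' @export
zcc_scan_fasta <- function(path, genes = NULL, oric = NULL,
                           longest_only = FALSE, ...) {
  seqs <- read_fasta(path, longest_only = longest_only)
  if (is.character(genes)) genes <- read_genes(genes)
  if (is.character(oric)) oric <- read_oric_table(oric, genomes = seqs)
  rows <- lapply(seqs, function(s) {
    g <- if (!is.null(genes))
      genes[genes$genome_id == s$genome_id, , drop = FALSE] else NULL
    o <- if (!is.null(oric)) {
      hit <- oric[oric$genome_id == s$genome_id, , drop = FALSE]
      if (nrow(hit)) hit[1, , drop = FALSE] else NULL
    } else NULL
    fit <- tryCatch(zcc_genome(s, genes = g, oric = o, ...),
                    error = function(e)
                      stop(sprintf("record '%s': %s", s$genome_id,
                                   conditionMessage(e)), call. = FALSE))
    as.data.frame(fit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
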