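new_replichore_model <- function(genome_id, ori, ter, N, source, confidence) {
  if (ori == ter) stop("ori and ter coincide", call. = FALSE)
  structure(list(genome_id = genome_id, ori = as.integer(ori),
                 ter = as.integer(ter), N = as.integer(N),
                 source = source, confidence = confidence),
            class = "replichore_model")
}

#' @export
print.replichore_model <- function(x, ...) {
  cat(sprintf("<replichore_model> %s: ori = %d, ter = %d (0-based), N = %d\n",
              x$genome_id, x$ori, x$ter, x$N))
  cat(sprintf("  source = %s, confidence = %.3f\n", x$source, x$confidence))
  invisible(x)
}

# Chord-detrend a cumulative track: subtract the straight line through its
# first and last points. On circular genomes this makes extrema positions
# equivariant under rotation of the deposited start.
detrend_track <- function(b) {
  N <- length(b) - 1L
  b - (b[1L] + (0:N) / N * (b[N + 1L] - b[1L]))
}

#' Estimate replication origin and terminus from disparity extrema
#'
#' Locates ori and ter as the extrema of the (detrended) cumulative G-C
#' disparity track. The leading strand is G-enriched, so G-C rises along
#' each leading arc: starting from ori the curve is an inverted V peaking at
#' ter, hence ori = minimum and ter = maximum. For circular topology the
#' track is first detrended by removing the chord from `(0, b_0)` to
#' `(N, b_N)`, which makes the estimates rotation-equivariant; without it
#' the deposited start biases the extrema.
#'
#' Confidence is the detrended peak-to-trough amplitude divided by N,
#' clipped to `[0, 1]` — roughly the average per-base skew.
#'
#' @param curves A `disparity_curves` object (or anything [compute_zcurve()]
#'   accepts).
#' @param topology `"circular"` (detrended) or `"linear"` (raw extrema).
#' @param track `"gc"` (default) or `"at"`.
#' @param min_n Warn below this length: extremum estimates on short
#'   sequences are dominated by noise.
#' @return A `replichore_model` with `source = "extrema"`; positions are
#'   0-based on the deposited forward strand.
#' @export
estimate_ori_ter <- function(curves, topology = c("circular", "linear"),
                             track = c("gc", "at"), min_n = 1000L) {
  topology <- match.arg(topology)
  track <- match.arg(track)
  if (!inherits(curves, "disparity_curves")) curves <- disparity_curves(curves)
  N <- curves$N
  if (N < min_n)
    warning(sprintf("sequence length %d < %d: ori/ter estimate unreliable",
                    N, min_n))
  b <- as.numeric(curves[[track]])
  d <- if (topology == "circular") detrend_track(b) else b
  if (max(d) == min(d))
    stop("no signal: disparity track is flat, cannot place ori/ter",
         call. = FALSE)
  ori <- (which.min(d) - 1L) %% N
  ter <- (which.max(d) - 1L) %% N
  if (ori == ter)
    stop("no signal: ori and ter estimates coincide", call. = FALSE)
  conf <- min(1, (max(d) - min(d)) / N)
  new_replichore_model(curves$genome_id, ori, ter, N, "extrema", conf)
}

#' Build a replichore model from a known oriC
#'
#' Takes ori from a curated oriC interval (its integer midpoint on the
#' circle, ties broken downward) or directly as a 0-based position, and ter
#' either as given or estimated as the detrended-extremum of the GC
#' disparity track farthest from ori along the circle.
#'
#' @param oric Either a one-row data frame with `oric_start`, `oric_end`
#'   (1-based inclusive, possibly wrapping) or a single 0-based position.
#' @param N Genome length.
#' @param ter Optional 0-based terminus position.
#' @param curves `disparity_curves`, required when `ter` is `NULL`.
#' @param genome_id Identifier for the model (taken from `oric` or `curves`
#'   when available).
#' @return A `replichore_model` with `source = "table"`.
#' @export
build_replichores <- function(oric, N, ter = NULL, curves = NULL,
                              genome_id = NULL) {
  if (is.data.frame(oric)) {
    stopifnot(nrow(oric) == 1L)
    if (is.null(genome_id) && !is.null(oric$genome_id))
      genome_id <- oric$genome_id
    s <- oric$oric_start; e <- oric$oric_end
    if (e < s) e <- e + N  # origin interval spanning the deposited start
    ori <- ((s + e) %/% 2L - 1L) %% N  # 1-based midpoint, tie down, to 0-based
  } else {
    ori <- as.integer(oric) %% N
  }
  if (is.null(genome_id))
    genome_id <- if (!is.null(curves)) curves$genome_id else "genome"
  conf <- 1
  if (is.null(ter)) {
    if (is.null(curves))
      stop("ter not given: disparity curves required to estimate it",
           call. = FALSE)
    d <- detrend_track(as.numeric(curves$gc))
    if (max(d) == min(d))
      stop("no signal: disparity track is flat, cannot place ter",
           call. = FALSE)
    cand <- c((which.min(d) - 1L) %% N, (which.max(d) - 1L) %% N)
    dist_circ <- pmin((cand - ori) %% N, (ori - cand) %% N)
    ter <- cand[which.max(dist_circ)]
    conf <- min(1, (max(d) - min(d)) / N)
  }
  ter <- as.integer(ter) %% N
  if (ter == ori) stop("ter collides with ori", call. = FALSE)
  new_replichore_model(genome_id, ori, ter, N, "table", conf)
}

# Half-open circular arc membership: p in [a, b) moving in increasing
# coordinate, wrapping at N.
in_arc <- function(p, a, b) {
  if (a < b) p >= a & p < b else p >= a | p < b
}

# Continuous 0-based midpoint of a (possibly wrapping) 1-based gene interval.
gene_midpoint0 <- function(start, end, N) {
  end <- ifelse(end < start, end + N, end)
  ((start - 1 + end) / 2) %% N
}

#' Assign genes to the leading or lagging strand
#'
#' A gene whose midpoint lies on the ori-to-ter arc (increasing coordinates,
#' wrapping) is on the leading strand iff it is on the forward (`+`) strand;
#' on the ter-to-ori arc the assignment is mirrored. Arcs are half-open
#' (`[ori, ter)` and `[ter, ori)`), so a midpoint exactly at ori or ter is
#' assigned deterministically.
#'
#' @param genes Data frame as from [read_genes()] (columns `start`, `end`,
#'   `strand`; 1-based inclusive).
#' @param model A `replichore_model`.
#' @return Character vector, `"leading"` or `"lagging"`, one per gene.
#' @export
assign_strand <- function(genes, model) {
  stopifnot(inherits(model, "replichore_model"))
  mid <- gene_midpoint0(genes$start, genes$end, model$N)
  fwd_arc <- in_arc(mid, model$ori, model$ter)
  ifelse(fwd_arc == (genes$strand == "+"), "leading", "lagging")
}

#' Strand-biased gene distribution (SGD)
#'
#' Fraction of genes on the leading strand, the classic measure of
#' replication-associated gene-orientation bias.
#'
#' @param genes Gene data frame; rows whose `genome_id` differs from the
#'   model's are skipped with a warning (other replicons).
#' @param model A `replichore_model`.
#' @return An `sgd_result`: `genome_id`, `n_leading`, `n_lagging`,
#'   `fraction_leading`.
#' @export
sgd_fraction <- function(genes, model) {
  stopifnot(inherits(model, "replichore_model"))
  if (!is.null(genes$genome_id)) {
    other <- genes$genome_id != model$genome_id
    if (any(other)) {
      warning(sprintf("%d gene(s) on other replicons skipped", sum(other)))
      genes <- genes[!other, , drop = FALSE]
    }
  }
  if (nrow(genes) == 0L)
    stop("SGD undefined: no assignable genes", call. = FALSE)
  cls <- assign_strand(genes, model)
  n_lead <- sum(cls == "leading")
  structure(list(genome_id = model$genome_id,
                 n_leading = n_lead,
                 n_lagging = nrow(genes) - n_lead,
                 fraction_leading = n_lead / nrow(genes)),
            class = "sgd_result")
}

#' @export
print.sgd_result <- function(x, ...) {
  cat(sprintf("<sgd_result> %s: %d leading / %d lagging (%.1f%% leading)\n",
              x$genome_id, x$n_leading, x$n_lagging,
              100 * x$fraction_leading))
  invisible(x)
}

#' Rotate a circular genome so that ori becomes the first position
#'
#' Disparity curves plotted from the replication origin show the canonical
#' inverted-V (or V) shapes; this rotation produces that frame. Annotations
#' must be rotated consistently with [rotate_genes()].
#'
#' @param seq A circular [genome_seq()].
#' @param model A `replichore_model` (or a 0-based offset).
#' @return The rotated `genome_seq`.
#' @export
rotate_to_ori <- function(seq, model) {
  stopifnot(inherits(seq, "genome_seq"))
  if (seq$topology != "circular")
    stop("cannot rotate a linear sequence", call. = FALSE)
  off <- if (inherits(model, "replichore_model")) model$ori else
    as.integer(model)
  off <- off %% seq$N
  if (off == 0L) return(seq)
  rot <- paste0(substr(seq$residues, off + 1L, seq$N),
                substr(seq$residues, 1L, off))
  genome_seq(seq$genome_id, rot, seq$topology)
}

#' Rotate gene annotations by the same offset as [rotate_to_ori()]
#'
#' @param genes Gene data frame (1-based inclusive coordinates).
#' @param model A `replichore_model` or 0-based offset.
#' @param N Genome length (taken from the model when available).
#' @return The gene data frame with shifted coordinates; genes pushed across
#'   the deposited start get `wraps = TRUE` (`start > end`).
#' @export
rotate_genes <- function(genes, model, N = NULL) {
  if (inherits(model, "replichore_model")) {
    off <- model$ori; N <- model$N
  } else {
    off <- as.integer(model)
    if (is.null(N)) stop("N required when model is a bare offset", call. = FALSE)
  }
  off <- off %% N
  shift1 <- function(p) ((p - 1L - off) %% N) + 1L
  end_unwrapped <- ifelse(genes$end < genes$start, genes$end + N, genes$end)
  new_start <- shift1(genes$start)
  new_end <- ((end_unwrapped - 1L - off) %% N) + 1L
  genes$start <- new_start
  genes$end <- new_end
  genes$wraps <- new_start > new_end
  genes
}

#' Export the two replichore arcs as BED intervals
#'
#' @param model A `replichore_model`.
#' @param path Optional output file (BED: 0-based half-open).
#' @return Data frame of BED rows (chrom, chromStart, chromEnd, name);
#'   wrapping arcs are split at the deposited start.
#' @export
replichore_bed <- function(model, path = NULL) {
  arc_rows <- function(a, b, name) {
    if (a < b) {
      data.frame(chrom = model$genome_id, chromStart = a, chromEnd = b,
                 name = name, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = model$genome_id,
                 chromStart = c(a, 0L), chromEnd = c(model$N, b),
                 name = name, stringsAsFactors = FALSE)
    }
  }
  bed <- rbind(arc_rows(model$ori, model$ter, "replichore_1"),
               arc_rows(model$ter, model$ori, "replichore_2"))
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
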