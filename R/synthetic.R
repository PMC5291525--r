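#' Specification for a synthetic strand-asymmetric genome
#'
#' Describes a circular chromosome with two replichores and a first-order
#' strand-composition bias. On the arc where the deposited forward strand
#' is the leading strand (ori to ter, increasing coordinates), bases are
#' drawn i.i.d. from `leading_probs`; on the other arc the forward strand
#' is the lagging strand, so base `b` is drawn with the leading probability
#' of its complement. Gene annotations are placed with a configurable
#' leading-strand preference.
#'
#' Defaults model a typical desk-scale study condition: a 200 kb replicon
#' with a per-base enrichment of 0.05 of A and G on the leading strand
#' (the purine-asymmetry, positive-ZCC regime), about one 900 bp gene per
#' kilobase, and a 0.78 leading-strand gene placement probability in the
#' range reported for strongly strand-biased bacteria.
#'
#' @param N Genome length in bases.
#' @param ori,ter 0-based ori and ter positions; `ter` defaults to the
#'   antipode of `ori`.
#' @param leading_probs Named probabilities (`A`, `C`, `G`, `T`) of each
#'   base on the leading strand; must sum to 1.
#' @param n_genes Number of non-overlapping genes to place.
#' @param p_leading Probability that a gene is on the leading strand.
#' @param mean_gene_len Mean gene length in bases.
#' @param seed Integer seed; required for reproducible generation.
#' @return A validated `skew_spec` list.
#' @seealso [regime_probs()] for canonical regimes, [generate_genome()].
#' @export
skew_spec <- function(N = 200000L, ori = 0L, ter = NULL,
                      leading_probs = regime_probs("purine"),
                      n_genes = 200L, p_leading = 0.78,
                      mean_gene_len = 900L, seed = NULL) {
  N <- as.integer(N)
  ori <- as.integer(ori) %% N
  ter <- if (is.null(ter)) (ori + N %/% 2L) %% N else as.integer(ter) %% N
  if (ori == ter) stop("ori and ter must differ", call. = FALSE)
  p <- leading_probs[c("A", "C", "G", "T")]
  if (anyNA(p) || any(p <= 0) || any(p >= 1) || abs(sum(p) - 1) > 1e-12)
    stop("leading_probs must be named A/C/G/T, each in (0,1), summing to 1",
         call. = FALSE)
  if (p_leading < 0 || p_leading > 1)
    stop("p_leading must be in [0, 1]", call. = FALSE)
  structure(list(N = N, ori = ori, ter = ter, leading_probs = p,
                 n_genes = as.integer(n_genes), p_leading = p_leading,
                 mean_gene_len = as.integer(mean_gene_len), seed = seed),
            class = "skew_spec")
}

#' Canonical leading-strand composition regimes
#'
#' * `"purine"`: A and G enriched on the leading strand (purine asymmetry;
#'   AT and GC disparities move together, positive-ZCC regime).
#' * `"keto"`: G and T enriched (the common bacterial pattern; disparities
#'   move oppositely, negative-ZCC regime).
#' * `"uniform"`: no bias (null regime).
#'
#' @param regime Regime name.
#' @param delta Per-base enrichment added to each favored base (and removed
#'   from its complement), default 0.05.
#' @return Named probability vector over A, C, G, T.
#' @export
regime_probs <- function(regime = c("purine", "keto", "uniform"),
                         delta = 0.05) {
  regime <- match.arg(regime)
  p <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  switch(regime,
         purine = p + c(delta, -delta, delta, -delta),
         keto = p + c(-delta, -delta, delta, delta),
         uniform = p)
}

# Expected ZCC sign of a regime: positive when the per-base AT and GC
# disparity drifts (p_A - p_T and p_G - p_C) share a sign.
expected_zcc_sign <- function(p) {
  sign((p[["A"]] - p[["T"]]) * (p[["G"]] - p[["C"]]))
}

#' Generate a synthetic strand-asymmetric circular genome
#'
#' Samples the deposited forward strand base-by-base under the two-replichore
#' model of [skew_spec()]. Deterministic given `spec$seed`.
#'
#' @param spec A `skew_spec`.
#' @param genome_id Identifier for the generated sequence.
#' @return A list with `seq` (the [genome_seq()]) and `truth` (class
#'   `synthetic_truth`: the spec, `true_ori`, `true_ter`, and
#'   `expected_zcc_sign` in `{-1, 0, 1}`).
#' @export
generate_genome <- function(spec, genome_id = "synth_1") {
  stopifnot(inherits(spec, "skew_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  p_lead <- spec$leading_probs
  # forward strand lagging on the second arc: P(b) = p_lead[complement(b)]
  p_lag <- c(A = p_lead[["T"]], C = p_lead[["G"]],
             G = p_lead[["C"]], T = p_lead[["A"]])
  pos <- 0:(spec$N - 1L)
  fwd_leading <- in_arc(pos, spec$ori, spec$ter)
  draws <- character(spec$N)
  draws[fwd_leading] <- sample(bases, sum(fwd_leading), replace = TRUE,
                               prob = p_lead)
  draws[!fwd_leading] <- sample(bases, sum(!fwd_leading), replace = TRUE,
                                prob = p_lag)
  seq <- genome_seq(genome_id, paste(draws, collapse = ""), "circular")
  truth <- structure(list(spec = spec, genome_id = genome_id,
                          true_ori = spec$ori, true_ter = spec$ter,
                          expected_zcc_sign = expected_zcc_sign(p_lead)),
                     class = "synthetic_truth")
  list(seq = seq, truth = truth)
}

#' Generate non-overlapping gene annotations for a synthetic genome
#'
#' Places `spec$n_genes` non-overlapping intervals around the circle
#' (lengths jittered around `spec$mean_gene_len`, separated by random gaps)
#' and chooses each gene's strand so that it lies on the leading strand
#' with probability `spec$p_leading` given its arc. The intended class is
#' recorded in the returned truth.
#'
#' @param spec A `skew_spec`.
#' @param truth The `synthetic_truth` from [generate_genome()] (supplies
#'   `genome_id` and arcs); gene placement draws from the current RNG
#'   stream, so call this right after [generate_genome()] for a fully
#'   seed-determined pair, or seed explicitly.
#' @return A list with `genes` (data frame in the gene-TSV dialect, plus
#'   `wraps`) and `true_class` (character, `"leading"`/`"lagging"` per gene).
#' @export
generate_genes <- function(spec, truth) {
  stopifnot(inherits(spec, "skew_spec"), inherits(truth, "synthetic_truth"))
  n <- spec$n_genes
  lens <- pmax(3L, as.integer(round(stats::rnorm(n, spec$mean_gene_len,
                                                 spec$mean_gene_len / 4))))
  if (sum(lens) >= spec$N)
    stop(sprintf("genome too short: %d genes of ~%d bp do not fit in %d bp",
                 n, spec$mean_gene_len, spec$N), call. = FALSE)
  free <- spec$N - sum(lens)
  gaps <- as.vector(stats::rmultinom(1L, free, rep(1 / n, n)))
  offset <- sample.int(spec$N, 1L) - 1L
  starts0 <- (offset + cumsum(gaps) + c(0L, cumsum(lens[-n]))) %% spec$N
  start1 <- starts0 + 1L
  end1 <- ((starts0 + lens - 1L) %% spec$N) + 1L
  mid <- gene_midpoint0(start1, end1, spec$N)
  fwd_arc <- in_arc(mid, spec$ori, spec$ter)
  lead <- stats::runif(n) < spec$p_leading
  strand <- ifelse(fwd_arc == lead, "+", "-")
  genes <- data.frame(genome_id = truth$genome_id,
                      start = start1, end = end1, strand = strand,
                      label = sprintf("%s_g%04d", truth$genome_id, seq_len(n)),
                      wraps = start1 > end1,
                      stringsAsFactors = FALSE)
  list(genes = genes, true_class = ifelse(lead, "leading", "lagging"))
}

#' Generate a multi-phylum synthetic cohort on disk
#'
#' Desk-scale stand-in for a genome survey: for each row of `regime_mix`
#' it generates `n_genomes` genomes under the named regime, annotates them,
#' and writes `genomes.fasta`, `genes.tsv`, `metadata.tsv` and
#' `truth.json` into `dir`. Downstream cohort statistics on these files
#' recover the designed group labels and polymerase cross-tab structure.
#'
#' @param dir Output directory (created if needed).
#' @param regime_mix Data frame with columns `phylum`, `regime` (`"purine"`,
#'   `"keto"` or `"uniform"`), `n_genomes`, `has_polc` (logical); optional
#'   `delta` (default 0.05) and `p_leading` per phylum.
#' @param N,n_genes Genome size and gene count per genome.
#' @param mean_gene_len Mean gene length in bases.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return Invisibly, a list with the file `paths` and the `truth` table
#'   (data frame: genome_id, phylum, regime, true_ori, true_ter,
#'   expected_zcc_sign, p_leading).
#' @export
generate_cohort <- function(dir, regime_mix, N = 200000L, n_genes = 200L,
                            mean_gene_len = 900L, seed) {
  stopifnot(all(c("phylum", "regime", "n_genomes", "has_polc") %in%
                  names(regime_mix)))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (is.null(regime_mix$delta)) regime_mix$delta <- 0.05
  if (is.null(regime_mix$p_leading)) regime_mix$p_leading <- 0.78
  seqs <- list(); gene_tabs <- list(); meta_rows <- list(); truth_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(regime_mix))) {
    row <- regime_mix[i, ]
    for (j in seq_len(row$n_genomes)) {
      k <- k + 1L
      gid <- sprintf("%s_%03d", row$phylum, j)
      sp <- skew_spec(N = N,
                      ori = sample.int(N, 1L) - 1L,
                      leading_probs = regime_probs(row$regime, row$delta),
                      n_genes = n_genes, p_leading = row$p_leading,
                      mean_gene_len = mean_gene_len, seed = NULL)
      gen <- generate_genome(sp, gid)
      ann <- generate_genes(sp, gen$truth)
      seqs[[k]] <- gen$seq
      gene_tabs[[k]] <- ann$genes
      meta_rows[[k]] <- data.frame(genome_id = gid, phylum = row$phylum,
                                   has_polc = row$has_polc,
                                   dnae_types = "DnaE",
                                   stringsAsFactors = FALSE)
      truth_rows[[k]] <- data.frame(genome_id = gid, phylum = row$phylum,
                                    regime = row$regime,
                                    true_ori = sp$ori, true_ter = sp$ter,
                                    expected_zcc_sign =
                                      expected_zcc_sign(sp$leading_probs),
                                    p_leading = row$p_leading,
                                    stringsAsFactors = FALSE)
    }
  }
  paths <- list(fasta = file.path(dir, "genomes.fasta"),
                genes = file.path(dir, "genes.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                truth = file.path(dir, "truth.json"))
  write_fasta(seqs, paths$fasta)
  write_genes_tsv(do.call(rbind, gene_tabs), paths$genes)
  meta <- do.call(rbind, meta_rows)
  utils::write.table(meta, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- do.call(rbind, truth_rows)
  jsonlite::write_json(truth, paths$truth, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
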