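#' Read genomes from a FASTA file
#'
#' Each record becomes a [genome_seq()]; the header token before the first
#' whitespace is the `genome_id`, residues are upper-cased and validated
#' against the IUPAC DNA alphabet (U is rejected: DNA mode only). Record
#' order is preserved.
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record (bacterial chromosomes
#'   default to circular).
#' @param longest_only Keep only the longest record — selects the chromosome
#'   from assemblies that also carry plasmids, since a single-oriC analysis
#'   applies to the chromosome.
#' @return A named list of `genome_seq` objects.
#' @export
read_fasta <- function(path, topology = c("circular", "linear"),
                       longest_only = FALSE) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  # raw read (BStringSet) so that validation can name the record and offset
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  seqs <- unname(as.character(set))
  out <- vector("list", length(set))
  for (i in seq_along(seqs)) {
    out[[i]] <- genome_seq(ids[i], seqs[i], topology)
  }
  names(out) <- ids
  if (longest_only && length(out) > 1L) {
    out <- out[which.max(vapply(out, `[[`, 0L, "N"))]
  }
  out
}

#' Write genomes to a FASTA file
#'
#' @param seqs A `genome_seq` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "genome_id")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts GFF3 (via `rtracklayer`) or the package's 4-column tab-separated
#' dialect `seq_id  start  end  strand` (header line optional, recognized by
#' a non-numeric second field). Coordinates are 1-based inclusive in both
#' formats. From GFF3 only features of `feature_type` (default `"gene"`)
#' are kept.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param feature_type GFF3 feature type to keep.
#' @return A data frame with columns `genome_id`, `start`, `end`, `strand`,
#'   `label`, `wraps` (logical: origin-spanning gene on a circular genome,
#'   encoded as `start > end`).
#' @export
read_genes <- function(path, format = c("auto", "gff3", "tsv"),
                       feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    df <- df[!is.na(df$type) & as.character(df$type) %in% feature_type, ,
             drop = FALSE]
    strand <- as.character(df$strand)
    if (any(strand == "*"))
      stop("gene with strand '.' (unstranded) is not supported", call. = FALSE)
    label <- if (!is.null(df$ID)) as.character(df$ID) else
      sprintf("gene_%d", seq_len(nrow(df)))
    genes <- data.frame(genome_id = as.character(df$seqnames),
                        start = df$start, end = df$end,
                        strand = strand, label = label,
                        stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "#")
    if (ncol(raw) < 4L)
      stop("gene TSV needs 4 columns: seq_id, start, end, strand", call. = FALSE)
    if (nrow(raw) > 0L && is.na(suppressWarnings(as.integer(raw[1, 2]))))
      raw <- raw[-1L, , drop = FALSE]  # header line
    genes <- data.frame(genome_id = raw[[1]],
                        start = as.integer(raw[[2]]),
                        end = as.integer(raw[[3]]),
                        strand = raw[[4]],
                        label = if (ncol(raw) >= 5L) raw[[5]] else
                          sprintf("gene_%d", seq_len(nrow(raw))),
                        stringsAsFactors = FALSE)
  }
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad))
    stop(sprintf("invalid strand '%s' (expect + or -)",
                 genes$strand[which(bad)[1]]), call. = FALSE)
  if (any(is.na(genes$start)) || any(is.na(genes$end)) ||
      any(genes$start < 1L) || any(genes$end < 1L))
    stop("gene coordinates must be positive integers", call. = FALSE)
  genes$wraps <- genes$start > genes$end
  genes
}

#' Write gene annotations in the 4-column TSV dialect
#'
#' @param genes Data frame as returned by [read_genes()].
#' @param path Output file.
#' @param header Write a header line.
#' @return `path`, invisibly.
#' @export
write_genes_tsv <- function(genes, path, header = TRUE) {
  out <- genes[, c("genome_id", "start", "end", "strand")]
  names(out)[1] <- "seq_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a replication-origin (oriC) table
#'
#' CSV with at least an accession column and the oriC start/end coordinate
#' columns (1-based). Column names are configurable because curated origin
#' databases vary in schema. Duplicate accessions keep the first row with a
#' warning; when genomes are supplied coordinates are bounds-checked.
#'
#' @param path CSV file.
#' @param columns Named character vector mapping the roles `genome_id`,
#'   `oric_start`, `oric_end` to column names in the file.
#' @param genomes Optional list of [genome_seq()] for bounds validation.
#' @return Data frame `genome_id`, `oric_start`, `oric_end`.
#' @export
read_oric_table <- function(path,
                            columns = c(genome_id = "genome_id",
                                        oric_start = "oric_start",
                                        oric_end = "oric_end"),
                            genomes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(tab))
  if (length(missing_cols))
    stop(sprintf("oriC table is missing column(s): %s (expected %s)",
                 paste(missing_cols, collapse = ", "),
                 paste(sprintf("%s=%s", names(columns), columns),
                       collapse = ", ")),
         call. = FALSE)
  out <- data.frame(genome_id = as.character(tab[[columns[["genome_id"]]]]),
                    oric_start = as.integer(tab[[columns[["oric_start"]]]]),
                    oric_end = as.integer(tab[[columns[["oric_end"]]]]),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$genome_id)
  if (any(dup)) {
    warning(sprintf("duplicate oriC rows for %s; keeping the first",
                    paste(unique(out$genome_id[dup]), collapse = ", ")))
    out <- out[!dup, , drop = FALSE]
  }
  if (!is.null(genomes)) {
    lens <- vapply(genomes, `[[`, 0L, "N")
    ids <- vapply(genomes, `[[`, "", "genome_id")
    for (i in seq_len(nrow(out))) {
      j <- match(out$genome_id[i], ids)
      if (is.na(j)) next
      if (out$oric_start[i] < 1L || out$oric_start[i] > lens[j] ||
          out$oric_end[i] < 1L || out$oric_end[i] > lens[j])
        stop(sprintf("oriC coordinates (%d, %d) outside [1, %d] for %s",
                     out$oric_start[i], out$oric_end[i], lens[j],
                     out$genome_id[i]), call. = FALSE)
    }
  }
  out
}

RESULT_COLUMNS <- c("genome_id", "N", "gc_content", "zcc", "rymk",
                    "degenerate", "ori", "ter", "ori_source",
                    "sgd_fraction", "phylum")

#' Write / read the per-genome results table
#'
#' One row per analyzed sequence with a fixed, deterministic column order:
#' `genome_id, N, gc_content, zcc, rymk, degenerate, ori, ter, ori_source,
#' sgd_fraction, phylum`. Values round-trip through the matching reader to
#' at least 12 significant digits; absent fields are blank (TSV) or `null`
#' (JSON). The JSON form is an array of objects keyed like the TSV columns.
#'
#' @param records Data frame carrying (a subset of) the result columns.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path` invisibly (writer); the records data frame (reader).
#' @export
write_results_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  for (col in setdiff(RESULT_COLUMNS, names(records))) records[[col]] <- NA
  records <- records[, RESULT_COLUMNS]
  if (format == "tsv") {
    fmt <- records
    for (col in c("gc_content", "zcc", "rymk", "sgd_fraction")) {
      fmt[[col]] <- ifelse(is.na(records[[col]]), "",
                           sprintf("%.15g", records[[col]]))
    }
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    records <- jsonlite::fromJSON(path)
  } else {
    records <- utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE, quote = "",
                                 na.strings = "")
  }
  for (col in setdiff(RESULT_COLUMNS, names(records))) records[[col]] <- NA
  records$degenerate <- as.logical(records$degenerate)
  records[, RESULT_COLUMNS]
}

#' Read a per-genome metadata table
#'
#' Tab-separated with columns `genome_id`, `phylum`, `has_polc`
#' (true/false/unknown) and optionally `dnae_types` (comma-separated).
#' Unknown polymerase status is kept as `NA` and later excluded from
#' polymerase cross-tabs.
#'
#' @param path TSV file.
#' @return Data frame `genome_id`, `phylum`, `has_polc` (logical, `NA` for
#'   unknown), `dnae_types`.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("genome_id", "phylum", "has_polc")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop(sprintf("metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  hp <- tolower(as.character(tab$has_polc))
  tab$has_polc <- ifelse(hp %in% c("true", "t", "1", "yes"), TRUE,
                         ifelse(hp %in% c("false", "f", "0", "no"), FALSE, NA))
  if (is.null(tab$dnae_types)) tab$dnae_types <- "DnaE"
  tab[, c("genome_id", "phylum", "has_polc", "dnae_types")]
}
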