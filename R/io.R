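## Format readers/writers. Standard formats go through Biostrings /
## rtracklayer / Rsamtools; TSV is plain UTF-8 with a header row and no
## quoting, matching the deposited screen data records.

read_fastq_seqs <- function(fastq, with_ids = FALSE) {
  if (inherits(fastq, "DNAStringSet")) {
    seqs <- as.character(fastq)
    ids <- names(fastq) %||% as.character(seq_along(seqs))
  } else {
    stopifnot(is.character(fastq), length(fastq) == 1L)
    if (!file.exists(fastq)) stop("FASTQ file not found: ", fastq)
    validate_fastq_structure(fastq)
    x <- tryCatch(
      Biostrings::readDNAStringSet(fastq, format = "fastq"),
      error = function(e) {
        stop("malformed FASTQ in ", fastq, ": ", conditionMessage(e),
             call. = FALSE)
      })
    seqs <- as.character(x)
    ids <- names(x)
  }
  # read id = text up to the first whitespace, with any /1 /2 pair suffix kept
  ids <- sub("\\s.*$", "", ids)
  if (with_ids) names(seqs) <- ids else names(seqs) <- NULL
  seqs
}

## Structural check of 4-line FASTQ records (Biostrings tolerates some
## truncations silently); errors name the offending record's offset.
validate_fastq_structure <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": truncated record at line ",
         4L * (length(lines) %/% 4L) + 1L, call. = FALSE)
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  sep <- lines[seq(3L, length(lines), by = 4L)]
  bad_h <- which(!startsWith(hdr, "@"))
  if (length(bad_h)) {
    stop("malformed FASTQ in ", path, ": record ", bad_h[1],
         " (line ", 4L * (bad_h[1] - 1L) + 1L, ") does not start with '@'",
         call. = FALSE)
  }
  bad_s <- which(!startsWith(sep, "+"))
  if (length(bad_s)) {
    stop("malformed FASTQ in ", path, ": record ", bad_s[1],
         " lacks a '+' separator line", call. = FALSE)
  }
  invisible(TRUE)
}

write_fastq <- function(seqs, ids, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a TSV file
#'
#' Header row, tab separated, UTF-8, no quoting; CRLF line endings accepted.
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write a TSV file
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample sheet
#'
#' Expected columns: `sample`, `fastq_path`, `condition`, `replicate`,
#' `library`, `end_label`. Only `sample` is mandatory for count-matrix use.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv(path)
  if (!"sample" %in% names(sheet)) {
    stop("sample sheet ", path, " lacks a 'sample' column")
  }
  sheet
}

#' Read gene models from GTF/GFF
#'
#' Parses gene records into gene-body spans: for each `gene_id`, the span
#' from the minimum start to the maximum end over all its records on one
#' chromosome. Quoted and unquoted `gene_id` attributes are both accepted
#' (rtracklayer handles either).
#'
#' @param path GTF/GFF file path.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand` (1-based, closed intervals).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta)) {
    stop("GTF ", path, " has no gene_id attributes")
  }
  df <- data.frame(gene_id = as.character(meta$gene_id),
                   gene_name = if ("gene_name" %in% names(meta))
                     as.character(meta$gene_name) else as.character(meta$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  agg_s <- stats::aggregate(start ~ gene_id + chrom, data = df, FUN = min)
  agg_e <- stats::aggregate(end ~ gene_id + chrom, data = df, FUN = max)
  out <- merge(agg_s, agg_e, by = c("gene_id", "chrom"))
  first <- df[!duplicated(df$gene_id), c("gene_id", "gene_name", "strand")]
  out <- merge(out, first, by = "gene_id")
  out[order(out$chrom, out$start), c("gene_id", "gene_name", "chrom",
                                     "start", "end", "strand")]
}
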