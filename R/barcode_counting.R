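#' Extract random barcodes from amplicon reads
#'
#' Scans single-end amplicon reads for the constant sequence immediately 5'
#' of the random barcode, and counts the 25-mer that follows it. The flank is
#' matched by Hamming distance over a fixed window (no indels), which keeps
#' extraction O(1) per read. Reads are discarded (and tallied by reason) when
#' the flank does not match within `max_mismatch`, the read is too short to
#' contain flank + barcode (+ optional 3' flank), or the barcode window
#' contains an N. An N is treated as a failed base, not a wildcard: wild-
#' carding would glue unrelated barcodes together during grouping.
#'
#' @param fastq Path to a FASTQ file (optionally gzipped) or a
#'   `Biostrings::DNAStringSet` of reads.
#' @param sample Sample identifier attached to every count.
#' @param flank5 Constant sequence immediately 5' of the barcode.
#' @param flank3 Optional constant sequence immediately 3' of the barcode;
#'   when given it is also checked at `max_mismatch`.
#' @param max_mismatch Hamming mismatch budget for each flank.
#' @param barcode_length Barcode length in bp (25 for this transposon).
#' @return A list of class `barcode_counts` with elements `counts`
#'   (data.frame: `barcode`, `sample`, `reads`) and `discarded` (data.frame:
#'   `reason`, `reads`).
#' @export
extract_barcodes <- function(fastq, sample = "S1",
                             flank5 = default_params()$flank5,
                             flank3 = default_params()$flank3,
                             max_mismatch = default_params()$flank_mismatch,
                             barcode_length = default_params()$barcode_length) {
  seqs <- read_fastq_seqs(fastq)
  n <- length(seqs)
  if (n == 0L) {
    warning("no reads in input for sample ", sample)
    return(structure(list(
      counts = data.frame(barcode = character(), sample = character(),
                          reads = integer(), stringsAsFactors = FALSE),
      discarded = data.frame(reason = character(), reads = integer(),
                             stringsAsFactors = FALSE)),
      class = "barcode_counts"))
  }

  lf <- nchar(flank5)
  need <- lf + barcode_length + if (is.null(flank3)) 0L else nchar(flank3)
  reason <- rep(NA_character_, n)

  too_short <- nchar(seqs) < need
  reason[too_short] <- "too-short"

  mm <- hamming_prefix(seqs, flank5)
  flank_fail <- !too_short & (is.na(mm) | mm > max_mismatch)
  reason[flank_fail] <- "flank-fail"

  ok <- is.na(reason)
  bc <- substr(seqs, lf + 1L, lf + barcode_length)
  if (!is.null(flank3)) {
    after <- substr(seqs, lf + barcode_length + 1L,
                    lf + barcode_length + nchar(flank3))
    mm3 <- hamming_prefix(after, flank3)
    bad3 <- ok & (is.na(mm3) | mm3 > max_mismatch)
    reason[bad3] <- "flank3-fail"
    ok <- is.na(reason)
  }
  has_n <- ok & grepl("[^ACGT]", bc)
  reason[has_n] <- "N-in-barcode"
  ok <- is.na(reason)

  tab <- table(bc[ok])
  counts <- data.frame(barcode = as.character(names(tab)),
                       sample = rep(sample, length(tab)),
                       reads = as.integer(tab), stringsAsFactors = FALSE)
  counts <- counts[order(-counts$reads, counts$barcode), , drop = FALSE]
  rownames(counts) <- NULL

  dtab <- table(reason[!ok])
  discarded <- data.frame(reason = names(dtab), reads = as.integer(dtab),
                          stringsAsFactors = FALSE)
  structure(list(counts = counts, discarded = discarded),
            class = "barcode_counts")
}

#' Count barcodes for every sample in a sample sheet
#'
#' @param sample_sheet data.frame with columns `sample`, `fastq_path`, and
#'   optionally `condition`, `replicate`, `library`, `end_label`.
#' @param ... Passed to [extract_barcodes()].
#' @return `barcode_counts` object pooling all samples.
#' @export
count_samples <- function(sample_sheet, ...) {
  stopifnot(all(c("sample", "fastq_path") %in% names(sample_sheet)))
  res <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    extract_barcodes(sample_sheet$fastq_path[i],
                     sample = sample_sheet$sample[i], ...)
  })
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  disc <- do.call(rbind, lapply(seq_along(res), function(i) {
    d <- res[[i]]$discarded
    if (nrow(d)) d$sample <- sample_sheet$sample[i]
    d
  }))
  structure(list(counts = counts, discarded = disc),
            class = "barcode_counts")
}

## Candidate pairs for Levenshtein clustering by the pigeonhole principle:
## split each barcode into (max_edit + 1) chunks; two barcodes within edit
## distance max_edit must share at least one chunk, allowing the chunk to
## shift by up to max_edit positions in the partner. Index every barcode by
## (chunk index, chunk sequence at offsets -max_edit..max_edit) and emit
## pairs that collide. Verification is exact, so spurious collisions only
## cost time.
levenshtein_candidates <- function(barcodes, max_edit) {
  n <- length(barcodes)
  if (n < 2L) return(cbind(integer(0), integer(0)))
  len <- nchar(barcodes[1])
  k <- max_edit + 1L
  starts <- floor(seq(0, len, length.out = k + 1L))
  keys <- list(); ids <- list()
  for (j in seq_len(k)) {
    s <- starts[j] + 1L
    e <- starts[j + 1L]
    w <- e - s + 1L
    for (off in -max_edit:max_edit) {
      ss <- s + off
      if (ss < 1L || ss + w - 1L > len) next
      keys[[length(keys) + 1L]] <-
        paste0(j, ":", off == 0L, ":", substr(barcodes, ss, ss + w - 1L))
      ids[[length(ids) + 1L]] <- seq_len(n)
    }
  }
  # A pair is a candidate when barcode a's canonical chunk (offset 0) equals
  # barcode b's chunk at any offset. Bucket on (chunk index, sequence): the
  # offset-0 entries are the "anchors", any entry is a potential partner.
  key_all <- sub(":TRUE:", ":", sub(":FALSE:", ":", unlist(keys)))
  anchor <- grepl(":TRUE:", unlist(keys), fixed = TRUE)
  id_all <- unlist(ids)
  split_ids <- split(seq_along(id_all), key_all)
  pairs <- vector("list", length(split_ids))
  pi <- 0L
  for (idx in split_ids) {
    if (length(idx) < 2L) next
    a <- unique(id_all[idx[anchor[idx]]])
    b <- unique(id_all[idx])
    if (length(a) == 0L || length(b) < 2L) next
    grid <- expand.grid(a = a, b = b)
    grid <- grid[grid$a < grid$b, , drop = FALSE]
    if (nrow(grid)) {
      pi <- pi + 1L
      pairs[[pi]] <- as.matrix(grid)
    }
  }
  if (pi == 0L) return(cbind(integer(0), integer(0)))
  unique(do.call(rbind, pairs[seq_len(pi)]))
}

#' Group near-identical barcodes
#'
#' Barcodes within a small Levenshtein distance of an abundant barcode are
#' overwhelmingly PCR or sequencing errors of it, so they are clustered by
#' single linkage (union-find over all pairs at distance <= `max_edit`,
#' computed across the pooled barcode universe, not per sample) and counted
#' together. The canonical barcode of a group is its most abundant member
#' (ties broken by lexicographic order), and per-sample counts are summed
#' over members, so reads are conserved exactly.
#'
#' @param counts A `barcode_counts` object or a data.frame with columns
#'   `barcode`, `sample`, `reads`.
#' @param max_edit Maximum Levenshtein distance joining two barcodes.
#' @return A list of class `barcode_groups` with elements `counts`
#'   (data.frame: `canonical`, `sample`, `reads`), `members` (data.frame:
#'   `barcode`, `canonical`) and `groups` (data.frame: `canonical`,
#'   `n_members`, `total_reads`, sorted by total reads descending).
#' @export
group_barcodes <- function(counts, max_edit = default_params()$max_edit) {
  if (inherits(counts, "barcode_counts")) counts <- counts$counts
  stopifnot(max_edit >= 0, all(c("barcode", "sample", "reads") %in% names(counts)))
  barcodes <- sort(unique(counts$barcode))
  n <- length(barcodes)
  total <- tapply(counts$reads, factor(counts$barcode, levels = barcodes), sum)
  total[is.na(total)] <- 0

  if (max_edit == 0L || n < 2L) {
    comp <- seq_len(n)
  } else {
    cand <- levenshtein_candidates(barcodes, max_edit)
    if (nrow(cand)) {
      d <- mapply(function(a, b) utils::adist(barcodes[a], barcodes[b]),
                  cand[, 1], cand[, 2])
      keep <- d <= max_edit
      comp <- uf_components(n, cand[keep, 1], cand[keep, 2])
    } else {
      comp <- seq_len(n)
    }
  }

  # canonical per component: max total reads, tie -> lexicographically first
  ord <- order(comp, -as.numeric(total), barcodes)
  first <- !duplicated(comp[ord])
  canon_of_comp <- barcodes[ord][first]
  names(canon_of_comp) <- comp[ord][first]
  canonical <- canon_of_comp[as.character(comp)]

  members <- data.frame(barcode = barcodes, canonical = unname(canonical),
                        stringsAsFactors = FALSE)
  counts$canonical <- members$canonical[match(counts$barcode, members$barcode)]
  agg <- stats::aggregate(reads ~ canonical + sample, data = counts, FUN = sum)
  gtot <- tapply(agg$reads, agg$canonical, sum)
  groups <- data.frame(canonical = names(gtot),
                       n_members = as.integer(table(members$canonical)[names(gtot)]),
                       total_reads = as.integer(gtot), stringsAsFactors = FALSE)
  groups <- groups[order(-groups$total_reads, groups$canonical), , drop = FALSE]
  rownames(groups) <- NULL
  agg <- agg[order(match(agg$canonical, groups$canonical), agg$sample), ,
             drop = FALSE]
  rownames(agg) <- NULL
  structure(list(counts = agg[, c("canonical", "sample", "reads")],
                 members = members, groups = groups),
            class = "barcode_groups")
}

#' Build the barcode-by-sample count matrix
#'
#' @param groups A `barcode_groups` object (or its long `counts` data.frame).
#' @param sample_sheet data.frame with columns `sample`, `condition` and
#'   optionally `replicate`, `library`; defines column order and labels.
#' @return List of class `screen_counts`: `counts` (integer matrix, rows =
#'   canonical barcodes, columns = samples) and `samples` (the sheet rows in
#'   column order).
#' @export
build_count_matrix <- function(groups, sample_sheet) {
  long <- if (inherits(groups, "barcode_groups")) groups$counts else groups
  stopifnot(all(c("sample", "condition") %in% names(sample_sheet)))
  missing <- setdiff(unique(long$sample), sample_sheet$sample)
  if (length(missing)) {
    stop("samples present in counts but absent from sample sheet: ",
         paste(missing, collapse = ", "))
  }
  rows <- unique(long$canonical)
  mat <- matrix(0L, nrow = length(rows), ncol = nrow(sample_sheet),
                dimnames = list(rows, sample_sheet$sample))
  idx <- cbind(match(long$canonical, rows), match(long$sample, sample_sheet$sample))
  mat[idx] <- as.integer(long$reads)
  message("count matrix: ", nrow(mat), " barcode groups x ", ncol(mat),
          " samples; column sums ",
          paste(colnames(mat), colSums(mat), sep = "=", collapse = ", "))
  structure(list(counts = mat, samples = as.data.frame(sample_sheet)),
            class = "screen_counts")
}
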