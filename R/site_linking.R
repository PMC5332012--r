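#' Parse paired inverse-PCR reads
#'
#' Inverse-PCR amplicons carry the random barcode at one end and the
#' transposon-genome junction at the other, sequenced as a read pair. The
#' junction-side read must open with the transposon terminal sequence
#' (`expected_start`, checked by Hamming distance within `start_mismatch`)
#' and retain at least `min_genomic` genomic bases after trimming it;
#' otherwise the pair is discarded as `wrong-start` or `truncated`. The
#' barcode is extracted from the mate with the same flank logic as
#' [extract_barcodes()].
#'
#' @param fq_barcode,fq_junction Paths (or `DNAStringSet`s) for the
#'   barcode-side and junction-side reads; ids must pair up.
#' @param library Library identifier attached to every pair.
#' @param end_label Transposon end, `"PB3"` (West) or `"PB5"` (Sims).
#' @param expected_start Transposon terminal sequence opening the junction
#'   read.
#' @param flank5,max_mismatch,barcode_length Barcode-side flank settings, as in
#'   [extract_barcodes()].
#' @param start_mismatch Mismatch budget for `expected_start`.
#' @param min_genomic Minimum genomic bases required after trimming.
#' @return List of class `invpcr_pairs`: `pairs` (data.frame: `read_id`,
#'   `barcode`, `junction_seq`, `library`, `end_label`) and `discarded`
#'   (data.frame: `reason`, `reads`).
#' @export
parse_invpcr_pairs <- function(fq_barcode, fq_junction,
                               library = "L1", end_label = c("PB3", "PB5"),
                               expected_start = default_params()$expected_start,
                               flank5 = default_params()$flank5,
                               max_mismatch = default_params()$flank_mismatch,
                               start_mismatch = default_params()$start_mismatch,
                               min_genomic = default_params()$min_genomic,
                               barcode_length = default_params()$barcode_length) {
  end_label <- match.arg(end_label)
  if (!nzchar(expected_start)) stop("expected_start must be a non-empty sequence")
  bc_reads <- read_fastq_seqs(fq_barcode, with_ids = TRUE)
  jx_reads <- read_fastq_seqs(fq_junction, with_ids = TRUE)
  id_b <- sub("/[12]$", "", names(bc_reads))
  id_j <- sub("/[12]$", "", names(jx_reads))
  if (length(id_b) != length(id_j) || !all(id_b == id_j)) {
    stop("barcode and junction FASTQ files are not properly paired")
  }

  n <- length(bc_reads)
  reason <- rep(NA_character_, n)
  les <- nchar(expected_start)

  reason[nchar(jx_reads) < les + min_genomic] <- "truncated"
  mm_start <- hamming_prefix(jx_reads, expected_start)
  reason[is.na(reason) & (is.na(mm_start) | mm_start > start_mismatch)] <-
    "wrong-start"

  lf <- nchar(flank5)
  short_bc <- nchar(bc_reads) < lf + barcode_length
  reason[is.na(reason) & short_bc] <- "barcode-short"
  mm_flank <- hamming_prefix(bc_reads, flank5)
  reason[is.na(reason) & (is.na(mm_flank) | mm_flank > max_mismatch)] <-
    "barcode-flank-fail"
  bc <- substr(bc_reads, lf + 1L, lf + barcode_length)
  reason[is.na(reason) & grepl("[^ACGT]", bc)] <- "barcode-N"

  ok <- is.na(reason)
  pairs <- data.frame(read_id = id_j[ok],
                      barcode = bc[ok],
                      junction_seq = substr(jx_reads[ok], les + 1L,
                                            nchar(jx_reads[ok])),
                      library = library, end_label = end_label,
                      stringsAsFactors = FALSE)
  dtab <- table(reason[!ok])
  structure(list(pairs = pairs,
                 discarded = data.frame(reason = names(dtab),
                                        reads = as.integer(dtab),
                                        stringsAsFactors = FALSE)),
            class = "invpcr_pairs")
}

## Count matching characters between two equal-length strings.
count_matches <- function(a, b) {
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

## All ungapped hits of `query` in `ref` (named character vector of
## chromosome sequences), both strands, anchored by an exact seed of the
## query's first `seed_length` bases. Returns a data.frame of hits with the
## site coordinate convention: pos = reference base matching the query's
## first base (leftmost base of the window on +, rightmost on -).
ungapped_hits <- function(query, ref, seed_length, min_identity, min_match) {
  hits <- list()
  L <- nchar(query)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    seed <- if (strand == "+") substr(q, 1L, seed_length)
            else substr(q, L - seed_length + 1L, L)
    seed_off <- if (strand == "+") 0L else L - seed_length
    for (chrom in names(ref)) {
      occ <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(seed), Biostrings::DNAString(ref[[chrom]])))
      for (s in occ) {
        a_start <- s - seed_off         # window start for full query
        a_end <- a_start + L - 1L
        cs <- max(a_start, 1L); ce <- min(a_end, nchar(ref[[chrom]]))
        alen <- ce - cs + 1L
        if (alen < min_match) next
        qs <- cs - a_start + 1L
        matches <- count_matches(substr(q, qs, qs + alen - 1L),
                                 substr(ref[[chrom]], cs, ce))
        if (matches / alen < min_identity) next
        pos <- if (strand == "+") cs else ce
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, strand = strand, score = matches,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  unique(do.call(rbind, hits))
}

#' Map junction sequences to the reference
#'
#' Builtin mode is an exact-seed (default k = 16) plus ungapped-extension
#' aligner: a junction maps iff it has a unique best hit with at least
#' `min_identity` identity over at least `min_match` bases. SAM-import mode
#' takes alignments produced externally (e.g. by bwa) instead. The site
#' coordinate is the first genomic base after the transposon end: the
#' leftmost base of the aligned window for a forward hit, the rightmost for
#' a reverse-strand hit.
#'
#' @param pairs `invpcr_pairs` object or its `pairs` data.frame.
#' @param reference Named character vector, `DNAStringSet`, or FASTA path
#'   (builtin mode).
#' @param mode `"builtin"` or `"sam"`.
#' @param sam SAM file path (sam mode); read names must equal `read_id`.
#' @param seed_length,min_identity,min_match Builtin-aligner thresholds.
#' @return List of class `junction_hits`: `mapped` (data.frame: `read_id`,
#'   `barcode`, `library`, `end_label`, `chrom`, `pos`, `strand`) and
#'   `discarded` (reason tallies).
#' @export
map_junctions <- function(pairs, reference = NULL,
                          mode = c("builtin", "sam"), sam = NULL,
                          seed_length = default_params()$seed_length,
                          min_identity = default_params()$min_identity,
                          min_match = default_params()$min_match) {
  mode <- match.arg(mode)
  if (inherits(pairs, "invpcr_pairs")) pairs <- pairs$pairs
  if (mode == "builtin") {
    ref <- load_reference(reference)
    uq <- unique(pairs$junction_seq)
    res <- lapply(uq, function(j) {
      if (nchar(j) < max(seed_length, min_match)) return("too-short")
      h <- ungapped_hits(j, ref, seed_length, min_identity, min_match)
      if (is.null(h)) return("unmapped")
      best <- h[h$score == max(h$score), , drop = FALSE]
      if (nrow(best) > 1L) return("multimapping")
      best
    })
    names(res) <- uq
    is_fail <- vapply(res, is.character, logical(1))
    fail_reason <- unlist(res[is_fail])
    m <- match(pairs$junction_seq, uq)
    keep <- !is_fail[m]
    hit <- do.call(rbind, res[!is_fail])[match(pairs$junction_seq[keep],
                                               uq[!is_fail]), , drop = FALSE]
    mapped <- cbind(pairs[keep, c("read_id", "barcode", "library",
                                  "end_label"), drop = FALSE],
                    hit[, c("chrom", "pos", "strand"), drop = FALSE])
    rownames(mapped) <- NULL
    reason_per_read <- fail_reason[match(pairs$junction_seq[!keep],
                                         uq[is_fail])]
    dtab <- table(reason_per_read)
  } else {
    if (is.null(sam)) stop("sam mode requires a SAM file")
    aln <- read_sam_alignments(sam)
    if (!is.null(reference)) {
      ref <- load_reference(reference)
      bad <- setdiff(stats::na.omit(unique(aln$chrom)), names(ref))
      if (length(bad)) {
        stop("SAM references absent from FASTA: ", paste(bad, collapse = ", "))
      }
    }
    multi <- names(which(table(aln$read_id) > 1L))
    status <- rep("mapped", nrow(pairs))
    status[!pairs$read_id %in% aln$read_id] <- "unmapped"
    status[pairs$read_id %in% multi] <- "multimapping"
    m <- match(pairs$read_id, aln$read_id)
    status[!is.na(m) & is.na(aln$chrom[m])] <- "unmapped"
    keep <- status == "mapped"
    mapped <- cbind(pairs[keep, c("read_id", "barcode", "library",
                                  "end_label"), drop = FALSE],
                    aln[m[keep], c("chrom", "pos", "strand"), drop = FALSE])
    rownames(mapped) <- NULL
    dtab <- table(status[!keep])
  }
  structure(list(mapped = mapped,
                 discarded = data.frame(reason = names(dtab),
                                        reads = as.integer(dtab),
                                        stringsAsFactors = FALSE)),
            class = "junction_hits")
}

load_reference <- function(reference) {
  if (is.null(reference)) stop("builtin mode requires a reference")
  if (inherits(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (is.character(reference) && !is.null(names(reference))) {
    reference
  } else {
    stop("reference must be a FASTA path, DNAStringSet, or named character")
  }
}

## SAM alignments via Rsamtools; site coordinate derived from POS and the
## reference-consumed CIGAR length for reverse-strand hits. Unmapped records
## come back with chrom = NA.
read_sam_alignments <- function(sam) {
  bam <- Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar")))[[1]]
  rev <- bitwAnd(b$flag, 16L) != 0L
  unmapped <- bitwAnd(b$flag, 4L) != 0L
  ref_len <- cigar_ref_length(b$cigar)
  pos <- ifelse(rev, b$pos + ref_len - 1L, b$pos)
  data.frame(read_id = b$qname,
             chrom = ifelse(unmapped, NA_character_, as.character(b$rname)),
             pos = ifelse(unmapped, NA_integer_, pos),
             strand = ifelse(rev, "-", "+"),
             stringsAsFactors = FALSE)
}

## Reference bases consumed by a CIGAR string (M/D/N/=/X operations).
cigar_ref_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Tally integration sites from mapped pairs
#'
#' Aggregates mapped junction reads into candidate integration sites, one
#' per (chrom, pos, strand, end_label, library), with supporting read counts
#' and reads-per-million computed within each (library, end_label) mapping
#' run -- the denominator the downstream rpm filter expects.
#'
#' @param hits `junction_hits` object or its `mapped` data.frame.
#' @return data.frame: `chrom`, `pos`, `strand`, `end_label`, `library`,
#'   `reads`, `rpm`, sorted by (chrom, pos).
#' @export
tally_sites <- function(hits) {
  if (inherits(hits, "junction_hits")) hits <- hits$mapped
  key <- c("chrom", "pos", "strand", "end_label", "library")
  agg <- stats::aggregate(list(reads = rep(1L, nrow(hits))), hits[key], sum)
  run_total <- stats::aggregate(list(run_reads = agg$reads),
                                agg[c("library", "end_label")], sum)
  agg <- merge(agg, run_total, by = c("library", "end_label"))
  agg$rpm <- agg$reads / agg$run_reads * 1e6
  agg$run_reads <- NULL
  agg <- agg[order(agg$chrom, agg$pos, agg$strand, agg$end_label,
                   agg$library), c(key, "reads", "rpm")]
  rownames(agg) <- NULL
  agg
}

#' Filter and merge integration sites
#'
#' Sites supported by fewer than `min_rpm` reads per million (strict
#' less-than) within their mapping run are discarded. Surviving sites from
#' the same library, chromosome, strand and transposon end whose positions
#' lie within `window` bp of each other are combined transitively; the
#' merged site takes the position of its most-supported member (ties to the
#' smallest position) and the summed read count, so reads are conserved
#' after the filter.
#'
#' @param sites data.frame as from [tally_sites()].
#' @param min_rpm Reads-per-million threshold (sites below it are dropped).
#' @param window Merge radius in bp.
#' @return data.frame of merged sites with a `site_id` column, sorted by
#'   (chrom, pos); attribute `members` maps each surviving input site to its
#'   `site_id`.
#' @export
filter_and_merge_sites <- function(sites,
                                   min_rpm = default_params()$min_rpm,
                                   window = default_params()$merge_window) {
  keep <- sites$rpm >= min_rpm
  s <- sites[keep, , drop = FALSE]
  if (!nrow(s)) {
    out <- s
    out$site_id <- character(0)
    attr(out, "members") <- out
    return(out)
  }
  grp_key <- interaction(s$chrom, s$strand, s$library, s$end_label, drop = TRUE)
  ord <- order(grp_key, s$pos)
  s <- s[ord, , drop = FALSE]
  gk <- grp_key[ord]
  new_cluster <- c(TRUE, diff(s$pos) > window | gk[-1] != gk[-length(gk)])
  cluster <- cumsum(new_cluster)

  # clusters are numbered 1..K in (group, pos) order; one merged row each
  rep_idx <- vapply(split(seq_len(nrow(s)), cluster), function(ii) {
    ii[order(-s$reads[ii], s$pos[ii])][1]
  }, integer(1))
  merged <- s[rep_idx, , drop = FALSE]
  merged$reads <- as.integer(tapply(s$reads, cluster, sum))
  merged$rpm <- as.numeric(tapply(s$rpm, cluster, sum))
  ord2 <- order(merged$chrom, merged$pos, merged$strand, merged$end_label,
                merged$library)
  merged <- merged[ord2, , drop = FALSE]
  merged$site_id <- sprintf("site_%05d", seq_len(nrow(merged)))
  rownames(merged) <- NULL

  cluster_site <- merged$site_id[match(seq_along(rep_idx), ord2)]
  members <- s
  members$site_id <- cluster_site[cluster]
  rownames(members) <- NULL
  attr(merged, "members") <- members
  merged
}

#' Link canonical barcodes to merged integration sites
#'
#' Builds the barcode-to-site database: one link per (canonical barcode,
#' merged site) with its supporting read count. Links supported by fewer
#' than `min_link_reads` reads are dropped; a barcode still linked to more
#' than one merged site afterwards is flagged ambiguous. A barcode may
#' genuinely map to several sites when distinct mutants drew the same
#' barcode from a plasmid pool of limited complexity.
#'
#' @param hits `junction_hits` object or its `mapped` data.frame; barcodes
#'   should be canonical (see `groups`).
#' @param merged_sites Output of [filter_and_merge_sites()].
#' @param groups Optional `barcode_groups` object used to translate raw
#'   barcodes to canonical ones before linking.
#' @param min_link_reads Minimum supporting reads per link.
#' @return data.frame: `barcode`, `site_id`, `reads`, `ambiguous`.
#' @export
link_barcodes_to_sites <- function(hits, merged_sites, groups = NULL,
                                   min_link_reads = default_params()$min_link_reads) {
  if (inherits(hits, "junction_hits")) hits <- hits$mapped
  if (!is.null(groups)) {
    m <- match(hits$barcode, groups$members$barcode)
    hits$barcode <- ifelse(is.na(m), hits$barcode, groups$members$canonical[m])
  }
  members <- attr(merged_sites, "members")
  key_hit <- paste(hits$chrom, hits$pos, hits$strand, hits$end_label,
                   hits$library)
  key_mem <- paste(members$chrom, members$pos, members$strand,
                   members$end_label, members$library)
  hits$site_id <- members$site_id[match(key_hit, key_mem)]
  hits <- hits[!is.na(hits$site_id), , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(barcode = character(), site_id = character(),
                      reads = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(reads = rep(1L, nrow(hits))),
                          hits[c("barcode", "site_id")], sum)
  agg <- agg[agg$reads >= min_link_reads, , drop = FALSE]
  n_sites <- table(agg$barcode)
  agg$ambiguous <- as.integer(n_sites[agg$barcode]) > 1L
  agg <- agg[order(agg$barcode, agg$site_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Annotate integration sites with genes
#'
#' Assigns every gene whose gene-body span overlaps the site position
#' (1-based, strand-agnostic: the gene trap disrupts either orientation's
#' annotation candidates; orientation is recorded upstream but not used to
#' filter). Intergenic sites are labelled `"none"`.
#'
#' @param sites data.frame with `chrom`, `pos` and (optionally) `site_id`.
#' @param genes Gene models: data.frame from [read_gene_models()] or a GTF
#'   path.
#' @return data.frame: `site_id`, `chrom`, `pos`, `gene_id`, `gene_name`;
#'   one row per overlapping gene, or a single `"none"` row.
#' @export
annotate_sites <- function(sites, genes) {
  if (is.character(genes) && length(genes) == 1L) {
    genes <- read_gene_models(genes)
  }
  if (!"site_id" %in% names(sites)) {
    sites$site_id <- sprintf("site_%05d", seq_len(nrow(sites)))
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  annotated <- data.frame(site_id = sites$site_id[qi],
                          chrom = sites$chrom[qi], pos = sites$pos[qi],
                          gene_id = genes$gene_id[si],
                          gene_name = genes$gene_name[si],
                          stringsAsFactors = FALSE)
  orphan_idx <- setdiff(seq_len(nrow(sites)), unique(qi))
  if (length(orphan_idx)) {
    annotated <- rbind(annotated, data.frame(
      site_id = sites$site_id[orphan_idx],
      chrom = sites$chrom[orphan_idx], pos = sites$pos[orphan_idx],
      gene_id = "none", gene_name = "none", stringsAsFactors = FALSE))
  }
  annotated <- annotated[order(annotated$chrom, annotated$pos,
                               annotated$gene_id), , drop = FALSE]
  rownames(annotated) <- NULL
  annotated
}
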