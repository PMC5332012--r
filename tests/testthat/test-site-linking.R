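make_pair_fastqs <- function(bc_seqs, jx_seqs, ids = NULL) {
  ids <- ids %||% sprintf("p%03d", seq_along(bc_seqs))
  list(bc = write_test_fastq(bc_seqs, tempfile(fileext = ".fastq"), ids),
       jx = write_test_fastq(jx_seqs, tempfile(fileext = ".fastq"), ids))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("junction reads are kept only with the expected transposon start", {
  withr::with_seed(2, {
    bc <- random_barcodes(3)
    genomic <- random_barcodes(3, len = 60)
  })
  jx <- c(paste0(estart, genomic[1]),          # exact prefix
          paste0("GG", substr(estart, 3, nchar(estart)), genomic[2]),  # wrong
          paste0(estart, substr(genomic[3], 1, 10)))  # truncated
  fq <- make_pair_fastqs(paste0(flank, bc, "AA"), jx)
  res <- parse_invpcr_pairs(fq$bc, fq$jx, library = "L1", end_label = "PB3")
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$junction_seq, genomic[1])
  expect_equal(res$pairs$barcode, bc[1])
  expect_setequal(res$discarded$reason, c("wrong-start", "truncated"))
})

test_that("unpaired read ids are a hard error", {
  fq <- make_pair_fastqs(paste0(flank, strrep("A", 25)),
                         paste0(estart, strrep("C", 40)))
  fq2 <- write_test_fastq(paste0(estart, strrep("C", 40)),
                          tempfile(fileext = ".fastq"), ids = "other")
  expect_error(parse_invpcr_pairs(fq$bc, fq2, "L1", "PB3"), "paired")
  expect_error(parse_invpcr_pairs(fq$bc, fq$jx, "L1", "PB3",
                                  expected_start = ""), "non-empty")
})

test_that("builtin mapper agrees with a brute-force scan of every offset", {
  withr::with_seed(21, {
    ref <- c(chrA = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                          collapse = ""),
             chrB = paste(sample(c("A", "C", "G", "T"), 15000, TRUE),
                          collapse = ""))
    cases <- lapply(1:20, function(i) {
      chrom <- sample(names(ref), 1)
      start <- sample.int(nchar(ref[[chrom]]) - 70, 1)
      fwd <- sample(c(TRUE, FALSE), 1)
      win <- substr(ref[[chrom]], start, start + 59)
      list(chrom = chrom, start = start, fwd = fwd,
           seq = if (fwd) win else
             as.character(Biostrings::reverseComplement(
               Biostrings::DNAString(win))))
    })
  })
  pairs <- data.frame(read_id = sprintf("r%02d", seq_along(cases)),
                      barcode = strrep("A", 25),
                      junction_seq = vapply(cases, `[[`, "", "seq"),
                      library = "L1", end_label = "PB3")
  m <- map_junctions(pairs, reference = ref)$mapped
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    # brute-force: locate the junction (or its revcomp) at every offset
    hits_f <- gregexpr(cs$seq, ref[[cs$chrom]], fixed = TRUE)[[1]]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cs$seq)))
    hits_r <- gregexpr(rc, ref[[cs$chrom]], fixed = TRUE)[[1]]
    n_occ <- sum(hits_f > 0) + sum(hits_r > 0)
    row <- m[m$read_id == sprintf("r%02d", i), ]
    if (n_occ == 1L) {
      expect_equal(row$chrom, cs$chrom)
      if (cs$fwd) {
        expect_equal(row$pos, cs$start)
        expect_equal(row$strand, "+")
      } else {
        expect_equal(row$pos, cs$start + 59)
        expect_equal(row$strand, "-")
      }
    } else {
      expect_equal(nrow(row), 0L)
    }
  }
})

test_that("a junction present twice in the reference is multimapping", {
  withr::with_seed(4, {
    core <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    filler <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  })
  ref <- c(chr1 = paste0(filler, core, filler, core, filler))
  pairs <- data.frame(read_id = "r1", barcode = strrep("A", 25),
                      junction_seq = core, library = "L1", end_label = "PB3")
  m <- map_junctions(pairs, reference = ref)
  expect_equal(nrow(m$mapped), 0L)
  expect_equal(m$discarded$reason, "multimapping")
})

test_that("SAM import reproduces builtin positions including reverse strand", {
  withr::with_seed(31, {
    ref <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                          collapse = ""))
  })
  jx_f <- substr(ref, 101, 160)
  jx_r <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref, 301, 360))))
  pairs <- data.frame(read_id = c("a", "b"), barcode = strrep("A", 25),
                      junction_seq = c(jx_f, jx_r),
                      library = "L1", end_label = "PB3")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:5000",
    paste("a", 0, "chr1", 101, 60, "60M", "*", 0, 0, jx_f,
          strrep("I", 60), sep = "\t"),
    paste("b", 16, "chr1", 301, 60, "10M2D50M", "*", 0, 0,
          substr(ref, 301, 360), strrep("I", 60), sep = "\t")), sam)
  m <- map_junctions(pairs, mode = "sam", sam = sam)$mapped
  expect_equal(m$pos[m$read_id == "a"], 101)
  expect_equal(m$strand[m$read_id == "a"], "+")
  # reverse hit: pos = POS + reference-consumed CIGAR length - 1 (62 here)
  expect_equal(m$pos[m$read_id == "b"], 301 + 62 - 1)
  expect_equal(m$strand[m$read_id == "b"], "-")

  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrX\tLN:5000",
               paste("a", 0, "chrX", 101, 60, "60M", "*", 0, 0, jx_f,
                     strrep("I", 60), sep = "\t")), sam)
  expect_error(map_junctions(pairs[1, ], reference = ref, mode = "sam",
                             sam = sam), "absent from FASTA")
})

test_that("rpm filter is strict and boundary-exact", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 500L), strand = "+",
                      end_label = "PB3", library = "L1",
                      reads = c(9L, 10L), rpm = c(9, 10))
  out <- filter_and_merge_sites(sites, min_rpm = 10, window = 5)
  expect_equal(out$pos, 500L)
})

test_that("sites within 5 bp merge transitively to the most-supported position", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 104L, 106L, 200L, 206L),
                      strand = "+", end_label = "PB3", library = "L1",
                      reads = c(30L, 5L, 2L, 8L, 4L), rpm = 1000)
  out <- filter_and_merge_sites(sites, min_rpm = 10, window = 5)
  # 100-104-106 chain transitively (100 to 106 is 6 apart but linked via 104)
  expect_equal(out$pos, c(100L, 200L, 206L))
  expect_equal(out$reads, c(37L, 8L, 4L))
})

test_that("filter/merge matches the brute-force oracle on random site lists", {
  for (seed in 1:60) {
    withr::with_seed(seed, s <- random_site_table(sample(5:40, 1)))
    run <- aggregate(list(total = s$reads), s[c("library", "end_label")], sum)
    s <- merge(s, run)
    s$rpm <- s$reads / s$total * 1e6
    s$total <- NULL
    s <- s[sample(nrow(s)), c("chrom", "pos", "strand", "end_label",
                              "library", "reads", "rpm")]
    mine <- filter_and_merge_sites(s, min_rpm = 3e4, window = 5)
    oracle <- oracle_filter_merge(s, min_rpm = 3e4, window = 5)
    expect_equal(mine$pos, oracle$pos, label = paste("seed", seed))
    expect_equal(mine$reads, oracle$reads, label = paste("seed", seed))
    # conservation post-filter and idempotence
    expect_equal(sum(mine$reads), sum(s$reads[s$rpm >= 3e4]))
    again <- filter_and_merge_sites(mine[, names(s)], min_rpm = 3e4,
                                    window = 5)
    expect_equal(again$pos, mine$pos)
    expect_equal(again$reads, mine$reads)
  }
})

test_that("barcode-site links carry support thresholds and ambiguity flags", {
  mapped <- data.frame(
    read_id = sprintf("r%02d", 1:11),
    barcode = c(rep("BC1", 5), rep("BC2", 5), "BC2"),
    library = "L1", end_label = "PB3",
    chrom = "chr1",
    pos = c(rep(100L, 5), rep(300L, 3), rep(500L, 2), 700L),
    strand = "+")
  sites <- tally_sites(mapped)
  merged <- filter_and_merge_sites(sites, min_rpm = 10, window = 5)
  links <- link_barcodes_to_sites(mapped, merged, min_link_reads = 2)
  # BC1 -> one site, unambiguous; BC2 -> two sites with support >= 2 ->
  # ambiguous; its singleton link at pos 700 is dropped
  expect_equal(nrow(links), 3L)
  expect_false(links$ambiguous[links$barcode == "BC1"])
  expect_true(all(links$ambiguous[links$barcode == "BC2"]))
  expect_equal(sum(links$barcode == "BC2"), 2L)
})

test_that("gene annotation assigns overlapping genes and labels intergenic", {
  genes <- data.frame(gene_id = c("G1", "G2"), gene_name = c("GeneA", "GeneB"),
                      chrom = "chr1", start = c(100L, 150L),
                      end = c(200L, 250L), strand = "+")
  sites <- data.frame(chrom = "chr1", pos = c(175L, 99L, 220L),
                      site_id = c("s1", "s2", "s3"))
  ann <- annotate_sites(sites, genes)
  expect_setequal(ann$gene_id[ann$site_id == "s1"], c("G1", "G2"))
  expect_equal(ann$gene_id[ann$site_id == "s2"], "none")  # 1 bp outside
  expect_equal(ann$gene_id[ann$site_id == "s3"], "G2")
})

test_that("GTF round-trips through gene model reading and annotation", {
  genes <- data.frame(gene_id = "G1", gene_name = "GeneA", chrom = "chr1",
                      start = 500L, end = 1500L, strand = "+")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "test", "gene", 500, 1500, ".", "+", ".",
                   'gene_id "G1"; gene_name "GeneA";', sep = "\t"), gtf)
  gm <- read_gene_models(gtf)
  expect_equal(gm$start, 500L)
  expect_equal(gm$end, 1500L)
  ann <- annotate_sites(data.frame(chrom = "chr1", pos = 1000L,
                                   site_id = "s1"), gtf)
  expect_equal(ann$gene_id, "G1")

  bad <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "test", "gene", 500, 1500, ".", "+", ".",
                   'foo "bar";', sep = "\t"), bad)
  expect_error(read_gene_models(bad), "gene_id")
})
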