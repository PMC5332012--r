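#' Default pipeline parameters
#'
#' Single source of truth for every tunable parameter in the pipeline.
#' Command-line defaults and [run_pipeline()] configuration defaults are all
#' taken from this list, so the documented default and the effective default
#' cannot drift apart.
#'
#' @return Named list of default parameter values.
#' @export
default_params <- function() {
  list(
    barcode_length  = 25L,    # random barcode length at each transposon end
    flank5          = "ACGACGCTCTTCCGATCT",  # constant sequence 5' of the barcode
    flank3          = NULL,   # optional constant sequence 3' of the barcode
    flank_mismatch  = 2L,     # Hamming budget for the 5' flank match
    max_edit        = 2L,     # Levenshtein radius for barcode grouping
    expected_start  = "TTAACCCTAGAAAGATAGTCTGC",  # transposon terminal sequence
                              # opening every junction-side inverse-PCR read
    start_mismatch  = 0L,     # mismatch budget for expected_start
    min_genomic     = 20L,    # minimum genomic bases after trimming
    seed_length     = 16L,    # exact-seed length for the builtin junction mapper
    min_identity    = 0.95,   # identity threshold for a junction hit
    min_match       = 20L,    # minimum aligned length for a junction hit
    min_rpm         = 10,     # discard sites with fewer reads/million than this
    merge_window    = 5L,     # sites within this many bp are combined
    min_link_reads  = 2L,     # read support needed to keep a barcode-site link
    trim_logratio   = 0.3,    # TMM trim fraction on M values
    trim_abundance  = 0.05,   # TMM trim fraction on A values
    prior_count     = 0.125,  # prior count for log fold changes
    default_dispersion = 0.1, # fallback NB dispersion without replication
    fc_cutoff       = 1,      # |log2 FC| cutoff for gene hit calling
    p_cutoff        = 0.05,   # P-value cutoff for gene hit calling
    min_insertions  = 2L      # independent significant insertions per gene hit
  )
}

## Hamming distance between a fixed pattern and the same-length prefix of many
## reads, vectorised position by position (no indels: flank matching is a
## fixed-window comparison by design).
hamming_prefix <- function(reads, pattern) {
  n <- nchar(pattern)
  mm <- integer(length(reads))
  for (i in seq_len(n)) {
    mm <- mm + (substr(reads, i, i) != substr(pattern, i, i))
  }
  mm[nchar(reads) < n] <- NA_integer_
  mm
}

## Union-find with path compression over an edge list; returns component id
## per node (the smallest member index of its component).
uf_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

## Golden-section maximisation of f on [lo, hi].
golden_section_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol * (abs(a) + abs(b) + 1e-12)) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

## Reverse complement of plain character barcodes/reads.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Random DNA of given lengths.
random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

## Stable per-stage seed derived from a global seed; keeps derived seeds
## within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, library = 211L, selection = 307L, reads = 401L,
               counts = 503L, test = 601L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
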