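# Independent brute-force reference implementations used to grade the
# package's algorithms, plus small fixture builders. These deliberately use
# different code paths (all-pairs distance matrices, graph components,
# direct enumeration) from the implementations they check.

random_barcodes <- function(n, len = 25) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_barcode <- function(b, n_sub = 1) {
  s <- strsplit(b, "")[[1]]
  pos <- sample.int(length(s), n_sub)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

# single-linkage Levenshtein clustering by all-pairs distance matrix +
# graph connected components
oracle_cluster <- function(barcodes, max_edit) {
  d <- utils::adist(barcodes, barcodes)
  g <- igraph::graph_from_adjacency_matrix(d <= max_edit, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# rpm filter + transitive 5-bp merge by explicit pairwise closure
oracle_filter_merge <- function(sites, min_rpm, window) {
  s <- sites[sites$rpm >= min_rpm, , drop = FALSE]
  if (!nrow(s)) return(s)
  key <- paste(s$chrom, s$strand, s$library, s$end_label)
  n <- nrow(s)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    key[i] == key[j] & abs(s$pos[i] - s$pos[j]) <= window
  })
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected", diag = FALSE))$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(ii) {
    rep_i <- ii[order(-s$reads[ii], s$pos[ii])][1]
    r <- s[rep_i, , drop = FALSE]
    r$reads <- sum(s$reads[ii])
    r$rpm <- sum(s$rpm[ii])
    r
  }))
  out[order(out$chrom, out$pos, out$strand, out$end_label, out$library), ,
      drop = FALSE]
}

# exact conditional NB test by direct enumeration of dnbinom products
oracle_exact_test <- function(sA, sB, nA, nB, phi) {
  t <- sA + sB
  if (t == 0) return(1)
  a <- 0:t
  mu <- 10  # arbitrary per-sample mean; the conditional law is free of it
  if (phi == 0) {
    p <- dpois(a, nA * mu) * dpois(t - a, nB * mu)
  } else {
    p <- dnbinom(a, size = nA / phi, mu = nA * mu) *
      dnbinom(t - a, size = nB / phi, mu = nB * mu)
  }
  obs <- p[sA + 1]
  sum(p[p <= obs * (1 + 1e-12)]) / sum(p)
}

random_site_table <- function(n, n_chrom = 2, span = 300) {
  data.frame(
    chrom = sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE),
    pos = sample.int(span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    end_label = sample(c("PB3", "PB5"), n, replace = TRUE),
    library = sample(c("L1", "L2"), n, replace = TRUE),
    reads = sample.int(60, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# small FASTQ writer for hand-built fixtures
write_test_fastq <- function(seqs, path, ids = sprintf("read%03d", seq_along(seqs))) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

read_fastq_seqs_test <- function(path) {
  bartrap:::read_fastq_seqs(path, with_ids = TRUE)
}

flank <- bartrap::default_params()$flank5
estart <- bartrap::default_params()$expected_start
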