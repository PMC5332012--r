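#' Simulation configuration
#'
#' Defaults emulate the structure of the screen the package analyses: ten
#' pools of 10,000 transposon mutants, a finite barcoded-plasmid pool (so
#' distinct mutants can draw the same barcode), mainly single-copy
#' integrations with a 5% double-integration fraction, selection for eight
#' days at a drug dose killing 50% of wild-type-like cells, two drug and
#' two vehicle replicates, and roughly two million usable barcode reads per
#' sample. Growth is deterministic exponential with multiplicative
#' lognormal noise; `generations` is the number of doublings over the
#' selection period (default 8, one per day).
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param n_chroms,chrom_length,n_genes Synthetic genome shape.
#' @param n_pools,n_mutants_per_pool Library structure.
#' @param barcode_pool_size Distinct barcodes in the plasmid pool; finite to
#'   emulate barcode collisions.
#' @param multi_copy_fraction Fraction of mutants with two integrations.
#' @param generations Cell doublings over the selection period.
#' @param drug_survival Fraction of wild-type-like cells surviving the drug
#'   arm relative to vehicle (sets the default drug fitness).
#' @param noise_sigma Lognormal sigma on final per-mutant abundance.
#' @param cells_per_mutant Founding cells per mutant in a pool.
#' @param read_depth Barcode reads per screen sample.
#' @param n_replicates Replicates per condition.
#' @param error_rate Per-base substitution error rate in emitted reads.
#' @param pcr_jackpot Coefficient of variation of a gamma PCR-jackpot
#'   factor multiplying each mutant's molecule count (0 disables).
#' @param invpcr_reads_per_site Inverse-PCR read pairs per integration.
#' @param junction_length Genomic bases in each junction read.
#' @param sequenced_end Transposon end whose barcodes are sequenced in the
#'   screen samples.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 100000L,
                       n_genes = 20L, n_pools = 10L,
                       n_mutants_per_pool = 10000L,
                       barcode_pool_size = 1000000L,
                       multi_copy_fraction = 0.05,
                       generations = 8, drug_survival = 0.5,
                       noise_sigma = 0.3, cells_per_mutant = 200,
                       read_depth = 2000000L, n_replicates = 2L,
                       error_rate = 0.01, pcr_jackpot = 0,
                       invpcr_reads_per_site = 50L,
                       junction_length = 60L,
                       sequenced_end = "PB3") {
  cfg <- as.list(environment())
  stopifnot(cfg$barcode_pool_size >= 1, cfg$chrom_length >= 10000,
            cfg$generations > 0, cfg$noise_sigma >= 0, cfg$error_rate >= 0,
            cfg$drug_survival > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Validate a configuration list against [sim_config()]
#'
#' Unknown keys are rejected rather than silently ignored.
#' @param x Named list (e.g. parsed from YAML).
#' @return `sim_config` object.
#' @export
as_sim_config <- function(x) {
  known <- names(formals(sim_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown simulation config keys: ",
                        paste(bad, collapse = ", "))
  do.call(sim_config, x)
}

#' Simulate a reference genome and gene models
#'
#' Uniform-random DNA (which carries TTAA tetranucleotides at the expected
#' ~1/256 per-position density) with non-overlapping gene bodies; a TTAA is
#' injected at the centre of any gene span that happens to lack one, so
#' every gene is disruptable.
#'
#' @param config `sim_config`.
#' @return List: `genome` (named character vector of chromosome sequences)
#'   and `genes` (data.frame: `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`).
#' @export
simulate_genome_and_genes <- function(config) {
  set.seed(derive_seed(config$seed, "genome"))
  genome <- stats::setNames(random_dna(config$n_chroms, config$chrom_length),
                            paste0("chr", seq_len(config$n_chroms)))
  # non-overlapping gene bodies: partition each chromosome into slots and
  # place one gene inside every used slot
  per_chrom <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    slot <- floor(config$chrom_length / ng)
    if (slot < 3000L) stop("gene demand exceeds genome capacity: ",
                           ng, " genes on a ", config$chrom_length, " bp chromosome")
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      glen <- sample(2000:min(8000, slot - 1000L), 1)
      start <- (k - 1L) * slot + sample.int(slot - glen - 500L, 1) + 250L
      span <- substr(genome[ci], start, start + glen - 1L)
      if (!grepl("TTAA", span, fixed = TRUE)) {
        mid <- start + glen %/% 2L
        substr(genome[ci], mid, mid + 3L) <- "TTAA"
      }
      genes[[gi]] <- data.frame(
        gene_id = sprintf("GENE%04d", gi),
        gene_name = sprintf("Gm%04d", gi),
        chrom = names(genome)[ci], start = start, end = start + glen - 1L,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
  }
  list(genome = genome, genes = do.call(rbind, genes))
}

#' Write simulated genome and genes to FASTA and GTF
#' @param sim Output of [simulate_genome_and_genes()].
#' @param fasta,gtf Output paths.
#' @export
write_genome_files <- function(sim, fasta, gtf) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), fasta)
  gr <- GenomicRanges::GRanges(sim$genes$chrom,
                               IRanges::IRanges(sim$genes$start, sim$genes$end),
                               strand = sim$genes$strand)
  S4Vectors::mcols(gr)$source <- "bartrap_sim"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$gene_id <- sim$genes$gene_id
  S4Vectors::mcols(gr)$gene_name <- sim$genes$gene_name
  rtracklayer::export(gr, gtf, format = "gtf")
  invisible(list(fasta = fasta, gtf = gtf))
}

## Gene overlapping a position, by direct interval arithmetic (kept free of
## the annotation module on purpose: the truth table must not depend on the
## code it validates).
truth_gene_at <- function(genes, chrom, pos) {
  hit <- genes$chrom == chrom & genes$start <= pos & genes$end >= pos
  if (any(hit)) genes$gene_id[which(hit)[1]] else "none"
}

#' Simulate barcoded transposon libraries
#'
#' Each mutant receives one integration at a uniformly chosen internal TTAA
#' (a `multi_copy_fraction` of mutants receive a second), and independent
#' PB3/PB5 barcodes drawn with replacement from the finite plasmid pool, so
#' barcode collisions between mutants occur at the birthday-problem rate.
#' Integrations are laid down in a fixed orientation: the PB3 junction
#' flank runs rightward from the TTAA (site on the + strand, position
#' `ttaa_pos + 4`), the PB5 flank leftward (site on the - strand, position
#' `ttaa_pos - 1`).
#'
#' @param config `sim_config`.
#' @param sim Output of [simulate_genome_and_genes()].
#' @param n_pools,n_mutants_per_pool Optional overrides of the config.
#' @return List of class `sim_truth`: `mutants` (data.frame: `mutant_id`,
#'   `library`, `barcode_pb3`, `barcode_pb5`, `f_drug`, `f_vehicle`),
#'   `sites` (per mutant copy and end: `mutant_id`, `library`, `end_label`,
#'   `chrom`, `pos`, `strand`, `ttaa_pos`, `gene_id`), and `config`.
#' @export
simulate_library <- function(config, sim,
                             n_pools = config$n_pools,
                             n_mutants_per_pool = config$n_mutants_per_pool) {
  set.seed(derive_seed(config$seed, "library"))
  jl <- config$junction_length
  ttaa <- lapply(sim$genome, function(s) {
    p <- Biostrings::start(Biostrings::matchPattern("TTAA",
                                                    Biostrings::DNAString(s)))
    p[p > jl + 4L & p + 3L + jl + 4L < nchar(s)]
  })
  ttaa_tab <- data.frame(
    chrom = rep(names(ttaa), lengths(ttaa)),
    pos = unlist(ttaa, use.names = FALSE), stringsAsFactors = FALSE)

  mutants <- list(); sites <- list()
  mi <- 0L
  wt_drug_fitness <- 1 + log2(config$drug_survival) / config$generations
  for (lib in seq_len(n_pools)) {
    n <- n_mutants_per_pool
    ids <- sprintf("L%d_m%05d", lib, seq_len(n))
    bc3_id <- sample.int(config$barcode_pool_size, n, replace = TRUE)
    bc5_id <- sample.int(config$barcode_pool_size, n, replace = TRUE)
    mutants[[lib]] <- data.frame(
      mutant_id = ids, library = paste0("L", lib),
      barcode_pb3 = barcode_pool_seq(bc3_id, config$seed),
      barcode_pb5 = barcode_pool_seq(bc5_id, config$seed, salt = 1L),
      f_drug = wt_drug_fitness, f_vehicle = 1,
      stringsAsFactors = FALSE)
    n_copies <- 1L + stats::rbinom(n, 1L, config$multi_copy_fraction)
    site_rows <- sample.int(nrow(ttaa_tab), sum(n_copies), replace = TRUE)
    owner <- rep(seq_len(n), n_copies)
    sites[[lib]] <- data.frame(
      mutant_id = ids[owner], library = paste0("L", lib),
      chrom = ttaa_tab$chrom[site_rows],
      ttaa_pos = ttaa_tab$pos[site_rows], stringsAsFactors = FALSE)
  }
  mutants <- do.call(rbind, mutants)
  one_end <- do.call(rbind, sites)
  sites <- rbind(
    cbind(one_end, end_label = "PB3", pos = one_end$ttaa_pos + 4L,
          strand = "+", stringsAsFactors = FALSE),
    cbind(one_end, end_label = "PB5", pos = one_end$ttaa_pos - 1L,
          strand = "-", stringsAsFactors = FALSE))
  sites$gene_id <- vapply(seq_len(nrow(sites)), function(i) {
    truth_gene_at(sim$genes, sites$chrom[i], sites$pos[i])
  }, character(1))
  sites <- sites[order(sites$library, sites$mutant_id, sites$end_label), ,
                 drop = FALSE]
  rownames(mutants) <- rownames(sites) <- NULL
  structure(list(mutants = mutants, sites = sites, config = config),
            class = "sim_truth")
}

## Deterministic barcode sequence for a plasmid-pool member id: the pool is
## never materialised; each id is expanded to a 25-mer from its own seeded
## stream so two draws of the same id always collide to the same sequence.
barcode_pool_seq <- function(ids, seed, salt = 0L) {
  uq <- unique(ids)
  seqs <- vapply(uq, function(i) {
    set.seed((seed * 131 + i * 2 + salt) %% .Machine$integer.max)
    paste(sample(c("A", "C", "G", "T"), 25L, replace = TRUE), collapse = "")
  }, character(1))
  seqs[match(ids, uq)]
}

#' Set fitness for selected mutants
#'
#' @param truth `sim_truth`.
#' @param mutant_id Mutants to modify.
#' @param f_drug,f_vehicle New relative growth rates (1 = wild-type
#'   vehicle growth; the wild-type drug rate is derived from the configured
#'   drug survival).
#' @return Modified `sim_truth`.
#' @export
set_fitness <- function(truth, mutant_id, f_drug = NULL, f_vehicle = NULL) {
  i <- match(mutant_id, truth$mutants$mutant_id)
  if (anyNA(i)) stop("unknown mutant_id: ",
                     paste(mutant_id[is.na(i)], collapse = ", "))
  if (!is.null(f_drug)) truth$mutants$f_drug[i] <- f_drug
  if (!is.null(f_vehicle)) truth$mutants$f_vehicle[i] <- f_vehicle
  truth
}

#' Simulate drug or vehicle selection
#'
#' Deterministic exponential growth with multiplicative lognormal noise:
#' `cells_final = cells_0 * 2^(generations * f) * exp(N(0, sigma))`, with
#' the condition choosing which fitness column applies. A wild-type-like
#' mutant therefore ends the drug arm at `drug_survival` times its vehicle
#' abundance.
#'
#' @param truth `sim_truth`.
#' @param condition `"drug"` or `"vehicle"`.
#' @param cells0 Founding cells per mutant.
#' @return Named numeric vector of final cell counts per mutant.
#' @export
simulate_selection <- function(truth, condition = c("drug", "vehicle"),
                               cells0 = truth$config$cells_per_mutant) {
  condition <- match.arg(condition)
  f <- if (condition == "drug") truth$mutants$f_drug else truth$mutants$f_vehicle
  noise <- if (truth$config$noise_sigma > 0) {
    exp(stats::rnorm(nrow(truth$mutants), 0, truth$config$noise_sigma))
  } else 1
  stats::setNames(cells0 * 2^(truth$config$generations * f) * noise,
                  truth$mutants$mutant_id)
}

#' Simulate a barcode count matrix for one screened library
#'
#' Runs selection independently per replicate, optionally multiplies each
#' mutant's molecule count by a gamma PCR-jackpot factor, and samples reads
#' multinomially at the configured depth. Counts are reported per barcode
#' of the sequenced transposon end, so mutants sharing a barcode
#' (plasmid-pool collisions) are summed, exactly as a real screen would see
#' them.
#'
#' @param truth `sim_truth`.
#' @param library Library to screen (default: the first).
#' @param seed Seed for the selection/sampling randomness.
#' @return `screen_counts` object with `2 * n_replicates` columns plus a
#'   `truth_reads` attribute mapping mutants to their simulated counts.
#' @export
simulate_screen_counts <- function(truth, library = truth$mutants$library[1],
                                   seed = truth$config$seed) {
  set.seed(derive_seed(seed, "counts"))
  cfg <- truth$config
  sub <- truth$mutants[truth$mutants$library == library, , drop = FALSE]
  sub_truth <- truth; sub_truth$mutants <- sub
  bc <- if (cfg$sequenced_end == "PB3") sub$barcode_pb3 else sub$barcode_pb5

  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         condition = c("drug", "vehicle"),
                         stringsAsFactors = FALSE)
  samples$sample <- paste0(substr(samples$condition, 1, 1), samples$replicate)
  samples$library <- library

  per_mutant <- sapply(seq_len(nrow(samples)), function(k) {
    cells <- simulate_selection(sub_truth, samples$condition[k])
    w <- cells
    if (cfg$pcr_jackpot > 0) {
      shp <- 1 / cfg$pcr_jackpot^2
      w <- w * stats::rgamma(length(w), shape = shp, rate = shp)
    }
    as.integer(stats::rmultinom(1, cfg$read_depth, w))
  })
  rownames(per_mutant) <- sub$mutant_id
  colnames(per_mutant) <- samples$sample

  counts <- rowsum(per_mutant, group = bc)
  mode(counts) <- "integer"
  out <- structure(list(counts = counts,
                        samples = samples[, c("sample", "condition",
                                              "replicate", "library")]),
                   class = "screen_counts")
  attr(out, "truth_reads") <- per_mutant
  attr(out, "barcode_of_mutant") <- stats::setNames(bc, sub$mutant_id)
  out
}

#' Simulate a pure negative-binomial count matrix
#'
#' Direct NB sampling used for null calibration: every barcode has the same
#' expected count in every sample and dispersion `phi`.
#'
#' @param n_barcodes Rows.
#' @param n_per_group Columns per condition (drug, vehicle).
#' @param phi NB dispersion.
#' @param mean_count Expected count.
#' @return `screen_counts` object.
#' @export
simulate_nb_matrix <- function(n_barcodes = 1000L, n_per_group = 2L,
                               phi = 0.1, mean_count = 200) {
  n_samp <- 2L * n_per_group
  counts <- matrix(stats::rnbinom(n_barcodes * n_samp,
                                  mu = mean_count,
                                  size = if (phi > 0) 1 / phi else Inf),
                   nrow = n_barcodes,
                   dimnames = list(sprintf("bc%05d", seq_len(n_barcodes)),
                                   c(paste0("d", seq_len(n_per_group)),
                                     paste0("v", seq_len(n_per_group)))))
  structure(list(counts = counts,
                 samples = data.frame(
                   sample = colnames(counts),
                   condition = rep(c("drug", "vehicle"), each = n_per_group),
                   replicate = rep(seq_len(n_per_group), 2),
                   stringsAsFactors = FALSE)),
            class = "screen_counts")
}

## Apply per-base substitution errors to reads.
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Emit FASTQ reads for a simulated screen
#'
#' Writes one barcode-amplicon FASTQ per screen sample (reads = 5' flank +
#' barcode + constant tail) and one pair of inverse-PCR FASTQ files per
#' (library, transposon end): the barcode-side mate uses the same flank
#' structure, the junction-side mate is the transposon terminal sequence
#' followed by the genomic flank of the integration. Per-base substitution
#' errors are applied at the configured rate. Truth mutant ids are embedded
#' in read names for traceability; parsers must not rely on them.
#'
#' @param truth `sim_truth`.
#' @param sim Output of [simulate_genome_and_genes()].
#' @param counts `screen_counts` from [simulate_screen_counts()] (its
#'   `truth_reads` attribute drives barcode-read multiplicities). `NULL`
#'   skips barcode FASTQ output.
#' @param dir Output directory.
#' @param libraries Libraries for which to emit inverse-PCR reads.
#' @param gzip Compress outputs.
#' @return List: `sample_sheet` (data.frame describing barcode FASTQs) and
#'   `invpcr` (data.frame: `library`, `end_label`, `fastq_barcode`,
#'   `fastq_junction`).
#' @export
emit_reads <- function(truth, sim, counts = NULL, dir = tempfile("simreads"),
                       libraries = unique(truth$mutants$library),
                       gzip = FALSE) {
  cfg <- truth$config
  set.seed(derive_seed(cfg$seed, "reads"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  tail_seq <- "CTGTCTCTTATACACATCTGACGC"

  sheet <- NULL
  if (!is.null(counts)) {
    per_mutant <- attr(counts, "truth_reads")
    bc_of <- attr(counts, "barcode_of_mutant")
    sheet <- counts$samples
    sheet$fastq_path <- file.path(dir, paste0(sheet$sample, ext))
    for (k in seq_len(ncol(per_mutant))) {
      reps <- per_mutant[, k]
      owner <- rep(rownames(per_mutant), reps)
      seqs <- paste0(cfg$flank5 %||% default_params()$flank5,
                     rep(bc_of[rownames(per_mutant)], reps), tail_seq)
      seqs <- apply_errors(seqs, cfg$error_rate)
      ids <- sprintf("%s|%s|%07d", colnames(per_mutant)[k], owner,
                     seq_along(owner))
      write_fastq(seqs, ids, sheet$fastq_path[k])
    }
  }

  inv <- list()
  for (lib in libraries) {
    st <- truth$sites[truth$sites$library == lib, , drop = FALSE]
    mt <- truth$mutants[match(st$mutant_id, truth$mutants$mutant_id), ]
    for (end in c("PB3", "PB5")) {
      se <- st$end_label == end
      if (!any(se)) next
      s <- st[se, , drop = FALSE]
      bc <- if (end == "PB3") mt$barcode_pb3[se] else mt$barcode_pb5[se]
      nrep <- stats::rpois(nrow(s), cfg$invpcr_reads_per_site) + 1L
      flank <- vapply(seq_len(nrow(s)), function(i) {
        g <- sim$genome[[s$chrom[i]]]
        if (s$strand[i] == "+") {
          substr(g, s$pos[i], s$pos[i] + cfg$junction_length - 1L)
        } else {
          revcomp(substr(g, s$pos[i] - cfg$junction_length + 1L, s$pos[i]))
        }
      }, character(1))
      owner <- rep(seq_len(nrow(s)), nrep)
      ids <- sprintf("%s|%s|%s|%07d", lib, end, s$mutant_id[owner],
                     seq_along(owner))
      r1 <- apply_errors(paste0(default_params()$flank5, bc[owner], tail_seq),
                         cfg$error_rate)
      r2 <- apply_errors(paste0(default_params()$expected_start, flank[owner]),
                         cfg$error_rate)
      f1 <- file.path(dir, paste0("inv_", lib, "_", end, "_bc", ext))
      f2 <- file.path(dir, paste0("inv_", lib, "_", end, "_jx", ext))
      write_fastq(r1, ids, f1)
      write_fastq(r2, ids, f2)
      inv[[length(inv) + 1L]] <- data.frame(
        library = lib, end_label = end, fastq_barcode = f1,
        fastq_junction = f2, stringsAsFactors = FALSE)
    }
  }
  list(sample_sheet = sheet, invpcr = do.call(rbind, inv))
}
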