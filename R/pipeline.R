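#' Pipeline configuration
#'
#' Assembles and validates the end-to-end configuration. Unknown parameter
#' names are rejected; every tunable defaults to the value documented in
#' [default_params()].
#'
#' @param sample_sheet Path to (or data.frame of) the barcode-sample sheet:
#'   columns `sample`, `fastq_path`, `condition`, `replicate`, `library`.
#' @param invpcr_sheet Path to (or data.frame of) the inverse-PCR sheet:
#'   columns `library`, `end_label`, `fastq_barcode`, `fastq_junction`.
#' @param reference FASTA path (builtin mapping mode) or `NULL` with `sam`.
#' @param gtf Gene-model GTF path.
#' @param outdir Output directory.
#' @param sam Optional pre-computed SAM for import mode.
#' @param seed Global seed.
#' @param params Named list overriding entries of [default_params()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, invpcr_sheet, reference, gtf,
                            outdir, sam = NULL, seed = 1L, params = list()) {
  defaults <- default_params()
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown pipeline parameters: ",
                        paste(bad, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  for (f in c(gtf, if (is.character(reference)) reference, sam)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (is.character(invpcr_sheet)) invpcr_sheet <- read_tsv(invpcr_sheet)
  for (f in c(sample_sheet$fastq_path, invpcr_sheet$fastq_barcode,
              invpcr_sheet$fastq_junction)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  structure(list(sample_sheet = sample_sheet, invpcr_sheet = invpcr_sheet,
                 reference = reference, gtf = gtf, outdir = outdir,
                 sam = sam, seed = as.integer(seed), params = p),
            class = "pipeline_config")
}

#' Run the full screen deconvolution pipeline
#'
#' Executes count, group, link, map, filter, annotate, test and gene
#' stages, writing one TSV per stage plus a JSON run manifest (parameters,
#' input checksums, per-stage record counts) into the output directory.
#' With fixed inputs and seed the outputs are byte-identical across runs.
#'
#' @param config `pipeline_config` object.
#' @return (Invisibly) a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage <- function(name, n) message("[", name, "] ", n, " records")

  counted <- count_samples(config$sample_sheet, flank5 = p$flank5,
                           flank3 = p$flank3,
                           max_mismatch = p$flank_mismatch,
                           barcode_length = p$barcode_length)
  stage("count", nrow(counted$counts))

  pairs <- lapply(seq_len(nrow(config$invpcr_sheet)), function(i) {
    r <- config$invpcr_sheet[i, ]
    parse_invpcr_pairs(r$fastq_barcode, r$fastq_junction,
                       library = r$library, end_label = r$end_label,
                       expected_start = p$expected_start, flank5 = p$flank5,
                       max_mismatch = p$flank_mismatch,
                       start_mismatch = p$start_mismatch,
                       min_genomic = p$min_genomic,
                       barcode_length = p$barcode_length)
  })
  all_pairs <- do.call(rbind, lapply(pairs, `[[`, "pairs"))
  stage("link-parse", nrow(all_pairs))

  # pool barcodes from screen samples and inverse PCR for one grouping pass
  inv_counts <- stats::aggregate(
    list(reads = rep(1L, nrow(all_pairs))),
    data.frame(barcode = all_pairs$barcode, sample = "invpcr"), sum)
  groups <- group_barcodes(rbind(counted$counts, inv_counts),
                           max_edit = p$max_edit)
  stage("group", nrow(groups$groups))

  screen_groups <- groups
  screen_groups$counts <- groups$counts[groups$counts$sample != "invpcr", ,
                                        drop = FALSE]
  mat <- build_count_matrix(screen_groups, config$sample_sheet)

  mode <- if (is.null(config$sam)) "builtin" else "sam"
  hits <- map_junctions(all_pairs, reference = config$reference, mode = mode,
                        sam = config$sam, seed_length = p$seed_length,
                        min_identity = p$min_identity,
                        min_match = p$min_match)
  stage("map", nrow(hits$mapped))

  sites <- tally_sites(hits)
  merged <- filter_and_merge_sites(sites, min_rpm = p$min_rpm,
                                   window = p$merge_window)
  stage("filter-merge", nrow(merged))

  links <- link_barcodes_to_sites(hits, merged, groups = groups,
                                  min_link_reads = p$min_link_reads)
  annotations <- annotate_sites(merged, config$gtf)
  stage("annotate", nrow(annotations))

  results <- run_screen_test(mat, prior = p$prior_count)
  stage("test", nrow(results))

  joined <- join_results(results, links, annotations)
  gene_hits <- call_gene_hits(joined, fc_cutoff = p$fc_cutoff,
                              p_cutoff = p$p_cutoff,
                              min_insertions = p$min_insertions)
  stage("genes", nrow(gene_hits))

  out <- function(name) file.path(config$outdir, paste0(name, ".tsv"))
  count_tsv <- data.frame(barcode = rownames(mat$counts), mat$counts,
                          check.names = FALSE)
  write_tsv(count_tsv, out("counts"))
  write_tsv(counted$discarded, out("discards"))
  site_tab <- merge(merge(links, merged, by = "site_id"),
                    stats::aggregate(gene_id ~ site_id,
                                     data = annotations, FUN = paste,
                                     collapse = ","), by = "site_id")
  write_tsv(site_tab[, c("barcode", "chrom", "pos", "strand", "end_label",
                         "library", "reads.y", "rpm", "gene_id",
                         "ambiguous")], out("mapping"))
  write_tsv(as.data.frame(results), out("results"))
  write_tsv(joined$insertions, out("insertions"))
  write_tsv(as.data.frame(gene_hits), out("gene_hits"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("bartrap")),
    seed = config$seed, parameters = p,
    inputs = list(
      fastq_md5 = as.list(tools::md5sum(unique(c(
        config$sample_sheet$fastq_path,
        config$invpcr_sheet$fastq_barcode,
        config$invpcr_sheet$fastq_junction)))),
      gtf = config$gtf, reference = if (is.character(config$reference))
        config$reference else "in-memory"),
    records = list(barcodes = nrow(counted$counts),
                   groups = nrow(groups$groups),
                   mapped_pairs = nrow(hits$mapped),
                   merged_sites = nrow(merged),
                   links = nrow(links),
                   tested = nrow(results),
                   gene_hits = nrow(gene_hits)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = mat, groups = groups, pairs = all_pairs,
                 hits = hits, sites = sites, merged = merged, links = links,
                 annotations = annotations, results = results,
                 insertions = joined, gene_hits = gene_hits,
                 manifest = manifest))
}
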