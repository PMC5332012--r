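#' Join differential results to barcode-site-gene links
#'
#' Inner join on canonical barcode: each tested barcode is joined to its
#' merged integration site(s) and gene annotation(s) to produce a
#' per-insertion table. Barcodes linked to more than one merged site are
#' kept in the table with their ambiguity flag but are excluded from gene
#' tallies by default -- their depletion signal cannot be attributed to a
#' single locus. Barcodes with counts but no mapping are returned
#' separately as orphans.
#'
#' @param diff `screen_results` data.frame from [run_screen_test()].
#' @param links data.frame from [link_barcodes_to_sites()].
#' @param annotations data.frame from [annotate_sites()].
#' @return List of class `insertion_table`: `insertions` (per-insertion
#'   rows: barcode, site_id, gene_id, gene_name, logFC, PValue, FDR,
#'   ambiguous) and `orphans` (unmapped barcodes' result rows).
#' @export
join_results <- function(diff, links, annotations) {
  diff <- as.data.frame(diff)
  joined <- merge(diff, links, by = "barcode")
  joined <- merge(joined, annotations[, c("site_id", "gene_id", "gene_name")],
                  by = "site_id")
  orphans <- diff[!diff$barcode %in% links$barcode, , drop = FALSE]
  cols <- c("barcode", "site_id", "gene_id", "gene_name", "logFC", "PValue",
            "FDR", "reads", "ambiguous")
  if ("library" %in% names(joined)) cols <- c(cols, "library")
  joined <- joined[order(joined$PValue, joined$barcode, joined$site_id),
                   intersect(cols, names(joined)), drop = FALSE]
  rownames(joined) <- NULL
  rownames(orphans) <- NULL
  structure(list(insertions = joined, orphans = orphans),
            class = "insertion_table")
}

#' Call gene-level hits from multiple insertions
#'
#' A gene becomes a hit when at least `min_insertions` independent,
#' unambiguous insertions in it pass both the fold-change and P-value
#' cutoffs in a consistent direction. Evidence is combined across the
#' significant member insertions by Fisher's method (-2 sum ln P against
#' chi-square with 2k d.f.); insertions from different libraries count as
#' independent. Hits are ranked by number of significant insertions, then
#' combined P-value.
#'
#' @param insertions `insertion_table` or its `insertions` data.frame.
#' @param fc_cutoff Minimum |log2 fold change|.
#' @param p_cutoff Maximum P-value (raw `PValue` by default; set
#'   `use_fdr = TRUE` to cut on `FDR`).
#' @param min_insertions Minimum significant insertions per gene and
#'   direction.
#' @param use_fdr Cut on BH-adjusted P instead of raw P.
#' @param combine_all Combine all member insertions by Fisher's method
#'   instead of significant members only.
#' @return data.frame of class `gene_hits`: `gene_id`, `gene_name`,
#'   `direction`, `n_insertions_total`, `n_significant`, `n_libraries`,
#'   `median_logFC`, `combined_P`.
#' @export
call_gene_hits <- function(insertions,
                           fc_cutoff = default_params()$fc_cutoff,
                           p_cutoff = default_params()$p_cutoff,
                           min_insertions = default_params()$min_insertions,
                           use_fdr = FALSE, combine_all = FALSE) {
  stopifnot(fc_cutoff > 0, p_cutoff > 0)
  if (inherits(insertions, "insertion_table")) {
    insertions <- insertions$insertions
  }
  x <- insertions[!insertions$ambiguous & insertions$gene_id != "none", ,
                  drop = FALSE]
  if (!"library" %in% names(x)) x$library <- "all"
  p <- if (use_fdr) x$FDR else x$PValue
  x$significant <- abs(x$logFC) >= fc_cutoff & p <= p_cutoff
  x$direction <- ifelse(x$logFC < 0, "depleted", "enriched")
  x$pv <- p

  hits <- lapply(split(x, list(x$gene_id, x$direction), drop = TRUE),
                 function(g) {
    sig <- g[g$significant, , drop = FALSE]
    if (nrow(sig) < min_insertions) return(NULL)
    members <- if (combine_all) g else sig
    stat <- -2 * sum(log(pmax(members$pv, 1e-300)))
    data.frame(gene_id = g$gene_id[1], gene_name = g$gene_name[1],
               direction = g$direction[1],
               n_insertions_total = nrow(g),
               n_significant = nrow(sig),
               n_libraries = length(unique(sig$library)),
               median_logFC = stats::median(members$logFC),
               combined_P = stats::pchisq(stat, df = 2 * nrow(members),
                                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), gene_name = character(),
                      direction = character(), n_insertions_total = integer(),
                      n_significant = integer(), n_libraries = integer(),
                      median_logFC = numeric(), combined_P = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-out$n_significant, out$combined_P, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_hits", "data.frame")
  out
}
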