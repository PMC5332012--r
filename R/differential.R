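#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes between-sample scaling factors by the TMM method: for each
#' sample versus a reference column, gene-wise log ratios (M values) and
#' average log abundances (A values) are computed on barcodes nonzero in
#' both samples, both are trimmed (by default 30% of M and 5% of A from
#' each end), and the factor is the precision-weighted mean of the retained
#' M values. The reference column is the sample whose 75th-percentile
#' count-per-library-size is closest to the mean across samples. Factors
#' are rescaled to geometric mean 1, so they redistribute, never change,
#' the total library size.
#'
#' @param counts Count matrix (rows = barcode groups, columns = samples) or
#'   a `screen_counts` object.
#' @param trim_logratio Fraction of M values trimmed from each tail.
#' @param trim_abundance Fraction of A values trimmed from each tail.
#' @return List of class `norm_factors`: `factors` (named, geometric mean
#'   1), `lib_sizes` (column sums), `ref_column`.
#' @export
tmm_factors <- function(counts,
                        trim_logratio = default_params()$trim_logratio,
                        trim_abundance = default_params()$trim_abundance) {
  if (inherits(counts, "screen_counts")) counts <- counts$counts
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  uq <- apply(counts, 2, stats::quantile, p = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(counts)), function(i) {
    tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref],
             trim_logratio, trim_abundance)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = stats::setNames(f, colnames(counts)),
                 lib_sizes = lib, ref_column = colnames(counts)[ref]),
            class = "norm_factors")
}

## One TMM factor: observation column vs reference column.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_logratio, trim_abundance) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  # delta-method precision weights on binomial sampling of each count
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & A > -1e10
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_logratio) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_abundance) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  fval <- sum(M[keep] / w[keep], na.rm = TRUE) /
    sum(1 / w[keep], na.rm = TRUE)
  if (!is.finite(fval)) fval <- 0
  2^fval
}

#' Estimate the common negative-binomial dispersion
#'
#' Quantile-adjusted conditional maximum likelihood (qCML): counts are
#' mapped to pseudo-counts at a common library size (the geometric mean of
#' the effective library sizes) by matching quantiles of a moment-matched
#' gamma approximation to the NB, then the conditional log-likelihood --
#' conditioning each group on its barcode total, which removes the unknown
#' means -- is summed over barcodes and maximised over the dispersion by
#' golden-section search on \[1e-6, 10\] (log scale). Two rounds of
#' adjust-then-maximise are run, since the adjustment itself needs a
#' dispersion. With a single replicate per condition everywhere there is no
#' within-group information, and a configured default is returned with a
#' warning.
#'
#' @param counts Count matrix or `screen_counts` object.
#' @param group Condition label per column.
#' @param norm Optional `norm_factors`; effective library sizes are column
#'   sums times TMM factors.
#' @param default_dispersion Fallback without replication.
#' @return List of class `dispersion_estimate`: `dispersion`, `method`.
#' @export
estimate_common_dispersion <- function(counts, group, norm = NULL,
                                       default_dispersion = default_params()$default_dispersion) {
  if (inherits(counts, "screen_counts")) counts <- counts$counts
  group <- as.factor(group)
  stopifnot(ncol(counts) == length(group))
  if (max(table(group)) < 2L) {
    warning("no condition has replicates; using default dispersion ",
            default_dispersion)
    return(structure(list(dispersion = default_dispersion,
                          method = "default"),
                     class = "dispersion_estimate"))
  }
  lib <- colSums(counts)
  f <- if (is.null(norm)) rep(1, ncol(counts)) else norm$factors
  eff <- lib * f
  common <- exp(mean(log(eff)))

  keep <- rowSums(counts) > 0
  y <- counts[keep, , drop = FALSE]

  phi <- 0.01
  for (iter in 1:2) {
    pseudo <- quantile_adjust(y, group, eff, common, phi)
    ll <- function(lphi) cml_loglik(pseudo, group, exp(lphi))
    phi <- exp(golden_section_max(ll, log(1e-6), log(10), tol = 1e-8))
  }
  structure(list(dispersion = phi, method = "qCML"),
            class = "dispersion_estimate")
}

## Map counts to pseudo-counts at a common library size by gamma quantile
## matching: NB(mean mu, dispersion phi) ~ gamma(shape mu/(1+phi*mu),
## scale 1+phi*mu), which matches mean and variance. Identity when library
## sizes are already equal.
quantile_adjust <- function(y, group, eff, common, phi) {
  pseudo <- y
  for (g in levels(group)) {
    j <- which(group == g)
    p <- rowSums(y[, j, drop = FALSE]) / sum(eff[j])  # per-barcode proportion
    for (jj in j) {
      mu_in <- pmax(p * eff[jj], 1e-8)
      mu_out <- pmax(p * common, 1e-8)
      sh_in <- mu_in / (1 + phi * mu_in)
      sh_out <- mu_out / (1 + phi * mu_out)
      q <- stats::pgamma(y[, jj], shape = sh_in, scale = 1 + phi * mu_in)
      q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
      pseudo[, jj] <- stats::qgamma(q, shape = sh_out,
                                    scale = 1 + phi * mu_out)
      # preserve exact zeros: a zero count carries no fractional quantile
      pseudo[y[, jj] == 0, jj] <- 0
    }
  }
  pseudo
}

## Conditional log-likelihood of the dispersion given equalised library
## sizes: within each (barcode, group), conditioning on the group total z
## over n replicates leaves  sum_i lgamma(y_i + r) + lgamma(n r)
## - lgamma(z + n r) - n lgamma(r),  r = 1/phi.
cml_loglik <- function(y, group, phi) {
  r <- 1 / phi
  total <- 0
  for (g in levels(group)) {
    j <- which(group == g)
    n <- length(j)
    if (n < 2L) next
    z <- rowSums(y[, j, drop = FALSE])
    total <- total + sum(rowSums(lgamma(y[, j, drop = FALSE] + r)) +
                           lgamma(n * r) - lgamma(z + n * r) - n * lgamma(r))
  }
  total
}

#' Negative-binomial exact test for one barcode
#'
#' Two-group comparison of overdispersed counts, conditioning on the total.
#' The within-group sums of independent NB counts with a shared
#' mean-to-size ratio are themselves NB with proportionally larger size, so
#' given the total `t` the split follows a negative hypergeometric
#' distribution with parameters `nA/phi` and `nB/phi` that does not depend
#' on the (unknown) mean. The two-sided P-value is the total conditional
#' probability of every split whose probability does not exceed that of the
#' observed split (minimal-likelihood summation). In the `phi -> 0` limit
#' this reduces to the exact binomial test with success probability
#' `nA/(nA+nB)`.
#'
#' @param countsA,countsB Count vectors for the two groups (at equalised
#'   library sizes; non-integer pseudo-counts are rounded when summed).
#' @param phi Common NB dispersion (>= 0).
#' @return P-value in (0, 1]; `t = 0` returns 1 by convention.
#' @export
nb_exact_test <- function(countsA, countsB, phi) {
  if (phi < 0) stop("dispersion must be non-negative")
  if (any(c(countsA, countsB) < 0)) stop("counts must be non-negative")
  sA <- round(sum(countsA)); sB <- round(sum(countsB))
  t <- sA + sB
  if (t == 0) return(1)
  nA <- length(countsA); nB <- length(countsB)
  a <- 0:t
  if (phi < 1e-10) {
    logp <- stats::dbinom(a, t, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi; rB <- nB / phi
    logp <- lchoose(a + rA - 1, a) + lchoose(t - a + rB - 1, t - a) -
      lchoose(t + rA + rB - 1, t)
  }
  p <- exp(logp - max(logp))
  obs <- p[sA + 1]
  sum(p[p <= obs * (1 + 1e-12)]) / sum(p)
}

#' Log2 fold change of normalized abundance
#'
#' Prior-augmented counts-per-million: the prior count is scaled in
#' proportion to each sample's effective library size (so a constant
#' rescaling of one sample leaves its CPM unchanged), added to the count,
#' and the library size is offset by twice the scaled prior. The fold
#' change is the log2 ratio of mean CPM between the two conditions; the
#' prior keeps it finite when one condition has no reads.
#'
#' @param countsA,countsB Count vectors (drug, vehicle).
#' @param lib_sizesA,lib_sizesB Effective library sizes.
#' @param prior Prior count at the average library size.
#' @return log2 fold change (A vs B).
#' @export
log_fold_change <- function(countsA, countsB, lib_sizesA, lib_sizesB,
                            prior = default_params()$prior_count) {
  cpmA <- prior_cpm(countsA, lib_sizesA, c(lib_sizesA, lib_sizesB), prior)
  cpmB <- prior_cpm(countsB, lib_sizesB, c(lib_sizesA, lib_sizesB), prior)
  log2(mean(cpmA)) - log2(mean(cpmB))
}

prior_cpm <- function(counts, lib, all_lib, prior) {
  pr <- prior * lib / mean(all_lib)
  (counts + pr) / (lib + 2 * pr) * 1e6
}

#' Run the drug-vs-vehicle screen test
#'
#' The full per-barcode analysis: TMM normalization, common-dispersion
#' estimation, quantile adjustment of counts to a common library size, the
#' NB exact test, prior-augmented log2 fold changes, and
#' Benjamini-Hochberg adjustment across all tested barcodes. Barcodes with
#' zero counts in every sample are excluded from testing and from the BH
#' denominator. When the sample annotation carries a `library` column with
#' more than one level, each library is tested against its own replicates
#' and the results concatenated (BH still across all tested barcodes).
#'
#' @param counts `screen_counts` object, or a count matrix plus `design`.
#' @param design data.frame with a `condition` column (values `drug` /
#'   `vehicle`, or any two labels with `drug_label` naming the treatment);
#'   optional `library` column.
#' @param drug_label Condition label treated as the drug arm.
#' @param dispersion `"auto"` or a fixed numeric dispersion.
#' @param prior Prior count for fold changes.
#' @return data.frame of class `screen_results`: `barcode`, `logFC`,
#'   `PValue`, `FDR`, `meanCPM_drug`, `meanCPM_vehicle` (and `library` when
#'   split), sorted by P-value.
#' @export
run_screen_test <- function(counts, design = NULL, drug_label = "drug",
                            dispersion = "auto",
                            prior = default_params()$prior_count) {
  if (inherits(counts, "screen_counts")) {
    design <- design %||% counts$samples
    counts <- counts$counts
  }
  stopifnot(!is.null(design), "condition" %in% names(design),
            nrow(design) == ncol(counts))
  conds <- unique(design$condition)
  if (length(conds) < 2L) stop("design needs two conditions, got: ",
                               paste(conds, collapse = ", "))
  if (!drug_label %in% conds) stop("no '", drug_label, "' condition in design")

  libs <- if ("library" %in% names(design)) unique(design$library) else "all"
  res <- lapply(libs, function(lb) {
    j <- if (identical(libs, "all")) seq_len(ncol(counts))
         else which(design$library == lb)
    r <- screen_test_one(counts[, j, drop = FALSE], design$condition[j],
                         drug_label, dispersion, prior)
    if (!identical(libs, "all")) r$library <- lb
    r
  })
  out <- do.call(rbind, res)
  out$FDR <- stats::p.adjust(out$PValue, method = "BH")
  out <- out[order(out$PValue, -abs(out$logFC)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_results", "data.frame")
  out
}

screen_test_one <- function(counts, condition, drug_label, dispersion, prior) {
  is_drug <- condition == drug_label
  keep <- rowSums(counts) > 0
  y <- counts[keep, , drop = FALSE]
  norm <- tmm_factors(y)
  eff <- norm$lib_sizes * norm$factors
  phi <- if (identical(dispersion, "auto")) {
    estimate_common_dispersion(y, ifelse(is_drug, "drug", "vehicle"),
                               norm = norm)$dispersion
  } else as.numeric(dispersion)

  common <- exp(mean(log(eff)))
  grp <- factor(ifelse(is_drug, "drug", "vehicle"))
  pseudo <- quantile_adjust(y, grp, eff, common, phi)

  pA <- pseudo[, is_drug, drop = FALSE]
  pB <- pseudo[, !is_drug, drop = FALSE]
  pvals <- vapply(seq_len(nrow(y)), function(i) {
    nb_exact_test(pA[i, ], pB[i, ], phi)
  }, numeric(1))

  cpm_d <- t(t(y[, is_drug, drop = FALSE] + prior * eff[is_drug] / mean(eff)) /
               (eff[is_drug] + 2 * prior * eff[is_drug] / mean(eff))) * 1e6
  cpm_v <- t(t(y[, !is_drug, drop = FALSE] + prior * eff[!is_drug] / mean(eff)) /
               (eff[!is_drug] + 2 * prior * eff[!is_drug] / mean(eff))) * 1e6
  mean_d <- rowMeans(cpm_d)
  mean_v <- rowMeans(cpm_v)
  data.frame(barcode = rownames(y),
             logFC = log2(mean_d) - log2(mean_v),
             PValue = pvals,
             meanCPM_drug = mean_d,
             meanCPM_vehicle = mean_v,
             dispersion = phi,
             stringsAsFactors = FALSE)
}
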