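test_that("TMM factors: identical columns give 1, scaling is absorbed", {
  withr::with_seed(5, {
    y <- matrix(rnbinom(400 * 2, mu = 100, size = 5), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  })
  y[, 2] <- y[, 1]
  f <- tmm_factors(y)$factors
  expect_equal(unname(f), c(1, 1))

  # doubling one column changes library size, not composition: M values are
  # all zero so both factors stay 1
  y2 <- cbind(a = y[, 1], b = 2L * y[, 1])
  f2 <- tmm_factors(y2)$factors
  expect_equal(unname(f2), c(1, 1))
  expect_error(tmm_factors(cbind(a = y[, 1], b = 0L * y[, 1])), "all-zero")
})

test_that("TMM factors match the reference implementation to 1e-6", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      y <- matrix(rnbinom(500 * 4, mu = exp(runif(500 * 4, 2, 6)),
                          size = 5), ncol = 4,
                  dimnames = list(sprintf("b%03d", 1:500), paste0("s", 1:4)))
      # perturb a minority of barcodes to create composition bias
      y[1:50, 1] <- y[1:50, 1] * 5L
    })
    mine <- tmm_factors(y)$factors
    ref <- edgeR::calcNormFactors(y, method = "TMM")
    expect_lt(max(abs(mine - ref)), 1e-6)
  }
})

test_that("geometric mean of TMM factors is 1", {
  withr::with_seed(8, {
    y <- matrix(rnbinom(300 * 6, mu = 50, size = 2), ncol = 6)
  })
  colnames(y) <- paste0("s", 1:6)
  f <- tmm_factors(y)$factors
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
})

test_that("common dispersion recovers the Poisson limit and the truth", {
  withr::with_seed(12, {
    y_pois <- matrix(rpois(500 * 6, lambda = 500), ncol = 6)
  })
  d <- estimate_common_dispersion(y_pois, rep(c("a", "b"), each = 3))
  expect_lt(d$dispersion, 0.01)

  hits <- 0L
  for (seed in 1:10) {
    withr::with_seed(1000 + seed, {
      y <- matrix(rnbinom(500 * 6, mu = 200, size = 1 / 0.2), ncol = 6)
    })
    d <- estimate_common_dispersion(y, rep(c("a", "b"), each = 3))
    hits <- hits + (d$dispersion >= 0.15 && d$dispersion <= 0.25)
  }
  expect_gte(hits, 9L)
})

test_that("single replicates fall back to the default dispersion", {
  y <- matrix(c(10L, 20L, 30L, 40L), ncol = 2)
  expect_warning(d <- estimate_common_dispersion(y, c("a", "b")),
                 "default dispersion")
  expect_equal(d$dispersion, 0.1)
})

test_that("exact test equals brute-force enumeration for all small totals", {
  for (phi in c(0, 0.01, 0.1, 1)) {
    for (t in c(1, 5, 17, 50)) {
      for (sA in unique(c(0, 1, t %/% 3, t %/% 2, t))) {
        mine <- nb_exact_test(sA, t - sA, phi)
        oracle <- oracle_exact_test(sA, t - sA, 1, 1, phi)
        expect_equal(mine, oracle, tolerance = 1e-9,
                     label = sprintf("phi=%g t=%d sA=%d", phi, t, sA))
      }
    }
  }
  # unequal group sizes
  mine <- nb_exact_test(c(5, 3, 2), c(20, 18), 0.1)
  oracle <- oracle_exact_test(10, 38, 3, 2, 0.1)
  expect_equal(mine, oracle, tolerance = 1e-9)
})

test_that("exact test reaches the binomial limit as phi goes to zero", {
  for (case in list(c(3, 45), c(100, 150), c(0, 30))) {
    t <- sum(case)
    p_nb <- nb_exact_test(case[1], case[2], 0)
    p_binom <- stats::binom.test(case[1], t, p = 0.5)$p.value
    expect_equal(p_nb, p_binom, tolerance = 1e-6)
  }
})

test_that("exact test P-values are valid, symmetric, and tail-monotone", {
  expect_equal(nb_exact_test(0, 0, 0.1), 1)       # zero total, by convention
  expect_equal(nb_exact_test(c(25, 25), c(25, 25), 0.1), 1)  # balanced split
  expect_error(nb_exact_test(5, 5, -1), "non-negative")
  for (phi in c(0.05, 0.5)) {
    t <- 40
    p <- vapply(0:t, function(a) nb_exact_test(a, t - a, phi), numeric(1))
    expect_true(all(p > 0 & p <= 1))
    # symmetric in group swap
    swap <- vapply(0:t, function(a) nb_exact_test(t - a, a, phi), numeric(1))
    expect_equal(p, swap, tolerance = 1e-12)
    # monotone non-increasing moving away from the conditional mode
    mode_i <- which.max(p)
    expect_true(all(diff(p[mode_i:(t + 1)]) <= 1e-12))
    expect_true(all(diff(rev(p[1:mode_i])) <= 1e-12))
  }
})

test_that("exact test agrees with the reference small-P implementation", {
  withr::with_seed(33, {
    for (i in 1:20) {
      phi <- runif(1, 0.01, 0.5)
      yA <- matrix(rnbinom(2, mu = 50, size = 1 / phi), nrow = 1)
      yB <- matrix(rnbinom(2, mu = 50, size = 1 / phi), nrow = 1)
      mine <- nb_exact_test(yA[1, ], yB[1, ], phi)
      ref <- edgeR::exactTestBySmallP(yA, yB, dispersion = phi)
      expect_equal(mine, as.numeric(ref), tolerance = 1e-9)
    }
  })
})

test_that("log fold changes hit closed-form limits and stay finite", {
  lib <- rep(1e6, 4)
  expect_equal(log_fold_change(c(100, 100), c(100, 100), lib[1:2], lib[3:4]), 0)
  # halving at large counts: logFC -> -1 (prior shrinks it slightly)
  lfc <- log_fold_change(c(5000, 5000), c(10000, 10000), lib[1:2], lib[3:4])
  expect_equal(lfc, -1, tolerance = 0.05)
  # prior keeps zero drug counts finite
  lfc0 <- log_fold_change(c(0, 0), c(10000, 10000), lib[1:2], lib[3:4])
  expect_true(is.finite(lfc0) && lfc0 < -5)
})

test_that("screen test: label swap negates logFC and preserves P", {
  withr::with_seed(17, m <- simulate_nb_matrix(200, 2, 0.1, 150))
  r1 <- run_screen_test(m)
  design2 <- m$samples
  design2$condition <- ifelse(design2$condition == "drug", "vehicle", "drug")
  r2 <- run_screen_test(m$counts, design2)
  i <- match(r1$barcode, r2$barcode)
  expect_equal(r1$logFC, -r2$logFC[i], tolerance = 1e-9)
  expect_equal(r1$PValue, r2$PValue[i], tolerance = 1e-9)
  expect_error(run_screen_test(m$counts,
                               data.frame(condition = rep("drug", 4))),
               "two conditions")
})

test_that("screen test excludes all-zero barcodes and adjusts with BH", {
  withr::with_seed(19, m <- simulate_nb_matrix(100, 2, 0.1, 100))
  m$counts[1:5, ] <- 0L
  r <- run_screen_test(m)
  expect_equal(nrow(r), 95L)
  expect_true(all(r$FDR >= r$PValue - 1e-12))
  expect_equal(r$FDR, stats::p.adjust(r$PValue, "BH"))
})

test_that("a null screen stays calibrated at the nominal FDR", {
  withr::with_seed(23, m <- simulate_nb_matrix(800, 2, 0.1, 200))
  r <- run_screen_test(m)
  expect_lte(mean(r$FDR < 0.05), 0.05 + 0.02)
})

test_that("a strongly depleted spike-in is the top depleted barcode", {
  withr::with_seed(29, {
    m <- simulate_nb_matrix(400, 2, 0.05, 200)
    m$counts[1, m$samples$condition == "drug"] <- c(2L, 1L)
    m$counts[1, m$samples$condition == "vehicle"] <- c(210L, 190L)
  })
  r <- run_screen_test(m)
  dep <- r[r$logFC < 0, ]
  expect_equal(dep$barcode[1], "bc00001")
  expect_lt(r$FDR[r$barcode == "bc00001"], 0.05)
})
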