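test_that("gap masking excludes gaps and their neighbourhoods", {
  ident <- pairwise_alignment(strrep("A", 100), strrep("A", 100))
  expect_equal(count_alignment_differences(ident), list(D = 0L, L_aln = 100L))

  # 16 columns, gap at column 8, mismatch at column 16:
  # columns 4-12 masked, leaving 7 columns and the one substitution
  a <- rep("A", 16); b <- rep("A", 16)
  a[8] <- "-"; b[16] <- "C"
  aln <- pairwise_alignment(paste(a, collapse = ""),
                            paste(b, collapse = ""))
  expect_equal(count_alignment_differences(aln, 4), list(D = 1L, L_aln = 7L))

  # mismatch moved inside the mask is not counted
  b2 <- rep("A", 16); b2[10] <- "C"
  aln2 <- pairwise_alignment(paste(a, collapse = ""),
                             paste(b2, collapse = ""))
  expect_equal(count_alignment_differences(aln2, 4),
               list(D = 0L, L_aln = 7L))
})

test_that("rate calibration reproduces the published value and scales with T", {
  cal <- calibrate_rate(1227, 125531, 6e6)
  expect_equal(signif(cal$mu, 2), 8.1e-10)
  expect_equal(cal$mu, 1227 / (125531 * 2 * 6e6))
  expect_equal(calibrate_rate(0, 1000)$mu, 0)
  expect_equal(calibrate_rate(12, 1000, 6e6)$mu, 1e-9)
  # doubling the divergence time halves the rate
  expect_equal(calibrate_rate(1227, 125531, 12e6)$mu, cal$mu / 2)
})

test_that("modal haplotypes take per-site majorities with ancestral ties", {
  expect_identical(modal_haplotype(rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L))),
                   c(0L, 1L))
  expect_identical(modal_haplotype(rbind(c(0L, 0L), c(0L, 1L), c(0L, 1L))),
                   c(0L, 1L))
  expect_identical(modal_haplotype(rbind(c(0L, 1L), c(1L, 0L))), c(0L, 0L))
  expect_identical(modal_haplotype(rbind(c(0L, 1L), c(1L, 0L)),
                                   tie = "derived"), c(1L, 1L))
  expect_error(modal_haplotype(matrix(integer(0), 0, 2)), "empty")
})

test_that("differences from the modal haplotype count and average correctly", {
  geno <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  d <- diff_from_modal(geno, c(0L, 0L))
  expect_equal(d$counts, c(0L, 1L, 2L))
  expect_equal(d$total, 3L)
  expect_equal(d$mean, 1)
  # permuting chromosomes permutes counts, total unchanged
  d2 <- diff_from_modal(geno[c(3, 1, 2), ], c(0L, 0L))
  expect_equal(sort(d2$counts), sort(d$counts))
  expect_equal(d2$total, d$total)
})

test_that("age estimates reproduce the published per-sample dates", {
  mu <- calibrate_rate(1227, 125531, 6e6)
  expect_equal(round(estimate_age(822 / 1013, mu, 127419) / 1000, 1), 7.8)
  expect_equal(round(estimate_age(110 / 165, mu, 127419) / 1000, 1), 6.4)
  expect_equal(estimate_age(0, mu, 127419), 0)
})

test_that("the estimator is invariant to duplicating every chromosome", {
  sim <- simulate_star(n_chrom = 60, tmrca = 8000, seed = 12)
  g <- sim$panel$geno
  modal <- modal_haplotype(g)
  mu <- 8.145398e-10
  age1 <- estimate_age(diff_from_modal(g, modal)$mean, mu, 127419)
  g2 <- g[rep(seq_len(nrow(g)), each = 2), ]
  age2 <- estimate_age(diff_from_modal(g2, modal_haplotype(g2))$mean,
                       mu, 127419)
  expect_equal(age1, age2)
})

test_that("effective sample size follows the birthday process", {
  # a single class always duplicates on the second draw
  expect_equal(effective_sample_size(rep("x", 8), 500, seed = 1), 1)
  # two equal classes: P(count=1) = P(count=2) = 1/2 by enumeration,
  # so the median lies in [1, 2] and the observed frequencies match
  set.seed(2)
  counts <- replicate(4000, {
    seen <- character(0)
    repeat {
      d <- sample(c("a", "b"), 1)
      if (d %in% seen) break
      seen <- c(seen, d)
    }
    length(seen)
  })
  expect_equal(mean(counts == 1), 0.5, tolerance = 0.05)
  m <- effective_sample_size(c("a", "b"), 2000, seed = 3)
  expect_gte(m, 1); expect_lte(m, 2)
})

test_that("Garwood limits match chi-square quantiles and nest after scaling", {
  ci <- age_confidence_interval(10, 1000)
  expect_equal(ci[1], qchisq(0.025, 20) / 2 * 100, tolerance = 1e-12)
  expect_equal(ci[2], qchisq(0.975, 22) / 2 * 100, tolerance = 1e-12)
  expect_equal(round(ci / 100, 2), c(4.80, 18.39), tolerance = 0.01)

  # relative width shrinks as k grows; intervals for 2k nest inside k's
  for (k in c(2, 5, 20, 80)) {
    ci_k <- age_confidence_interval(k, 1000)
    ci_2k <- age_confidence_interval(2 * k, 1000)
    expect_true(ci_2k[1] > ci_k[1] && ci_2k[2] < ci_k[2])
  }
  big <- age_confidence_interval(1e6, 1000)
  expect_lt((big[2] - big[1]) / 1000, 0.01)
  expect_warning(z <- age_confidence_interval(0, 0), "degenerate")
  expect_equal(z[1], 0)
})

test_that("undercount correction is the power-weighted spectrum ratio", {
  expect_equal(undercount_correction(c(`1` = 5, `2` = 3),
                                     c(`1` = 1, `2` = 1)), 1)
  expect_equal(undercount_correction(c(`1` = 10, `2` = 5),
                                     c(`1` = 0.5, `2` = 1)), 25 / 15)
  expect_error(undercount_correction(c(`1` = 1), c(`2` = 1)),
               "no detection power")
  expect_error(undercount_correction(c(`1` = 1), c(`1` = 0)), "> 0")
  # monotone: raising any power never raises the factor
  set.seed(5)
  for (i in 1:20) {
    A <- setNames(rpois(4, 10) + 1, 1:4)
    P <- setNames(runif(4, 0.2, 0.9), 1:4)
    f <- undercount_correction(A, P)
    P2 <- P; j <- sample(4, 1); P2[j] <- min(1, P2[j] + 0.1)
    expect_lte(undercount_correction(A, P2), f)
  }
})

test_that("spectrum homogeneity testing matches the chi-square distribution", {
  expect_equal(round(pchisq(4.42, 5, lower.tail = FALSE), 2), 0.49)
  same <- substitution_spectrum_test(c(10, 20, 30), c(20, 40, 60))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  flat <- substitution_spectrum_test(c(10, 10), c(10, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$df, 1)
  # zero classes are pooled out with a warning
  expect_warning(
    z <- substitution_spectrum_test(c(a = 50, b = 0, c = 50),
                                    c(a = 40, b = 0, c = 60)),
    "zero expected")
  expect_equal(z$df, 1)
})

test_that("date_haplotype assembles the full report consistently", {
  mu <- calibrate_rate(1227, 125531, 6e6)
  est <- date_haplotype(1013, 822, 19, mu, 127419, correction_factor = 1.58)
  expect_equal(round(est$age_years / 1000, 1), 7.8)
  expect_equal(round(est$corrected_age_years / 1000, 1), 12.4)
  expect_equal(est$eff_count, 19 * 822 / 1013)
  expect_true(est$ci_years[1] < est$age_years &&
              est$age_years < est$ci_years[2])
  expect_equal(est$corrected_ci_years, est$ci_years * 1.58)
})
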