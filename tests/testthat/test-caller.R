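# Binomial false-positive model, q-values, candidate calling, hotspot
# flagging and final status assignment.

test_that("binomial false-positive probability matches closed forms and the exact oracle", {
  expect_equal(binomial_false_positive(1, 1, 0.005), 0.005)
  expect_equal(binomial_false_positive(2, 1, 0.5), 0.5)
  expect_equal(binomial_false_positive(200, 3, 0.005), 0.0612, tolerance = 1e-3)

  oracle <- read.delim(test_path("pmf-oracle.tsv"))
  got <- binomial_false_positive(oracle$n, oracle$k, oracle$p, mode = "pmf")
  rel <- abs(got - oracle$pmf) / pmax(oracle$pmf, .Machine$double.xmin)
  expect_lt(max(rel[oracle$pmf > 0]), 1e-10)

  # tail mode is the exceedance probability and dominates the point mass
  expect_equal(binomial_false_positive(10, 0, 0.005, mode = "tail"), 1)
  expect_gte(binomial_false_positive(200, 3, 0.005, mode = "tail"),
             binomial_false_positive(200, 3, 0.005, mode = "pmf"))
  expect_error(binomial_false_positive(5, 6, 0.005), "exceed")
})

test_that("the PMF is a probability mass function (sums to one)", {
  for (n in c(1L, 7L, 50L, 200L)) {
    expect_equal(sum(binomial_false_positive(n, 0:n, 0.005)), 1, tolerance = 1e-9)
    expect_equal(sum(binomial_false_positive(n, 0:n, 0.05)), 1, tolerance = 1e-9)
  }
})

test_that("q-values implement the step-up formula", {
  expect_equal(storey_qvalues(0.2, pi0 = 1), 0.2)
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.04), pi0 = 1), c(0.03, 0.03, 0.04))
  expect_equal(storey_qvalues(c(0.01, 0.02, 0.04), pi0 = 0.05),
               0.05 * c(0.03, 0.03, 0.04))
  expect_identical(storey_qvalues(numeric(0)), numeric(0))

  # double-loop oracle agreement on random inputs, including ties
  set.seed(31)
  for (i in 1:20) {
    p <- round(runif(sample(1:40, 1)), sample(1:3, 1))
    for (pi0 in c(1, 0.5, 0.05)) {
      expect_equal(storey_qvalues(p, pi0 = pi0), q_oracle(p, pi0 = pi0),
                   tolerance = 1e-12)
    }
  }
})

test_that("q-values are monotone along sorted p and bounded by pi0*m*p/rank", {
  set.seed(32)
  p <- runif(200)
  q <- storey_qvalues(p, pi0 = 0.05)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q[o] <= 0.05 * length(p) * p[o] / seq_along(p) + 1e-15))
})

test_that("pi0 estimation returns a proportion and reacts to signal", {
  set.seed(33)
  null_p <- runif(2000)
  expect_gt(estimate_pi0(null_p), 0.8)
  signal_p <- c(rbeta(1800, 0.2, 8), runif(200))
  expect_lt(estimate_pi0(signal_p), 0.6)
})

test_that("candidate calling applies the strict frequency threshold per alternate base", {
  cfg <- caller_config()
  counts <- mk_counts(list(A = 5900, G = 100),   # 1.67% -> candidate
                      list(A = 5910, G = 90),    # exactly 1.5% -> no candidate
                      list(A = 5785, G = 120, T = 95),  # multi-allelic
                      ref_seq = "AAA")
  cand <- call_candidates(counts, cfg, sample = "s1")
  expect_equal(nrow(cand), 2L)
  c1 <- cand[cand$pos == 1L, ]
  expect_identical(c1$variant, "G")
  expect_equal(c1$k, 100L)
  expect_equal(c1$n, 6000L)
  expect_equal(c1$freq, 100 / 6000)
  expect_false(c1$multi_allelic)
  c3 <- cand[cand$pos == 3L, ]
  expect_identical(c3$variant, "G")  # highest-count alternate represents the site
  expect_true(c3$multi_allelic)
  # zero-depth positions are skipped
  z <- mk_counts(list(), ref_seq = "A")
  expect_equal(nrow(call_candidates(z, cfg)), 0L)
})

test_that("homopolymer and adjacency hotspot rules flag the documented contexts", {
  ref <- ref_set(c(c1 = "GCAAAACTTTCGACGTACGA"), topology = "linear")
  calls <- data.frame(sample = "s", chrom = "c1",
                      pos = c(7L, 11L, 15L, 16L), stringsAsFactors = FALSE)
  # pos 7 (C) follows AAAA -> homopolymer; pos 11 (C) follows TTT (run of 3) -> clean
  flagged <- flag_hotspots(calls, ref)
  expect_identical(flagged$hotspot_homopolymer, c(TRUE, FALSE, FALSE, FALSE))
  # pos 15/16 are adjacent called sites: both flagged
  expect_identical(flagged$hotspot_adjacent, c(FALSE, FALSE, TRUE, TRUE))

  # 5' flank rule also applies on the other side (run after the site)
  ref2 <- ref_set(c(c2 = "ACGTCGGGGA"), topology = "linear")
  f2 <- flag_hotspots(data.frame(sample = "s", chrom = "c2", pos = 5L), ref2)
  expect_true(f2$hotspot_homopolymer)

  # circular wrap: first and last position are adjacent
  ref3 <- ref_set(c(c3 = "ACGTACGTAC"), topology = "circular")
  f3 <- flag_hotspots(data.frame(sample = "s", chrom = "c3", pos = c(1L, 10L)), ref3)
  expect_true(all(f3$hotspot_adjacent))
})

test_that("finalize assigns status in threshold order and reports attrition", {
  ref <- ref_set(c(c1 = strrep("ACGT", 10)), topology = "linear")
  cand <- data.frame(
    sample = "s", chrom = "c1", pos = c(2L, 6L, 10L),
    consensus = "C", variant = "T",
    k = c(100L, 4L, 120L), n = c(6000L, 200L, 6000L),
    freq = c(100 / 6000, 0.02, 0.02), multi_allelic = FALSE,
    stringsAsFactors = FALSE)
  cfg <- caller_config()
  res <- finalize_calls(cand, cfg, ref)
  expect_identical(res$calls$status, c("pass", "fail_pf", "pass"))
  expect_equal(res$attrition$n[res$attrition$stage == "pass"], 2L)
  # P_f at (200, 4): dbinom = 0.015 >= 0.01 -> fail_pf
  expect_gte(res$calls$p_f[2], cfg$pf_max)

  # a candidate passing the statistics but homopolymer-flagged fails on hotspot
  ref2 <- ref_set(c(c1 = paste0("GCAAAAC", strrep("ACGT", 8))), topology = "linear")
  cand2 <- data.frame(sample = "s", chrom = "c1", pos = 7L, consensus = "C",
                      variant = "T", k = 120L, n = 6000L, freq = 0.02,
                      multi_allelic = FALSE, stringsAsFactors = FALSE)
  res2 <- finalize_calls(cand2, cfg, ref2)
  expect_identical(res2$calls$status, "fail_hotspot")
  expect_equal(res2$attrition$n[res2$attrition$stage == "fail_hotspot"], 1L)
  # with the hotspot filter disabled the same candidate passes
  cfg_off <- caller_config(apply_hotspot_filter = FALSE)
  expect_identical(finalize_calls(cand2, cfg_off, ref2)$calls$status, "pass")

  # empty candidate set
  res0 <- finalize_calls(cand[0, ], cfg, ref)
  expect_equal(nrow(res0$calls), 0L)
})

test_that("no passing call sits at or below the frequency threshold", {
  sim <- sim_reference(sim_preset("louse"), seed = 41)
  pl <- sample_planted_sites(sim$ref, 30, freq = 0.02, seed = 42)
  simp <- simulate_pileup(sim$ref, pl, depth = 6000, seed = 43)
  res <- call_heteroplasmy(simp$counts, sim$ref, caller_config(), "s1")
  pass <- res$calls[res$calls$status == "pass", ]
  expect_true(all(pass$freq > 0.015))
  expect_true(all(pass$p_f >= 0 & pass$p_f <= 1))
  expect_true(all(pass$q_f >= 0 & pass$q_f <= 1))
})

test_that("minimum coverage for significance decreases with the frequency threshold", {
  min_cov <- function(f) {
    for (n in seq(60, 30000, by = 20)) {
      if (binomial_false_positive(n, ceiling(f * n), 0.005) < 0.01) return(n)
    }
    NA_integer_
  }
  covs <- vapply(c(0.01, 0.015, 0.03, 0.05), min_cov, numeric(1))
  expect_false(anyNA(covs))
  expect_true(all(diff(covs) < 0))
})
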