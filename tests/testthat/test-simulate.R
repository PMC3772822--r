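# Synthetic reference/pileup/read generation and truth-set evaluation.

test_that("presets produce the expected genome architectures deterministically", {
  sim <- sim_reference(sim_preset("louse"), seed = 1)
  expect_length(sim$ref$seqs, 20L)
  expect_true(all(sim$ref$lengths >= 3000 & sim$ref$lengths <= 4000))
  expect_true(all(table(sim$ann$chrom) >= 1 & table(sim$ann$chrom) <= 3))
  expect_equal(as.vector(table(sim$ann$class)[c("protein", "rRNA", "tRNA")]),
               c(12L, 2L, 22L))  # atp8-atp6 is one annotation unit

  tick <- sim_reference(sim_preset("tick"), seed = 1)
  expect_length(tick$ref$seqs, 1L)
  expect_equal(nrow(tick$ann), 36L)
  expect_gt(sum(tick$ann$length), 14000)

  # byte-identical outputs under a fixed seed
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  write_reference_set(sim_reference(sim_preset("louse"), seed = 9)$ref, fa1)
  write_reference_set(sim_reference(sim_preset("louse"), seed = 9)$ref, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  # different seed, different sequence
  fa3 <- tempfile(fileext = ".fa")
  write_reference_set(sim_reference(sim_preset("louse"), seed = 10)$ref, fa3)
  expect_false(identical(readLines(fa1), readLines(fa3)))
})

test_that("planted variant counts follow the binomial model", {
  ref <- sim_reference(sim_preset("louse"), seed = 2)$ref
  pl <- sample_planted_sites(ref, 40, freq = 0.05, seed = 3)
  simp <- simulate_pileup(ref, pl, depth = 2000, seed = 4, fixed_depth = TRUE)
  m <- as.matrix(simp$counts[, c("A", "C", "G", "T")])
  key <- paste(simp$counts$chrom, simp$counts$pos)
  idx <- match(paste(pl$chrom, pl$pos), key)
  kvar <- m[cbind(idx, match(pl$minor, c("A", "C", "G", "T")))]
  # mean 2000 * 0.05 * 0.995 = 99.5, sd ~9.7; all draws within 4.5 sd
  expect_true(all(abs(kvar - 99.5) < 4.5 * sqrt(2000 * 0.05 * 0.95)))
  expect_equal(mean(kvar), 99.5, tolerance = 0.08)
})

test_that("null pileups carry only ~p/3 errors per alternate base and none at p = 0", {
  ref <- ref_set(c(c1 = strrep("ACGT", 2000)), topology = "circular")
  simp <- simulate_pileup(ref, NULL, depth = 6000, seed = 5, fixed_depth = TRUE)
  m <- as.matrix(simp$counts[, c("A", "C", "G", "T")])
  alt <- m
  alt[cbind(seq_len(nrow(m)), match(simp$counts$ref, c("A", "C", "G", "T")))] <- NA
  # expected error count per alternate base: 6000 * 0.005 / 3 = 10
  expect_equal(mean(alt, na.rm = TRUE), 10, tolerance = 0.05)

  clean <- simulate_pileup(ref, NULL, depth = 100, error_rate = 0,
                           seed = 6, fixed_depth = TRUE)
  cm <- as.matrix(clean$counts[, c("A", "C", "G", "T")])
  expect_true(all(cm[cbind(seq_len(nrow(cm)),
                           match(clean$counts$ref, c("A", "C", "G", "T")))] == 100L))
  expect_equal(sum(cm), 100L * nrow(cm))
})

test_that("emitted reads rebuild the pileup exactly and planted low-quality reads are dropped", {
  ref <- ref_set(c(chrA = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
                   chrB = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")),
                 topology = "circular")
  pl <- sample_planted_sites(ref, 8, freq = 0.2, seed = 12)
  simp <- simulate_pileup(ref, pl, depth = 10, seed = 13, fixed_depth = TRUE)
  er <- emit_reads(simp$counts, ref, read_length = 120, n_lowq = 5, seed = 14)
  rebuilt <- build_site_counts(er$sam, ref)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(as.integer(rebuilt[[b]]), as.integer(simp$counts[[b]]))
  }
  # every site is covered by >= depth read bases
  expect_true(all(rebuilt$depth == 10L))

  fq <- read_fastq(er$fastq)
  out <- filter_reads(fq)
  expect_equal(out$report$n_dropped, 5L)  # exactly the injected low-quality reads

  # varying depth is refused
  vary <- simp$counts
  vary$A[1] <- vary$A[1] + 5L
  vary$depth[1] <- vary$depth[1] + 5L
  expect_error(emit_reads(vary, ref), "constant depth")
})

test_that("call evaluation computes recall, precision and frequency error", {
  truth <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L),
                      minor = c("G", "T", "C"), freq = 0.05,
                      is_artifact = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "c1", pos = c(10L, 20L),
                      variant = c("G", "T"), freq = c(0.048, 0.055),
                      stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$mean_freq_error, mean(c(0.002, 0.005)))
  # half recovered
  ev2 <- evaluate_calls(calls[1, ], truth)
  expect_equal(ev2$recall, 0.5)
  # empty truth -> recall undefined
  ev3 <- evaluate_calls(calls, truth[truth$is_artifact, ])
  expect_true(is.na(ev3$recall))
})

test_that("planted-frequency estimates are unbiased", {
  ref <- sim_reference(sim_preset("louse"), seed = 81)$ref
  pl <- sample_planted_sites(ref, 1000, freq = 0.05, seed = 82)
  simp <- simulate_pileup(ref, pl, depth = 6000, seed = 83)
  res <- call_heteroplasmy(simp$counts, ref, caller_config(), "s1")
  ev <- evaluate_calls(res$calls[res$calls$status == "pass", ], simp$truth)
  # under the generator model the expected minor-base frequency is
  # f(1-p) + p/3 (planted reads plus uniform error on the same base)
  expected <- ev$site_errors$true_freq * (1 - 0.005) + 0.005 / 3
  err <- ev$site_errors$called_freq - expected
  # mean deviation from the model expectation within 3 standard errors
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se + 1e-6)
  expect_gt(length(err), 950)
})

test_that("the hotspot filter removes injected artifacts but spares planted sites", {
  ref <- sim_reference(sim_preset("louse"), seed = 91)$ref
  pl <- sample_planted_sites(ref, 100, freq = 0.05, seed = 92)
  simp <- simulate_pileup(ref, pl, depth = 6000, seed = 93, n_artifacts = 40)
  art <- simp$truth[simp$truth$is_artifact, ]
  expect_equal(nrow(art), 40L)

  res_on <- call_heteroplasmy(simp$counts, ref, caller_config(), "s1")
  pass_on <- res_on$calls[res_on$calls$status == "pass", ]
  res_off <- call_heteroplasmy(simp$counts, ref,
                               caller_config(apply_hotspot_filter = FALSE), "s1")
  pass_off <- res_off$calls[res_off$calls$status == "pass", ]

  art_key <- paste(art$chrom, art$pos)
  called_art_off <- sum(paste(pass_off$chrom, pass_off$pos) %in% art_key)
  called_art_on <- sum(paste(pass_on$chrom, pass_on$pos) %in% art_key)
  expect_gt(called_art_off, 0)  # artifacts do get called without the filter
  expect_lte(called_art_on, 0.05 * called_art_off)  # >= 95% removed

  # planted (non-artifact) sites survive the filter
  ev_on <- evaluate_calls(pass_on, simp$truth)
  ev_off <- evaluate_calls(pass_off, simp$truth)
  expect_gte(ev_on$recall, 0.99 * ev_off$recall)
  expect_gt(ev_on$precision, ev_off$precision)  # the filter raises precision
})
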