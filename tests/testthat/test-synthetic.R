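test_that("generation is deterministic for a fixed seed", {
  spec <- synthetic_spec(400L, background_rate = 0.05,
                         clusters = data.frame(center = 200, sd = 5, n = 15,
                                               source = "clinical"),
                         seed = 42L)
  a <- generate_variants(spec)
  b <- generate_variants(spec)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$population, b$population)
  expect_identical(a$truth, b$truth)
  c2 <- generate_variants(synthetic_spec(400L, 0.05,
                                         data.frame(center = 200, sd = 5,
                                                    n = 15,
                                                    source = "clinical"),
                                         seed = 43L))
  expect_false(identical(a$population$raw_hgvs, c2$population$raw_hgvs))
})

test_that("clusters are clipped to range with exact n, and empty specs give empty tables", {
  spec <- synthetic_spec(500L, background_rate = 0,
                         clusters = data.frame(center = 400, sd = 8, n = 20,
                                               source = "clinical"),
                         seed = 7L)
  sim <- generate_variants(spec)
  expect_equal(nrow(sim$clinical), 20L)
  expect_true(all(sim$clinical$position >= 1L & sim$clinical$position <= 500L))
  expect_true(all(abs(sim$clinical$position - 400) <= 5 * 8))
  expect_equal(nrow(sim$population), 0L)
  expect_equal(sim$truth$start, 400L - 16L)
  expect_equal(sim$truth$end, 400L + 16L)

  empty <- generate_variants(synthetic_spec(100L, 0, seed = 1L))
  expect_equal(nrow(empty$clinical), 0L)
  expect_equal(nrow(empty$population), 0L)
})

test_that("records at one residue carry distinct substitutions so dedupe keeps them", {
  spec <- synthetic_spec(30L, background_rate = 2, seed = 3L)
  sim <- generate_variants(spec)
  expect_gt(nrow(sim$population), 30L)  # duplicates at some residues
  expect_equal(nrow(dedupe_variants(sim$population)), nrow(sim$population))
  expect_true(all(sim$population$consequence == "missense"))
})

test_that("impossible specs are rejected", {
  expect_error(synthetic_spec(100L, background_rate = -1),
               class = "senscan_spec_error")
  expect_error(synthetic_spec(100L, clusters = data.frame(
    center = 50, sd = 0, n = 5, source = "clinical")),
    class = "senscan_spec_error")
  expect_error(synthetic_spec(100L, clusters = data.frame(
    center = 500, sd = 5, n = 5, source = "clinical")),
    class = "senscan_spec_error")
  expect_error(generate_transcript(integer(0)), class = "senscan_spec_error")
  expect_error(generate_transcript(c(100L, 102L)),
               class = "senscan_spec_error")
})

test_that("background counts match the Poisson rate over seeded replicates", {
  L <- 300L
  rate <- 0.05
  n_rep <- 200L
  counts <- vapply(seq_len(n_rep), function(s) {
    nrow(generate_variants(synthetic_spec(L, rate, seed = s))$population)
  }, numeric(1))
  expected <- rate * L
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("depleted windows carry no background variants", {
  spec <- synthetic_spec(400L, background_rate = 0.5,
                         depleted_windows = data.frame(start = 100L,
                                                       end = 200L),
                         seed = 5L)
  sim <- generate_variants(spec)
  expect_false(any(sim$population$position >= 100L &
                     sim$population$position <= 200L))
  expect_gt(nrow(sim$population), 0L)
})

test_that("toy transcripts have invertible exon lookup", {
  tr <- generate_transcript(c(300L, 300L, 402L))
  expect_equal(tr$protein_length, 333L)
  bounds <- cumsum(tr$cds_exon_lengths)
  for (nt in c(1L, 300L, 301L, 600L, 601L, 1002L)) {
    expect_equal(cds_to_exon(tr, nt), findInterval(nt - 1L, c(0L, bounds)))
  }
})
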