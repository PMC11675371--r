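test_that("the Gaussian window kernel is unit-sum, symmetric and unimodal", {
  for (w in c(1L, 5L, 31L, 61L)) {
    k <- gaussian_window_kernel(w)
    expect_length(k, w)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, rev(k))
    expect_equal(which.max(k), (w + 1L) %/% 2L)
    if (w > 1L) expect_true(all(diff(k[1:((w + 1L) %/% 2L)]) > 0))
  }
  expect_identical(gaussian_window_kernel(1L), 1.0)
  expect_error(gaussian_window_kernel(30L), class = "senscan_config_error")
  expect_error(gaussian_window_kernel(31L, sigma = 0),
               class = "senscan_config_error")
})

test_that("a single interior variant produces an impulse peaking at the kernel center", {
  cu <- density_curve(missense_at(100L), 200L)
  k <- gaussian_window_kernel(31L)
  expect_equal(which.max(cu$values), 100L)
  expect_equal(max(cu$values), k[16L], tolerance = 1e-12)
  expect_true(all(cu$values >= 0))
})

test_that("no variants give an all-zero curve; out-of-range variants warn and are dropped", {
  cu <- density_curve(missense_at(integer(0)), 150L)
  expect_true(all(cu$values == 0))
  expect_warning(cu2 <- density_curve(missense_at(c(50L, 500L)), 150L),
                 "outside")
  expect_equal(cu2$n_variants, 1L)
})

test_that("edge correction flattens a uniform unit density across the whole protein", {
  cu <- density_curve(missense_at(1:200), 200L)
  expect_lt(max(cu$values) - min(cu$values), 1e-10)
})

test_that("optimized curve equals the direct summation oracle on random instances", {
  set.seed(1234)
  for (rep in 1:12) {
    L <- sample(40:2000, 1L)
    n <- sample(1:min(500, L), 1L)
    pos <- sort(sample(seq_len(L), n))
    w <- sample(c(11L, 31L, 51L), 1L)
    got <- density_curve(missense_at(pos), L, window = w)
    want <- oracle_density(pos, L, window = w)
    expect_lt(max(abs(got$raw - want$raw)), 1e-10)
    expect_lt(max(abs(got$values - want$corrected)), 1e-10)
  }
})

test_that("interior curve values are shift-equivariant", {
  pos <- c(200L, 205L, 240L)
  s <- 37L
  a <- density_curve(missense_at(pos), 600L)
  b <- density_curve(missense_at(pos + s), 600L)
  interior <- 100:500  # away from both termini for either placement
  expect_equal(b$values[interior + s], a$values[interior], tolerance = 1e-12)
})

test_that("masked intervals drop their variants and flag their residues", {
  cu <- density_curve(missense_at(c(100L, 180L)), 300L,
                      mask = data.frame(start = 170L, end = 205L))
  expect_equal(cu$n_variants, 1L)
  expect_true(all(cu$masked[170:205]))
  expect_false(any(cu$masked[c(1:169, 206:300)]))
  expect_equal(which.max(cu$values), 100L)
})

test_that("normalization rescales nonzero curves to max 1 and leaves zero curves alone", {
  a <- density_curve(missense_at(c(50L, 51L, 52L)), 200L)
  b <- density_curve(missense_at(150L), 200L)
  z <- density_curve(missense_at(integer(0)), 200L)
  n <- normalize_pair(a, b)
  expect_equal(max(n$clinical$values), 1)
  expect_equal(max(n$population$values), 1)
  n2 <- normalize_pair(z, b)
  expect_true(all(n2$clinical$values == 0))
  expect_equal(max(n2$population$values), 1)
  # idempotence
  n3 <- normalize_pair(n$clinical, n$population)
  expect_equal(n3$clinical$values, n$clinical$values)
  short <- density_curve(missense_at(10L), 100L)
  expect_error(normalize_pair(a, short), class = "senscan_shape_error")
})

test_that("delta is antisymmetric and self-cancelling", {
  va <- missense_at(c(50L, 60L, 61L))
  vb <- missense_at(c(150L, 151L))
  p_ab <- tolerance_profile(va, vb, 200L)
  p_ba <- tolerance_profile(vb, va, 200L)
  expect_equal(p_ab$delta, -p_ba$delta, tolerance = 1e-12)
  p_aa <- tolerance_profile(va, va, 200L)
  expect_true(all(p_aa$delta == 0))
  expect_equal(nrow(p_aa$regions), 0L)
})

test_that("a two-impulse toy yields negative delta around the clinical site and positive around the population site", {
  prof <- tolerance_profile(missense_at(50L), missense_at(150L), 200L)
  expect_true(all(prof$delta[35:65] < 0))
  expect_true(all(prof$delta[135:165] > 0))
  want <- oracle_density(50L, 200L)$corrected
  want <- want / max(want)
  expect_equal(prof$clinical_norm, want, tolerance = 1e-10)
})

test_that("sensitive regions are maximal negative runs with filled summaries", {
  # two clinical clusters separated by more than a window, empty between
  cl <- missense_at(c(98L, 100L, 102L, 298L, 300L, 302L))
  po <- missense_at(c(200L, 201L))
  prof <- tolerance_profile(cl, po, 400L)
  reg <- prof$regions
  expect_gte(nrow(reg), 2L)
  expect_true(any(reg$start <= 100L & reg$end >= 100L))
  expect_true(any(reg$start <= 300L & reg$end >= 300L))
  # maximality: delta is negative inside and non-negative at the flanks
  for (k in seq_len(nrow(reg))) {
    expect_true(all(prof$delta[reg$start[k]:reg$end[k]] < 0))
    if (reg$start[k] > 1L) expect_gte(prof$delta[reg$start[k] - 1L], 0)
    if (reg$end[k] < 400L) expect_gte(prof$delta[reg$end[k] + 1L], 0)
  }
  # per-region variant counts match a direct recount
  k100 <- which(reg$start <= 100L & reg$end >= 100L)[1]
  expect_equal(reg$n_clinical[k100],
               sum(cl$position >= reg$start[k100] &
                     cl$position <= reg$end[k100]))
  expect_equal(reg$n_population[k100], 0L)
})

test_that("min_length filters short regions and edge-confined regions are flagged low confidence", {
  delta <- rep(1, 100)
  delta[5] <- -0.1          # single-residue dip inside the edge zone
  delta[40:60] <- -0.2
  edge <- c(rep(TRUE, 15), rep(FALSE, 70), rep(TRUE, 15))
  all_reg <- call_sensitive_regions(delta, min_length = 1L,
                                    ignore_edges = TRUE, edge_flag = edge)
  expect_equal(nrow(all_reg), 2L)
  expect_true(all_reg$low_confidence[all_reg$start == 5])
  expect_false(all_reg$low_confidence[all_reg$start == 40])
  long_only <- call_sensitive_regions(delta, min_length = 5L)
  expect_equal(nrow(long_only), 1L)
  expect_equal(long_only$start, 40L)
  expect_equal(long_only$end, 60L)
})

test_that("the composite profile matches stagewise composition and labels sources correctly", {
  set.seed(99)
  cl <- missense_at(c(80L, 82L, 85L))
  po <- missense_at(sort(sample(1:400, 30)))
  prof <- tolerance_profile(cl, po, 400L, gene = "TOY")
  c1 <- density_curve(cl, 400L)
  c2 <- density_curve(po, 400L)
  n <- normalize_pair(c1, c2)
  expect_equal(prof$delta, delta_profile(n$clinical, n$population))
  expect_identical(prof$gene, "TOY")
  expect_equal(prof$curves$clinical$n_variants, 3L)
  # swapping sources exactly negates delta
  swapped <- tolerance_profile(po, cl, 400L)
  expect_equal(swapped$delta, -prof$delta, tolerance = 1e-12)
})

test_that("per-source masks apply only to the configured curve", {
  cl <- missense_at(c(100L, 180L))
  po <- missense_at(c(180L, 250L))
  mask <- data.frame(start = 165L, end = 205L, source = "population")
  prof <- tolerance_profile(cl, po, 300L, mask = mask)
  expect_equal(prof$curves$clinical$n_variants, 2L)   # clinical untouched
  expect_equal(prof$curves$population$n_variants, 1L) # 180 dropped
  expect_true(all(prof$masked[165:205]))
})
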