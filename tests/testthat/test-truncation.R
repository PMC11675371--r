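test_that("truncation sites are marked at the first codon nucleotide or the explicit hint", {
  tr <- toy_transcript()
  stop25 <- parse_hgvs_p("p.L25*")
  expect_equal(mark_truncation_site(stop25, tr), 73L)  # 3 * 24 + 1
  fs <- parse_hgvs_p("p.T271fs")
  expect_equal(mark_truncation_site(fs, tr, cds_hint = 812L), 812L)
  expect_error(mark_truncation_site(parse_hgvs_p("p.R45C"), tr),
               class = "senscan_consequence_error")
  expect_error(mark_truncation_site(parse_hgvs_p("p.Q999*"), tr),
               class = "senscan_range_error")
})

test_that("NMD prediction follows the last-exon rule for every codon of the toy transcript", {
  tr <- toy_transcript()  # coding 300/300/402, protein 333
  last_exon_first_codon <- (600L %/% 3L) + 1L  # codon 201 starts exon 3
  for (p in seq_len(tr$protein_length)) {
    v <- parse_hgvs_p(sprintf("p.W%d*", p))
    call <- classify_truncation(v, tr)
    expect_identical(call$predicted_nmd, p < last_exon_first_codon,
                     info = sprintf("codon %d", p))
    expect_identical(call$predicted_nmd, !call$is_last_exon)
  }
  # boundary: a stop at the first nucleotide of the last exon escapes NMD
  boundary <- classify_truncation(parse_hgvs_p("p.W201*"), tr)
  expect_equal(boundary$cds_position, 601L)
  expect_false(boundary$predicted_nmd)
})

test_that("single-exon transcripts never predict NMD", {
  tr1 <- generate_transcript(300L)
  for (p in c(1L, 50L, 99L)) {
    expect_false(classify_truncation(parse_hgvs_p(sprintf("p.W%d*", p)),
                                     tr1)$predicted_nmd)
  }
})

test_that("report counts equal a brute-force recount and ignore input order", {
  set.seed(11)
  tr <- toy_transcript()
  pos <- sample(seq_len(tr$protein_length), 40L)
  notations <- c(sprintf("p.W%d*", pos[1:25]), sprintf("p.T%dfs", pos[26:40]))
  po <- parse_hgvs_p(notations, gene = "TOY", source = "population")
  cl <- parse_hgvs_p("p.W10*", gene = "TOY", source = "clinical")
  rep1 <- haploinsufficiency_report(cl, po, tr)
  rep2 <- haploinsufficiency_report(cl, po[sample(nrow(po)), ], tr)
  expect_identical(rep1$population, rep2$population)
  expect_identical(rep1$tolerance_call, rep2$tolerance_call)

  dd <- dedupe_variants(po)
  nmd <- vapply(seq_len(nrow(dd)), function(k)
    classify_truncation(dd[k, , drop = FALSE], tr)$predicted_nmd, logical(1))
  expect_equal(rep1$population$total, nrow(dd))
  expect_equal(rep1$population$before_last_exon, sum(nmd))
  expect_equal(rep1$population$last_exon, sum(!nmd))
  expect_equal(rep1$population$total,
               rep1$population$before_last_exon + rep1$population$last_exon)
})

test_that("the four reconstructed NLGN datasets reproduce the published tolerance calls", {
  expected <- list(
    NLGN1 = list(call = "tolerant", po_total = 53L, cl_total = 3L),
    NLGN2 = list(call = "tolerant", po_total = 64L, cl_total = 2L),
    NLGN3 = list(call = "tolerant", po_total = 20L, cl_total = 3L),
    NLGN4X = list(call = "intolerant", po_total = 5L, cl_total = 6L))
  for (g in names(expected)) {
    fx <- nlgn_truncation_example(g)
    rep <- haploinsufficiency_report(fx$clinical, fx$population,
                                     fx$transcript)
    expect_identical(rep$tolerance_call, expected[[g]]$call, info = g)
    expect_equal(rep$population$total, expected[[g]]$po_total, info = g)
    expect_equal(rep$clinical$total, expected[[g]]$cl_total, info = g)
  }
  # the sex-linked genes surface the female-carrier bias in the rationale
  fx3 <- nlgn_truncation_example("NLGN3")
  rep3 <- haploinsufficiency_report(fx3$clinical, fx3$population,
                                    fx3$transcript)
  expect_match(rep3$rationale, "female-carrier bias")
  expect_match(rep3$rationale, "hemizygous males")
  expect_equal(rep3$population$before_last_exon, 11L)
  expect_equal(rep3$population$last_exon, 9L)
  fx1 <- nlgn_truncation_example("NLGN1")
  rep1 <- haploinsufficiency_report(fx1$clinical, fx1$population,
                                    fx1$transcript)
  expect_no_match(rep1$rationale, "female-carrier bias")
})

test_that("empty variant tables give an indeterminate call", {
  tr <- toy_transcript()
  e <- parse_hgvs_p(character(0))
  rep <- haploinsufficiency_report(e, e, tr)
  expect_identical(rep$tolerance_call, "indeterminate")
  expect_match(rep$rationale, "no truncating variants")
})
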