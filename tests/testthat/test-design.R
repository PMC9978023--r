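test_that("cut helpers satisfy the printed window, Tm and CpG constraints", {
  fix <- designable_glai_template(seed = 4)
  h <- fix$assay$helpers
  expect_true(h$end - h$start >= 18 && h$end - h$start <= 22)
  expect_true(h$Tm >= 65 && h$Tm <= 70)
  # the CpG lies within the final 5 nt of the helper's 3' end
  cpg <- fix$assay$coords$cpg
  if (h$strand == "top") {
    expect_true(cpg >= h$start && cpg + 2 <= h$start + 5)
  } else {
    expect_true(cpg >= h$end - 5 && cpg + 2 <= h$end)
  }
  # a CpG at the template edge has no helper window
  edge <- stem_template("e", paste0("CG", strrep("AT", 30)))
  expect_error(design_cut_helper(edge, 0), "no helper window|not a CpG")
})

test_that("the TFP is assembled AP-FR-blocker-CR with FR equal to P1's 5' end", {
  fix <- designable_glai_template(seed = 5)
  tfp <- fix$assay$tfp
  tpl <- fix$template
  c5 <- fix$assay$coords$c5
  fr_len <- nchar(tfp$fr$sequence)
  # FR is identical to the first bases of the digested strand
  expect_equal(tfp$fr$sequence, substr(tpl$bases, c5 + 1, c5 + fr_len))
  expect_true(fr_len >= 15 && fr_len <= 20)
  expect_true(tfp$fr$gc >= 0.50 && tfp$fr$gc <= 0.70)
  expect_equal(tfp$blocker_nt_equiv, 6L)
  # segment order 5'->3': AP then FR then (blocker) then CR
  expect_equal(tfp$sequence,
               paste0(tfp$ap$sequence, tfp$fr$sequence, tfp$cr$sequence))
  expect_equal(tfp$spacer_position,
               nchar(tfp$ap$sequence) + nchar(tfp$fr$sequence))
  # CR is complementary to the template 3'-ward of the cut, past the FR
  expect_true(tfp$cr$start >= tfp$fr$end)
  expect_equal(tfp$cr$sequence,
               fast_revcomp_oracle(substr(tpl$bases, tfp$cr$start + 1,
                                          tfp$cr$end)))
})

test_that("FR choice honors the GC window with the documented tie-break", {
  # a template whose P1 prefix makes every FR length 50% GC: equal-dG ties
  # are impossible to force, but relax_gc behavior is observable
  tpl <- stem_template("flat", paste0(strrep("T", 30),
                                      strrep("GGGG", 25)))
  # all-G FR region violates the GC ceiling
  expect_error(design_tfp(tpl, 40), "GC window")
  relaxed <- design_tfp(tpl, 40, config = design_config(relax_gc = TRUE))
  expect_equal(nchar(relaxed$fr$sequence), 15L)  # nearest-GC, shorter wins
})

test_that("single-site designs pass their own constraint and screen suite", {
  fix <- designable_glai_template(seed = 6)
  a <- fix$assay
  oligos <- tidy(a)
  expect_setequal(unique(oligos$role),
                  c("TFP", "AP", "TSP", "probe", "cut_helper"))
  # amplicon length equals an independent coordinate recount
  tsp_end <- oligos$end[oligos$role == "TSP"]
  ap_len <- nchar(oligos$sequence[oligos$role == "AP"])
  recount <- ap_len + nchar(a$tfp$fr$sequence) +
    (tsp_end - (a$coords$c5 + a$coords$fr_len))
  expect_equal(a$expected_amplicon_len, recount)
  # design determinism: same template, site and config give the same oligos
  a2 <- design_single_site_assay(fix$template, a$coords$cpg, "GlaI")
  expect_equal(tidy(a2), oligos)
  # an unmethylatable position is rejected
  expect_error(design_single_site_assay(fix$template, 3, "GlaI"),
               "not recognizable")
})

test_that("artificial primers share no 12-mer with the template", {
  fix <- designable_glai_template(seed = 7)
  tpl <- fix$template$bases
  kmers <- function(s, k = 12) {
    n <- nchar(s); unique(substring(s, 1:(n - k + 1), k:n))
  }
  for (ap in tidy(fix$assay)$sequence[tidy(fix$assay)$role == "AP"]) {
    expect_false(any(kmers(ap) %in% kmers(tpl)))
    expect_false(any(kmers(fast_revcomp_oracle(ap)) %in% kmers(tpl)))
  }
})

test_that("PNA designs cover the variant and abut the FR boundary", {
  fix <- designable_pna_template(seed = 8)
  a <- fix$assay
  pna <- a$coords$pna
  expect_true(a$coords$variant_pos >= pna[1] &&
                a$coords$variant_pos < pna[2])
  expect_true(pna[2] - pna[1] >= 12 && pna[2] - pna[1] <= 18)
  # polymerase-proximal edge exactly at the FR 5' boundary
  expect_equal(pna[2], a$coords$c5)
  # PNA is complementary to the mutant allele, not the reference
  foot_mut <- substr(a$mutant_template$bases, pna[1] + 1, pna[2])
  foot_ref <- substr(fix$template$bases, pna[1] + 1, pna[2])
  pna_seq <- tidy(a)$sequence[tidy(a)$role == "PNA"]
  expect_equal(pna_seq, fast_revcomp_oracle(foot_mut))
  expect_false(pna_seq == fast_revcomp_oracle(foot_ref))
  # PNA does not compete with the TFP
  scr <- cross_dimer_screen(c(PNA = pna_seq, TFP = a$tfp$sequence))
  expect_false(any(scr$flagged[scr$name1 != scr$name2]))
  # variants too close to the template end are rejected
  expect_error(design_pna_assay(fix$template, 5, "A"), "12 nt")
})

test_that("co-methylation designs respect the supported P1 range and BP block", {
  fix <- designable_co_template(seed = 3)
  a <- fix$assay
  expect_true(a$p1_len <= 165)
  expect_equal(a$coords$c3 - a$coords$c5, a$p1_len)
  oligos <- tidy(a)
  expect_true(oligos$three_prime_blocked[oligos$role == "BP"])
  expect_true(all(c("BP", "TFP", "AP2", "AP3", "probe") %in% oligos$role))
  # sites too far apart exceed the supported range
  far <- synth_template(500, list(list(enzyme = "GlaI", pos = 50),
                                  list(enzyme = "LpnPI", pos = 400)),
                        seed = 12, id = "far")
  expect_error(design_comethylation_assay(far, 51, 401), "supported range")
  expect_error(
    design_comethylation_assay(fix$template, 81, 171,
                               strand_5p = "top", strand_3p = "bottom"),
    "same strand")
})

test_that("design batches satisfy every printed constraint", {
  b <- design_batch(n = 12, seed = 9)
  s <- b$summary
  expect_equal(nrow(s), 12L)
  expect_true(all(s$fr_len >= 15 & s$fr_len <= 20))
  expect_true(all(s$fr_gc >= 0.50 & s$fr_gc <= 0.70))
  expect_true(all(s$helper_tm >= 65 & s$helper_tm <= 70))
  expect_true(all(s$blocker_nt_equiv == 6L))
  # batch determinism
  b2 <- design_batch(n = 3, seed = 9)
  expect_equal(b2$summary, b$summary[1:3, ])
})
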