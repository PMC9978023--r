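test_that("TFP extension stops at the specific 5' end or runs through", {
  fix <- designable_glai_template(seed = 10)
  a <- fix$assay; tfp <- a$tfp; c5 <- a$coords$c5
  L <- nchar(fix$template$bases)
  # digested molecule: fragment starts exactly at the cut
  ext <- extend_from_tfp(frag_row("t", c5, L, end5 = "specific"), tfp)
  expect_equal(ext$stop_pos, c5)
  expect_equal(ext$stop_reason, "template_5p_end")
  fold <- self_fold_and_prime(ext)
  expect_equal(fold$overhang3, 0L)
  expect_true(fold$self_primed)
  # native molecule: extension continues past the FR boundary
  ext2 <- extend_from_tfp(frag_row("t", 0, L), tfp)
  fold2 <- self_fold_and_prime(ext2)
  expect_equal(fold2$overhang3, c5)
  expect_false(fold2$self_primed)
  # a single extra 5' base leaves a 1-nt overhang and blocks self-priming
  ext3 <- extend_from_tfp(frag_row("t", c5 - 1, L, end5 = "arbitrary"), tfp)
  expect_equal(self_fold_and_prime(ext3)$overhang3, 1L)
  expect_false(self_fold_and_prime(ext3)$self_primed)
  # an FR-internal break deletes FR bases but can still self-prime
  ext4 <- extend_from_tfp(frag_row("t", c5 + 2, L, end5 = "arbitrary"), tfp)
  fold4 <- self_fold_and_prime(ext4)
  expect_equal(fold4$fr_deleted, 2L)
  expect_true(fold4$self_primed)
  expect_true(fold4$reduced_yield)
  # no capture region on the fragment: no priming
  expect_error(extend_from_tfp(frag_row("t", 0, c5 + 2), tfp), "no priming")
})

test_that("PNA blockers gate extension on a perfect footprint match", {
  fix <- designable_pna_template(seed = 11)
  a <- fix$assay
  blockers <- list(list(start = a$coords$pna[1], end = a$coords$pna[2],
                        target = a$pna_target))
  L <- nchar(fix$template$bases)
  ext_mut <- extend_from_tfp(frag_row("m", 0, L), a$tfp,
                             blockers = blockers,
                             template = a$mutant_template)
  expect_equal(ext_mut$stop_reason, "blocker_edge")
  expect_equal(ext_mut$stop_pos, a$coords$c5)
  expect_true(self_fold_and_prime(ext_mut)$self_primed)
  # one mismatch (wild type): the PNA does not bind, extension runs through
  ext_wt <- extend_from_tfp(frag_row("w", 0, L), a$tfp,
                            blockers = blockers,
                            template = fix$template)
  expect_equal(ext_wt$stop_reason, "template_5p_end")
  expect_false(self_fold_and_prime(ext_wt)$self_primed)
})

test_that("the truncation-penalty ledger matches the reported factors", {
  f <- function(ov, fd, cm) {
    p3_yield(list(overhang3 = ov, fr_deleted = fd, cr_missing = cm))
  }
  expect_equal(f(0, 0, 0), 1.0)
  expect_equal(f(1, 0, 0), 0)       # any 3' overhang blocks
  expect_equal(f(3, 0, 0), 0)
  expect_equal(f(0, 1, 0), 1.0)     # 1-nt FR deletion: configurable, default 1
  expect_equal(f(0, 2, 0), 0.1)     # 2-3 nt FR deletion: ~10x lower
  expect_equal(f(0, 3, 0), 0.1)
  expect_equal(f(0, 4, 0), 0)
  expect_equal(f(0, 0, 1), 0.2)     # 1-nt CR loss: 5x lower
  expect_equal(f(0, 0, 2), 0)       # more CR loss: none
  expect_equal(f(0, 2, 1), 0.1 * 0.2)
  expect_error(f(-1, 0, 0), "non-negative")
})

test_that("co-methylation fragments classify into T1-T4 by their ends", {
  fix <- designable_co_template(seed = 4)
  a <- fix$assay
  c5 <- a$coords$c5; c3 <- a$coords$c3
  expect_equal(classify_scenario(
    frag_row("t", c5, c3, "specific", "specific"), a), "T4")
  expect_equal(classify_scenario(
    frag_row("t", c5, c3 - 4, "specific", "arbitrary"), a), "T2")
  expect_equal(classify_scenario(
    frag_row("t", c5 - 8, c3, "arbitrary", "specific"), a), "T3")
  expect_equal(classify_scenario(
    frag_row("t", c5 - 8, c3 + 5, "native", "native"), a), "T1")
  expect_equal(classify_scenario(
    frag_row("t", 0, c5 - 10, "native", "arbitrary"), a), "none")
})

test_that("Ct follows the closed-form amplification model", {
  expect_equal(predict_ct(1e10, E = 0.9, Nq = 1e10), 0)
  expect_equal(predict_ct(1, E = 1, Nq = 1024), 10)
  expect_true(is.na(predict_ct(0)))
  cts <- vapply(10^(1:6), predict_ct, numeric(1), E = 0.9, Nq = 1e10)
  expect_true(all(diff(cts) < 0))
  # 100 copies with E = 1 and Nq = 100 * 2^20 cross threshold at cycle 20
  expect_equal(predict_ct(100, E = 1, Nq = 100 * 2^20), 20)
})

test_that("reactions are seed-reproducible and censored correctly", {
  fix <- designable_glai_template(seed = 12)
  a <- fix$assay; tpl <- fix$template
  pool <- make_mixture(tpl, unmethylated(tpl), 100, 10000)
  proto <- protocol_params(stochastic = TRUE, seed = 31L)
  r1 <- simulate_reaction(pool, a, proto)
  r2 <- simulate_reaction(pool, a, proto)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$trace, r2$trace)
  # zero methylated copies in excess unmethylated background: censored
  r0 <- simulate_reaction(make_mixture(tpl, unmethylated(tpl), 0, 10000), a)
  expect_false(r0$amplifiable)
  expect_true(is.na(r0$Ct))
})

test_that("dilution series are linear in log10 copies", {
  fix <- designable_glai_template(seed = 13)
  a <- fix$assay
  det <- run_dilution_series(a, c(2500, 1000, 200, 50, 10), 10000, 3,
                             protocol_params(stochastic = FALSE), seed = 5)
  expect_equal(det$fit$r.squared, 1, tolerance = 1e-9)
  expect_equal(det$fit$slope, -log(10) / log(1.9), tolerance = 1e-6)
  # a 0-copy level is censored and excluded from the fit
  withzero <- run_dilution_series(a, c(1000, 100, 0), 0, 1,
                                  protocol_params(), seed = 5)
  expect_equal(withzero$fit$n_levels, 2L)
  expect_false(any(withzero$results$amplifiable[withzero$results$copies == 0]))
  # tidiers expose the replicate table and the regression
  expect_s3_class(tidy(det), "tbl_df")
  expect_named(glance(det), c("slope", "intercept", "r.squared", "n_levels"))
  p <- autoplot(det)
  expect_s3_class(p, "ggplot")
})

test_that("optional P1-length decay raises Ct with template length", {
  fix <- designable_co_template(seed = 5)
  a <- fix$assay; t <- fix$template
  pool <- fragment_pool(list(t), 500)
  base <- simulate_reaction(pool, a, protocol_params())
  decay <- simulate_reaction(pool, a, protocol_params(length_decay_rate = 0.01))
  expect_gt(decay$Ct, base$Ct)
})
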