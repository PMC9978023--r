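test_that("built-in registry carries the published motifs and spacers", {
  reg <- builtin_enzymes()
  expect_equal(reg$spacer[reg$name == "MspJI"], 9L)
  expect_equal(reg$spacer[reg$name == "FspEI"], 12L)
  expect_equal(reg$spacer[reg$name == "LpnPI"], 10L)
  expect_equal(reg$motif[reg$name == "GlaI"], "RCGY")
  expect_equal(reg$cut_mode[reg$name == "GlaI"], "intra_motif")
  # extensible, but duplicate names are rejected
  ext <- builtin_enzymes(extra = tibble::tibble(
    name = "FakeI", motif = "CCGG", methyl_required_at = list(0L),
    cut_mode = "downstream_spacer", spacer = 5L, intra_offset = NA_integer_
  ))
  expect_true("FakeI" %in% ext$name)
  expect_error(builtin_enzymes(extra = tibble::tibble(
    name = "GlaI", motif = "RCGY", methyl_required_at = list(1L),
    cut_mode = "intra_motif", spacer = NA_integer_, intra_offset = 2L
  )), "duplicate")
})

test_that("MspJI cuts 9 nt downstream of a helper-covered methylated motif", {
  # motif occupies [10, 14): cut at 14 + 9 = 23 (hand count)
  tpl <- synth_template(60, list(list(enzyme = "MspJI", pos = 10)), seed = 2,
                        id = "m")
  h <- cut_helper(fast_revcomp_oracle(substr(tpl$bases, 6, 25)), "m", 5, 25,
                  strand = "top")
  ev <- find_cut_events(tpl, "MspJI", helpers = h)
  ev <- ev[ev$strand == "top", ]
  expect_equal(ev$cut_index, 23L)
  # no mark: intact
  expect_equal(nrow(find_cut_events(unmethylated(tpl, "u"), "MspJI",
                                    helpers = cut_helper(h$oligo, "u",
                                                         5, 25, "top"))), 0L)
  # no helper for a spacer-type enzyme: intact
  expect_equal(nrow(find_cut_events(tpl, "MspJI")), 0L)
  # helper on the wrong strand does not form the cuttable duplex
  hb <- cut_helper(substr(tpl$bases, 6, 25), "m", 5, 25, strand = "bottom")
  ev2 <- find_cut_events(tpl, "MspJI", helpers = hb)
  expect_false(any(ev2$strand == "top"))
  # a helper that is not complementary to its target is rejected
  expect_error(find_cut_events(tpl, "MspJI",
                               helpers = cut_helper(strrep("A", 20), "m",
                                                    5, 25, "top")),
               "not complementary")
})

test_that("digestion splits fragments with specific ends and conserves mass", {
  tpl <- synth_template(100, list(list(enzyme = "GlaI", pos = 40)), seed = 3,
                        id = "g")
  pool <- fragment_pool(list(tpl), copies = 7L)
  ev <- find_cut_events(tpl, "GlaI")
  expect_equal(unique(ev$cut_index), 42L)
  dig <- digest_pool(pool, ev)
  expect_equal(sort(dig$end - dig$start), c(42L, 58L))
  junction5 <- dig[dig$start == 42L, ]
  expect_equal(junction5$end5_type, "specific")
  expect_equal(junction5$end3_type, "native")
  # copies x bases conserved
  expect_equal(sum(dig$copies * (dig$end - dig$start)),
               sum(pool$copies * (pool$end - pool$start)))
  # idempotent at full efficiency
  dig2 <- digest_pool(dig, ev)
  expect_equal(as.data.frame(dig2), as.data.frame(dig))
  # empty event list: unchanged
  none <- find_cut_events(unmethylated(tpl, "g"), "GlaI")
  expect_equal(as.data.frame(digest_pool(pool, none)), as.data.frame(pool))
})

test_that("flanking GlaI + LpnPI cuts give a doubly specific middle fragment", {
  tpl <- designable_co_template(seed = 2)
  assay <- tpl$assay; t <- tpl$template
  h <- assay$helpers; h$seq_id <- t$id
  ev <- dplyr::bind_rows(find_cut_events(t, "GlaI"),
                         find_cut_events(t, "LpnPI", helpers = h))
  dig <- digest_pool(fragment_pool(list(t), 5L), ev)
  mid <- dig[dig$start == assay$coords$c5 & dig$end == assay$coords$c3, ]
  expect_equal(nrow(mid), 1L)
  expect_equal(mid$end5_type, "specific")
  expect_equal(mid$end3_type, "specific")
})

test_that("unmethylated pools have no specific ends for any registry enzyme", {
  tpl <- synth_template(150, list(), seed = 17, id = "u")
  pool <- fragment_pool(list(tpl), 3L)
  for (enz in builtin_enzymes()$name) {
    ev <- find_cut_events(tpl, enz)
    dig <- digest_pool(pool, ev)
    expect_false(any(dig$end5_type == "specific" |
                       dig$end3_type == "specific"))
  }
})

test_that("partial digestion distributes copies without losing molecules", {
  tpl <- synth_template(100, list(list(enzyme = "GlaI", pos = 40)), seed = 3,
                        id = "g")
  pool <- fragment_pool(list(tpl), copies = 400L)
  ev <- find_cut_events(tpl, "GlaI")
  dig <- digest_pool(pool, ev, digestion_efficiency = 0.5, seed = 99)
  expect_equal(sum(dig$copies * (dig$end - dig$start)),
               sum(pool$copies * (pool$end - pool$start)))
  uncut <- dig[dig$start == 0L & dig$end == 100L, ]
  expect_gt(nrow(uncut), 0)
  expect_gt(uncut$copies, 100)  # about half stay intact
  expect_lt(uncut$copies, 300)
})
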