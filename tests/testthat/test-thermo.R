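test_that("duplex Tm reproduces an independent nearest-neighbor calculator", {
  # reference values computed once with a published NN implementation
  # (unified 1998 parameters, entropy salt correction, CT/4 = 50 nM)
  frozen <- c(
    AGCTGACCTGAAGCTGATCG = 55.9452,
    CGCGGCTAGCCGCGTCGGCCAT = 70.1401,
    ACGTACGT = 16.4259,
    AAAAAAATTTTTTT = 25.3158,
    GGCGCCGGCGCC = 58.5371
  )
  cond <- thermo_conditions()
  for (s in names(frozen)) {
    expect_equal(duplex_thermo(s, cond)$Tm, frozen[[s]], tolerance = 1e-3)
  }
})

test_that("duplex thermodynamics obey basic physical constraints", {
  cond <- thermo_conditions()
  s20 <- "AGCTGACCTGAAGCTGATCG"
  # a 20-mer melts above its own 8-nt prefix
  expect_gt(duplex_thermo(s20, cond)$Tm,
            duplex_thermo(substr(s20, 1, 8), cond)$Tm)
  # duplex symmetry: Tm(s) == Tm(revcomp(s))
  set.seed(4)
  for (k in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = "")
    expect_equal(duplex_thermo(s, cond)$Tm,
                 duplex_thermo(revcomp(s), cond)$Tm, tolerance = 1e-9)
  }
  # more salt stabilizes
  expect_gt(duplex_thermo(s20, thermo_conditions(monovalent_mM = 150))$Tm,
            duplex_thermo(s20, thermo_conditions(monovalent_mM = 50))$Tm)
  # dG37 consistency with dH and dS
  d <- duplex_thermo(s20, cond)
  expect_equal(d$dG37, d$dH - 310.15 * d$dS / 1000, tolerance = 1e-6)
  expect_error(duplex_thermo("ACGT"), "at least 6")
  # length monotonicity on homogeneous-composition oligos
  tms <- vapply(c(8, 12, 16, 20), function(n) {
    duplex_thermo(strrep("GC", n / 2), cond)$Tm
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("PNA duplexes are stabilized relative to the DNA analog", {
  s <- "ACCTGAAGCTGATCGAT"
  expect_gt(pna_duplex_thermo(s)$Tm, duplex_thermo(s)$Tm)
})

test_that("hairpin stability grows with stem length and shrinks with loop", {
  cond <- thermo_conditions()
  set.seed(21)
  for (k in 1:5) {
    stem20 <- paste(sample(c("A", "C", "G", "T"), 20, TRUE,
                           prob = c(.2, .3, .3, .2)), collapse = "")
    tms <- vapply(c(8, 11, 14, 17, 20), function(L) {
      hairpin_thermo(substr(stem20, 1, L), loop_len = 40, cond)$Tm
    }, numeric(1))
    expect_true(all(diff(tms) > 0))
    # larger loop destabilizes at fixed stem
    expect_lt(hairpin_thermo(stem20, 40, cond)$dG,
              hairpin_thermo(stem20, 80, cond)$dG)
  }
  expect_error(hairpin_thermo("GC", 40), "at least 3")
  expect_error(hairpin_thermo("GCGCGC", 2), "sterically")
})

test_that("fold/hybridization competition conserves mass and is monotone", {
  base <- function(ap) {
    competition_fractions(-8, -12, ap, 1e-9, temperature = 65)
  }
  # no AP, no heteroduplex
  expect_equal(base(0)$f_heteroduplex, 0)
  # fractions sum to 1 over randomized valid inputs
  set.seed(9)
  for (k in 1:20) {
    f <- competition_fractions(runif(1, -15, -2), runif(1, -18, -5),
                               10^runif(1, -9, -5), 10^runif(1, -12, -7),
                               temperature = runif(1, 37, 75))
    expect_equal(f$f_folded + f$f_heteroduplex + f$f_unstructured, 1,
                 tolerance = 1e-9)
    expect_true(all(unlist(f) >= 0))
  }
  # folded fraction strictly decreases as AP concentration rises
  aps <- 10^seq(-9, -5, length.out = 9)
  folded <- vapply(aps, function(a) base(a)$f_folded, numeric(1))
  expect_true(all(diff(folded) < 0))
  # stronger hairpin folds more
  f1 <- competition_fractions(-6, -12, 2e-7, 1e-9, 65)$f_folded
  f2 <- competition_fractions(-10, -12, 2e-7, 1e-9, 65)$f_folded
  expect_gt(f2, f1)
  expect_error(competition_fractions(-500, -12, 2e-7, 1e-9, 65), "rescale")
})

test_that("cross-dimer screen flags true dimers and 3' complements", {
  # an oligo against its own reverse complement is a full duplex
  s <- "ACGTTGCAGGACTCAAGGTC"
  scr <- cross_dimer_screen(c(a = s, b = revcomp(s)))
  expect_true(scr$flagged[scr$name1 == "a" & scr$name2 == "b"])
  # poly-A cannot pair with itself
  scr2 <- cross_dimer_screen(c(a = strrep("A", 20)))
  expect_false(any(scr2$flagged))
  expect_equal(scr2$dG, 0)
  # exactly a 5-bp mutual 3'-terminal complement triggers the 3' rule;
  # brute-force check of the tail pairing backs the expectation
  a <- "TTATAGATCCTAGACGGTCAC"   # 3' tail GGTCAC
  b <- "TATTCATACTATTAGTGACC"    # 3' tail GTGACC = revcomp(GGTCAC)
  # oracle: in a k-bp mutual 3' dimer, a[na - s] pairs b[nb - k + 1 + s]
  tail_ok <- function(a, b, k) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    na <- length(av); nb <- length(bv)
    all(vapply(0:(k - 1), function(s) {
      av[na - s] == comp[[bv[nb - k + 1 + s]]]
    }, logical(1)))
  }
  expect_true(tail_ok(a, b, 6))
  expect_false(tail_ok(a, b, 7))
  scr3 <- cross_dimer_screen(c(a = a, b = b))
  row <- scr3[scr3$name1 == "a" & scr3$name2 == "b", ]
  expect_equal(row$three_prime_run, 6L)
  expect_true(row$flagged)
})
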