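# Nearest-neighbor duplex and hairpin thermodynamics.
#
# Parameter set: the unified nearest-neighbor table (SantaLucia 1998) with a
# logarithmic monovalent-salt correction applied to the entropy,
# dS' = dS + 0.368 (n - 1) ln[Na+], and a two-state bimolecular Tm at
# effective strand concentration CT/4 (non-self-complementary duplex, equal
# strands). The table ships as a versioned CSV under inst/extdata.

.thermo_cache <- new.env(parent = emptyenv())

nn_table <- function() {
  if (is.null(.thermo_cache$nn)) {
    path <- system.file("extdata", "nn_santalucia1998.csv", package = "stempcr")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .thermo_cache$nn <- setNames(
      lapply(seq_len(nrow(tab)), function(i) c(tab$dH_kcal[i], tab$dS_cal[i])),
      tab$term
    )
  }
  .thermo_cache$nn
}

loop_table <- function() {
  if (is.null(.thermo_cache$loop)) {
    path <- system.file("extdata", "hairpin_loop_dG37.csv", package = "stempcr")
    .thermo_cache$loop <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .thermo_cache$loop
}

#' Reaction conditions for thermodynamic calculations
#'
#' Defaults follow the reaction setup the designer targets: 50 mM monovalent
#' cation and 0.2 uM oligonucleotide (the TSP/AP concentration of a standard
#' run), with a 65 degC annealing reference temperature.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param monovalent_mM Monovalent cation concentration in mM.
#' @param oligo_conc Total oligo concentration in mol/L.
#' @return A `stem_conditions` list.
#' @export
thermo_conditions <- function(temperature = 65, monovalent_mM = 50,
                              oligo_conc = 2e-7) {
  stopifnot(temperature > -273.15, monovalent_mM > 0, oligo_conc > 0)
  structure(
    list(temperature = temperature, monovalent_mM = monovalent_mM,
         oligo_conc = oligo_conc),
    class = "stem_conditions"
  )
}

nn_vectors <- function() {
  if (is.null(.thermo_cache$nnv)) {
    nn <- nn_table()
    .thermo_cache$nnv <- list(
      dH = vapply(nn, `[`, numeric(1), 1L),
      dS = vapply(nn, `[`, numeric(1), 2L)
    )
  }
  .thermo_cache$nnv
}

# Sum of stacking terms over a sequence; returns c(dH kcal, dS cal).
nn_stack_sum <- function(seq_text) {
  n <- nchar(seq_text)
  steps <- substring(seq_text, 1:(n - 1L), 2:n)
  nnv <- nn_vectors()
  c(sum(nnv$dH[steps]), sum(nnv$dS[steps]))
}

nn_init <- function(seq_text) {
  nn <- nn_table()
  ends <- c(substr(seq_text, 1L, 1L), substr(seq_text, nchar(seq_text),
                                             nchar(seq_text)))
  dH <- 0; dS <- 0
  for (b in ends) {
    p <- if (b %in% c("G", "C")) nn[["init_GC"]] else nn[["init_AT"]]
    dH <- dH + p[1]; dS <- dS + p[2]
  }
  c(dH, dS)
}

salt_dS <- function(n_bases, monovalent_mM) {
  0.368 * (n_bases - 1L) * log(monovalent_mM / 1000)
}

#' Nearest-neighbor thermodynamics of an oligo against its perfect complement
#'
#' @param oligo A/C/G/T string, length >= 6.
#' @param conditions A [thermo_conditions] object.
#' @param pna_dG_per_bp Uniform stabilization (kcal/mol per base pair, applied
#'   to the enthalpy) for PNA:DNA duplexes; 0 for plain DNA. PNA binds its DNA
#'   complement more tightly than the DNA analog, modeled as a constant
#'   per-pair offset on the same nearest-neighbor table.
#' @return A one-row tibble: `dH` (kcal/mol), `dS` (cal/(mol K), salt
#'   corrected), `dG37` (kcal/mol) and `Tm` (degC) at the stated oligo
#'   concentration.
#' @examples
#' duplex_thermo("AGCTGACCTGAAGCTGATCG", thermo_conditions())
#' @export
duplex_thermo <- function(oligo, conditions = thermo_conditions(),
                          pna_dG_per_bp = 0) {
  v <- duplex_vals(oligo, conditions, pna_dG_per_bp)
  tibble::tibble(
    oligo = toupper(oligo), n = v$n,
    dH = v$dH, dS = v$dS, dG37 = v$dG37, Tm = v$Tm
  )
}

# scalar core of duplex_thermo (no tibble), used by the design search loops
duplex_vals <- function(oligo, conditions, pna_dG_per_bp = 0) {
  oligo <- toupper(oligo)
  if (nchar(oligo) < 6L) {
    stop("duplex_thermo() needs an oligo of at least 6 nt", call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", oligo)) {
    stop("oligo may only contain A, C, G, T", call. = FALSE)
  }
  n <- nchar(oligo)
  st <- nn_stack_sum(oligo) + nn_init(oligo)
  dH <- st[1] + pna_dG_per_bp * n
  dS <- st[2] + salt_dS(n, conditions$monovalent_mM)
  ct <- conditions$oligo_conc / 4
  list(n = n, dH = dH, dS = dS,
       dG37 = dH - .T37 * dS / 1000,
       Tm = dH * 1000 / (dS + .RGAS * log(ct)) - 273.15)
}

nn_tm <- function(oligo, conditions) duplex_vals(oligo, conditions)$Tm

#' PNA:DNA duplex thermodynamics
#'
#' Convenience wrapper around [duplex_thermo()] with the default PNA
#' stabilization of -0.35 kcal/mol per base pair.
#'
#' @inheritParams duplex_thermo
#' @export
pna_duplex_thermo <- function(oligo, conditions = thermo_conditions(),
                              pna_dG_per_bp = -0.35) {
  duplex_thermo(oligo, conditions, pna_dG_per_bp = pna_dG_per_bp)
}

hairpin_loop_dG37 <- function(loop_len) {
  tab <- loop_table()
  if (loop_len < 3L) stop("loop_len < 3 is sterically impossible", call. = FALSE)
  if (loop_len <= max(tab$loop_len)) {
    stats::approx(tab$loop_len, tab$dG37_kcal, xout = loop_len)$y
  } else {
    # Jacobson-Stockmayer extrapolation beyond the tabulated sizes
    mx <- max(tab$loop_len)
    tab$dG37_kcal[tab$loop_len == mx] +
      1.75 * .RGAS / 1000 * .T37 * log(loop_len / mx)
  }
}

#' Two-state hairpin (stem-loop) thermodynamics
#'
#' Unimolecular fold: the stem contributes nearest-neighbor stacking terms
#' (salt corrected) and the loop a length-dependent entropic penalty taken
#' from a tabulated hairpin-loop dG37, assigned entirely to the entropy.
#'
#' @param stem_seq Stem sequence (one strand of the stem), length >= 3.
#' @param loop_len Loop length in nt, >= 3.
#' @param conditions A [thermo_conditions] object.
#' @return One-row tibble: `stem_len`, `loop_len`, `dH`, `dS`, `dG`
#'   (kcal/mol at 37 degC) and `Tm` (degC).
#' @examples
#' hairpin_thermo("GCGCGCGCGC", loop_len = 40)
#' @export
hairpin_thermo <- function(stem_seq, loop_len, conditions = thermo_conditions()) {
  v <- hairpin_vals(stem_seq, loop_len, conditions)
  tibble::tibble(
    stem_len = v$stem_len, loop_len = as.integer(loop_len),
    dH = v$dH, dS = v$dS, dG = v$dG, Tm = v$Tm
  )
}

hairpin_vals <- function(stem_seq, loop_len, conditions) {
  stem_seq <- toupper(stem_seq)
  if (nchar(stem_seq) < 3L) {
    stop("hairpin stem must be at least 3 nt", call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", stem_seq)) {
    stop("stem_seq may only contain A, C, G, T", call. = FALSE)
  }
  if (loop_len < 3L) stop("loop_len < 3 is sterically impossible", call. = FALSE)
  n <- nchar(stem_seq)
  st <- nn_stack_sum(stem_seq)
  dH <- st[1]
  dS <- st[2] + salt_dS(n, conditions$monovalent_mM) -
    hairpin_loop_dG37(loop_len) * 1000 / .T37
  list(stem_len = n, dH = dH, dS = dS,
       dG = dH - .T37 * dS / 1000,
       Tm = dH * 1000 / dS - 273.15)
}

#' Competition between hairpin self-folding and hetero-hybridization with AP
#'
#' The self-primed product P3 can either fold on itself (unimolecular, free
#' energy `hairpin_dG`) or hybridize with the artificial primer AP
#' (bimolecular, `ap_duplex_dG`). The coupled mass-action equilibrium with
#' conservation of the strand and AP totals is solved in closed form
#' (quadratic in the bound-AP variable).
#'
#' @param hairpin_dG Hairpin folding free energy (kcal/mol) at `temperature`.
#' @param ap_duplex_dG AP:strand duplex free energy (kcal/mol) at
#'   `temperature`.
#' @param ap_total_conc Total AP concentration (mol/L), >= 0.
#' @param strand_total_conc Total strand concentration (mol/L), > 0.
#' @param temperature Temperature in degC.
#' @return One-row tibble `f_folded`, `f_heteroduplex`, `f_unstructured`
#'   (fractions of the strand total; they sum to 1).
#' @examples
#' competition_fractions(-8, -12, 2e-7, 1e-9, 65)
#' @export
competition_fractions <- function(hairpin_dG, ap_duplex_dG, ap_total_conc,
                                  strand_total_conc, temperature = 65) {
  stopifnot(ap_total_conc >= 0, strand_total_conc > 0)
  TK <- temperature + 273.15
  ef <- -hairpin_dG * 1000 / (.RGAS * TK)
  ed <- -ap_duplex_dG * 1000 / (.RGAS * TK)
  if (max(abs(ef), abs(ed)) > 500) {
    stop("free energies produce overflow in exp(); rescale dG inputs",
         call. = FALSE)
  }
  Kf <- exp(ef)          # unimolecular fold
  Ka <- exp(ed)          # bimolecular association, 1/M
  S <- strand_total_conc
  A <- ap_total_conc
  # D = Ka U [AP]; with B = Ka U: a B^2 + b B - S = 0, a = (1 + Kf)/Ka
  a <- (1 + Kf) / Ka
  if (!is.finite(a)) {
    stop("free energies produce overflow; rescale dG inputs", call. = FALSE)
  }
  b <- a + A - S
  disc <- sqrt(b^2 + 4 * a * S)
  B <- if (b >= 0) 2 * S / (b + disc) else (-b + disc) / (2 * a)
  U <- B / Ka
  D <- B * A / (1 + B)
  f_het <- D / S
  f_unstr <- U / S
  f_fold <- Kf * U / S
  tibble::tibble(
    f_folded = f_fold, f_heteroduplex = f_het, f_unstructured = f_unstr
  )
}

# Best ungapped antiparallel pairing between two oligos. The interaction
# free energy is that of the single most stable contiguous complementary
# run over all offsets (an ungapped duplex seed); the 3'-end check looks
# for mutual 3'-terminal complementarity (both 3' ends inside one run), the
# geometry a polymerase can extend into a primer dimer.
dimer_align <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]
  rcb <- fast_revcomp(b)
  zv <- strsplit(rcb, "")[[1]]  # match a[i] == z[i - o]
  # stacking dG37 of a's dinucleotide starting at i
  nnv <- nn_vectors()
  steps <- paste0(av[-na], av[-1L])
  stack_dg <- nnv$dH[steps] - .T37 * nnv$dS[steps] / 1000
  best <- 0
  for (o in seq(-(nb - 1L), na - 1L)) {
    i_lo <- max(1L, o + 1L); i_hi <- min(na, o + nb)
    if (i_hi - i_lo < 1L) next
    idx <- i_lo:i_hi
    m <- av[idx] == zv[idx - o]
    if (sum(m) < 2L) next
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      pos <- idx[starts[k]:ends[k]]
      dg <- sum(stack_dg[pos[-length(pos)]])
      if (dg < best) best <- dg
    }
  }
  # mutual 3'-terminal complementarity of k base pairs:
  # tail_k(a) == revcomp(tail_k(b)), i.e. a suffix of a equals a prefix of
  # revcomp(b); not nested in k, so all k are tried
  run3 <- 0L
  for (k in seq_len(min(na, nb))) {
    if (substr(a, na - k + 1L, na) == substr(rcb, 1L, k)) run3 <- k
  }
  list(dG = best, three_prime_run = run3)
}

#' Screen oligo pairs for cross-dimers and 3'-end complementarity
#'
#' Evaluates all unordered pairs (including self-pairs) by exhaustive
#' ungapped antiparallel alignment scored with nearest-neighbor stacking at
#' 37 degC. A pair is flagged when its most stable contiguous complementary
#' run falls below `dG_threshold`, or when the two 3' termini are mutually
#' complementary over at least `three_prime_min` base pairs (the geometry a
#' polymerase extends into a primer dimer).
#'
#' @param oligos Named character vector of sequences, or a data frame with
#'   `name` and `sequence` columns.
#' @param dG_threshold Flagging threshold in kcal/mol (default -12, about
#'   an 8-bp GC-clamped duplex seed).
#' @param three_prime_min Minimum 3'-anchored complementary run to flag
#'   (default 4).
#' @return Tibble with one row per pair: `name1`, `name2`, `dG`,
#'   `three_prime_run`, `flagged`.
#' @examples
#' cross_dimer_screen(c(a = "ACGTACGTACGT", b = "AAAAAAAAAA"))
#' @export
cross_dimer_screen <- function(oligos, dG_threshold = -12,
                               three_prime_min = 4L) {
  if (is.data.frame(oligos)) {
    oligos <- setNames(oligos$sequence, oligos$name)
  }
  if (is.null(names(oligos))) {
    names(oligos) <- paste0("oligo", seq_along(oligos))
  }
  stopifnot(length(oligos) >= 1L)
  nm <- names(oligos)
  n1 <- character(); n2 <- character(); dg <- numeric(); r3 <- integer()
  for (i in seq_along(oligos)) {
    for (j in i:length(oligos)) {
      al <- dimer_align(toupper(oligos[[i]]), toupper(oligos[[j]]))
      n1 <- c(n1, nm[i]); n2 <- c(n2, nm[j])
      dg <- c(dg, al$dG); r3 <- c(r3, al$three_prime_run)
    }
  }
  tibble::tibble(
    name1 = n1, name2 = n2, dG = dg, three_prime_run = r3,
    flagged = dg <= dG_threshold | r3 >= three_prime_min
  )
}
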