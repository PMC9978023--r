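# Assay design: cut helpers, tailored foldable primers (TFP) and the full
# oligo sets of the three STEM-PCR modes. All printed constraints are
# enforced here: FR 15-20 nt at 50-70% GC, helper ~20 bp with Tm 65-70 C,
# a 6 nt-equivalent PEG18 extension blocker, and a cross-dimer screen over
# every emitted oligo.

# Shipped artificial primer (AP) library: 22-mers with balanced GC,
# screened for self-structure and mutual dimers when the set was built.
.stem_ap_seqs <- c(
  "TTGAATACACCGCCCAGATCAG",
  "ACAAAGAAGATCCTCGGCACCA",
  "ATCCTCCCACGATGAGCCGATG",
  "GAAGCTTACGTAGCGGCATACA",
  "TGCGGATGGACGAGTAGCAACC",
  "ACGAGGGTAATTACGCGGACTA",
  "TACCTCGCTTCCGTACACACCT",
  "GCGTTGATGTGTTATCAGCCCG",
  "CCGACGTATCGATCACTAGAGT",
  "AGGACACGACCCTTAGGCTACA"
)

#' Shipped artificial primer library
#'
#' Template-independent 22-mers used as AP/AP1/AP2/AP3 tags. At design time
#' each candidate is additionally checked for shared k-mers (k >= 12)
#' against the template before use.
#'
#' @return Named character vector of sequences.
#' @export
stem_ap_library <- function() {
  setNames(.stem_ap_seqs, paste0("AP_lib_", seq_along(.stem_ap_seqs)))
}

#' Default design configuration
#'
#' @param ... Overrides for individual keys.
#' @return Named list with keys `fr_len_range`, `fr_gc_range`,
#'   `helper_tm_range`, `helper_len_range`, `max_p1_len`,
#'   `dimer_dG_threshold`, `cr_tm_target`, `tsp_tm_target`,
#'   `probe_tm_target`, `tm_tol`, `blocker_nt_equiv`, `min_cr_gap`,
#'   `pna_len_range`, `relax_gc`, `loop_ref`.
#' @export
design_config <- function(...) {
  cfg <- list(
    fr_len_range = c(15L, 20L),
    fr_gc_range = c(0.50, 0.70),
    helper_tm_range = c(65, 70),
    helper_len_range = c(18L, 22L),
    max_p1_len = 165L,
    dimer_dG_threshold = -12,
    cr_tm_target = 66, tsp_tm_target = 65, probe_tm_target = 73,
    tm_tol = 2,
    blocker_nt_equiv = 6L,
    min_cr_gap = 5L,
    pna_len_range = c(12L, 18L),
    relax_gc = FALSE,
    loop_ref = 40L
  )
  utils::modifyList(cfg, list(...))
}

# any shared k-mer between a and b (either orientation of a)?
has_kmer_match <- function(a, b, k = 12L) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  kmers <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  any(kmers(a) %in% kmers(b)) || any(kmers(fast_revcomp(a)) %in% kmers(b))
}

pick_ap <- function(template, used = character(),
                    library = stem_ap_library()) {
  for (nm in names(library)) {
    s <- library[[nm]]
    if (s %in% used) next
    if (!has_kmer_match(s, template$bases, 12L)) {
      return(list(name = nm, sequence = s))
    }
  }
  stop("no artificial primer in the library is orthogonal to the template",
       call. = FALSE)
}

# Pick the oligo window of target Tm from candidate lengths, anchored at a
# fixed template edge. side = "left" anchors `start`, "right" anchors `end`.
pick_window_by_tm <- function(template, anchor, side, lengths, tm_target,
                              conditions, sense = c("revcomp", "top")) {
  sense <- match.arg(sense)
  L <- nchar(template$bases)
  best <- NULL
  for (len in lengths) {
    if (side == "left") {
      start <- anchor; end <- anchor + len
    } else {
      start <- anchor - len; end <- anchor
    }
    if (start < 0 || end > L) next
    win <- subseq_top(template, start, end)
    if (grepl("N", win)) next
    seqn <- if (sense == "revcomp") fast_revcomp(win) else win
    tm <- nn_tm(seqn, conditions)
    d <- abs(tm - tm_target)
    if (is.null(best) || d < best$d) {
      best <- list(sequence = seqn, start = start, end = end, Tm = tm, d = d)
    }
  }
  if (is.null(best)) {
    stop("no oligo window available at the requested position", call. = FALSE)
  }
  best
}

#' Design a cut helper for a target CpG site
#'
#' Searches helper windows of 18-22 nt (preferring 20) on both strands,
#' keeping candidates whose nearest-neighbor duplex Tm falls in the 65-70 C
#' window and whose 3' end places the CpG within its final 5 nt. Either
#' strand may be used; when both strands admit a helper, the one with fewer
#' self-structure flags wins (ties go to the top strand).
#'
#' @param template A [stem_template].
#' @param cpg_site 0-based position of the CpG cytosine (top strand).
#' @param conditions A [thermo_conditions] object.
#' @param config A [design_config()] list.
#' @param motif_interval Optional `c(start, end)` that the helper must
#'   additionally cover (the enzyme recognition motif).
#' @param strand Allowed strand(s) of hybridization. The helper directs the
#'   enzyme to the strand it binds, so assay designers that build P1 on the
#'   top strand restrict this to `"top"`.
#' @return One-row [cut_helper()] tibble with an added `Tm` column.
#' @export
design_cut_helper <- function(template, cpg_site,
                              conditions = thermo_conditions(),
                              config = design_config(),
                              motif_interval = NULL,
                              strand = c("top", "bottom")) {
  strand_opts <- match.arg(strand, several.ok = TRUE)
  L <- nchar(template$bases)
  if (substr(template$bases, cpg_site + 1L, cpg_site + 2L) != "CG") {
    stop(sprintf("position %d is not a CpG cytosine", cpg_site), call. = FALSE)
  }
  lens <- config$helper_len_range[1]:config$helper_len_range[2]
  lens <- lens[order(abs(lens - 20L))]
  tmr <- config$helper_tm_range
  best_by_strand <- list()
  for (strand in strand_opts) {
    for (len in lens) {
      # helper 3' end must place the CpG within its final 5 nt
      hs_opts <- if (strand == "top") {
        max(0L, cpg_site - 3L):cpg_site
      } else {
        (max(len, cpg_site + 2L):min(L, cpg_site + 5L)) - len
      }
      hs_opts <- hs_opts[hs_opts >= 0L & hs_opts + len <= L]
      for (hs in hs_opts) {
        he <- hs + len
        if (!is.null(motif_interval) &&
            !(hs <= motif_interval[1] && he >= motif_interval[2])) next
        win <- subseq_top(template, hs, he)
        if (grepl("N", win)) next
        oligo <- if (strand == "top") fast_revcomp(win) else win
        tm <- nn_tm(oligo, conditions)
        if (tm < tmr[1] || tm > tmr[2]) next
        cand <- cut_helper(oligo, template$id, hs, he, strand)
        cand$Tm <- tm
        sc <- cross_dimer_screen(setNames(oligo, "h"),
                                 dG_threshold = config$dimer_dG_threshold)
        cand$self_flags <- sum(sc$flagged)
        if (is.null(best_by_strand[[strand]]) ||
            cand$self_flags < best_by_strand[[strand]]$self_flags) {
          best_by_strand[[strand]] <- cand
        }
      }
      if (!is.null(best_by_strand[[strand]])) break  # prefer length near 20
    }
  }
  if (length(best_by_strand) == 0) {
    stop(paste0(
      "no helper window of 18-22 nt reaches a Tm of 65-70 C at this site; ",
      "consider different conditions or another site"), call. = FALSE)
  }
  flags <- vapply(best_by_strand, function(x) x$self_flags, numeric(1))
  pick <- best_by_strand[[names(best_by_strand)[which.min(flags)]]]
  pick$self_flags <- NULL
  pick
}

#' Design the tailored foldable primer (TFP)
#'
#' The TFP is assembled 5'->3' as AP - FR - blocker - CR: an artificial
#' primer tag, the folding region (identical to the first bases of the
#' digested strand P1), a PEG18 extension blocker recorded as 6
#' nt-equivalent, and a capture region complementary to the template
#' 3'-ward of the cut. Among FR lengths 15-20 nt whose GC content lies in
#' 50-70%, the one with the most stable hairpin stem (nearest-neighbor dG
#' at the reference loop size) is chosen, ties broken by the shorter
#' length.
#'
#' @param template A [stem_template].
#' @param fr_boundary Inter-base coordinate of the specific 5' end of P1
#'   (a cut index or PNA stop).
#' @param ap_library Artificial primer library (see [stem_ap_library()]).
#' @param conditions A [thermo_conditions] object.
#' @param config A [design_config()] list; `relax_gc = TRUE` falls back to
#'   the FR length closest to the GC window when none satisfies it.
#' @param cr_offset Gap in nt between the FR 3' boundary and the CR
#'   template window (>= `min_cr_gap`; the single-site designer widens it
#'   to fit the probe and TSP).
#' @param used_aps Library sequences already taken by other oligos.
#' @return A `stem_tfp` list: `ap`, `fr`, `cr` components (sequence and
#'   coordinates), `blocker_nt_equiv`, `spacer_position`, and the
#'   assembled `sequence` (without the non-nucleotide blocker).
#' @export
design_tfp <- function(template, fr_boundary,
                       ap_library = stem_ap_library(),
                       conditions = thermo_conditions(),
                       config = design_config(),
                       cr_offset = NULL, used_aps = character()) {
  L <- nchar(template$bases)
  c5 <- as.integer(fr_boundary)
  stopifnot(c5 >= 0, c5 < L)
  lens <- config$fr_len_range[1]:config$fr_len_range[2]
  cand <- purrr::map_dfr(lens, function(len) {
    if (c5 + len > L) return(NULL)
    fr_seq <- subseq_top(template, c5, c5 + len)
    if (grepl("N", fr_seq)) return(NULL)
    tibble::tibble(
      len = len, sequence = fr_seq, gc = gc_fraction(fr_seq),
      dG = hairpin_vals(fr_seq, config$loop_ref, conditions)$dG
    )
  })
  if (nrow(cand) == 0) stop("no FR window fits the template", call. = FALSE)
  ok <- cand$gc >= config$fr_gc_range[1] & cand$gc <= config$fr_gc_range[2]
  if (!any(ok)) {
    if (!isTRUE(config$relax_gc)) {
      stop(paste0("no FR length in 15-20 nt meets the 50-70% GC window ",
                  "(set relax_gc to accept the nearest)"), call. = FALSE)
    }
    gdist <- pmax(config$fr_gc_range[1] - cand$gc,
                  cand$gc - config$fr_gc_range[2], 0)
    sel <- cand[order(gdist, cand$len), ][1, ]
  } else {
    sel <- cand[ok, ]
    sel <- sel[order(sel$dG, sel$len), ][1, ]
  }
  fr <- list(sequence = sel$sequence, start = c5, end = c5 + sel$len,
             gc = sel$gc, dG = sel$dG)
  cr_offset <- as.integer(cr_offset %||% config$min_cr_gap)
  if (cr_offset < config$min_cr_gap) {
    stop(sprintf("cr_offset below the minimum FR-CR gap of %d nt",
                 config$min_cr_gap), call. = FALSE)
  }
  cr <- pick_window_by_tm(
    template, anchor = fr$end + cr_offset, side = "left",
    lengths = 16:28, tm_target = config$cr_tm_target,
    conditions = conditions, sense = "revcomp"
  )
  ap <- pick_ap(template, used = used_aps, library = ap_library)
  structure(
    list(
      ap = ap, fr = fr,
      blocker_nt_equiv = as.integer(config$blocker_nt_equiv),
      cr = cr[c("sequence", "start", "end", "Tm")],
      spacer_position = nchar(ap$sequence) + nchar(fr$sequence),
      sequence = paste0(ap$sequence, fr$sequence, cr$sequence),
      fr_boundary = c5
    ),
    class = "stem_tfp"
  )
}

#' @export
print.stem_tfp <- function(x, ...) {
  cat(sprintf(
    "<stem_tfp> AP(%d nt) - FR(%d nt, GC %.0f%%) - PEG18(%d nt-equiv) - CR(%d nt, Tm %.1f)\n",
    nchar(x$ap$sequence), nchar(x$fr$sequence), 100 * x$fr$gc,
    x$blocker_nt_equiv, nchar(x$cr$sequence), x$cr$Tm))
  invisible(x)
}

oligo_row <- function(name, role, sequence, tm = NA_real_,
                      start = NA_integer_, end = NA_integer_,
                      three_prime_blocked = FALSE, is_pna = FALSE,
                      spacer_positions = integer(),
                      stage = "amplification") {
  tibble::tibble(
    name = name, role = role, sequence = sequence,
    Tm = tm, gc = vapply(sequence, gc_fraction, numeric(1)),
    start = as.integer(start), end = as.integer(end),
    three_prime_blocked = three_prime_blocked, is_pna = is_pna,
    spacer_positions = list(as.integer(spacer_positions)),
    stage = stage
  )
}

# oligo set used for the cross-dimer screen: the TFP is screened as its two
# nucleotide arms since the PEG18 blocker breaks stacking continuity.
screen_oligos <- function(oligos) {
  out <- character(); nm <- character()
  for (i in seq_len(nrow(oligos))) {
    o <- oligos[i, ]
    sp <- o$spacer_positions[[1]]
    if (length(sp) > 0) {
      out <- c(out, substr(o$sequence, 1L, sp),
               substr(o$sequence, sp + 1L, nchar(o$sequence)))
      nm <- c(nm, paste0(o$name, "_5arm"), paste0(o$name, "_3arm"))
    } else {
      out <- c(out, o$sequence); nm <- c(nm, o$name)
    }
  }
  setNames(out, nm)
}

# Oligos are screened within their reaction stage: cut helpers act in the
# digestion step (heat-inactivated before amplification), and in the
# co-methylation protocol the BP/TFP linear extension and the AP2s/AP3s
# exponential phase are separate reactions, so only oligos that share a
# tube are screened against each other.
assert_design_clean <- function(oligos, config) {
  scr_stage <- function(df) {
    if (nrow(df) == 0) return(NULL)
    cross_dimer_screen(screen_oligos(df),
                       dG_threshold = config$dimer_dG_threshold)
  }
  scr <- dplyr::bind_rows(lapply(split(oligos, oligos$stage), scr_stage))
  bad <- scr[scr$flagged, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop(sprintf(
      "design fails the cross-dimer screen: %s (dG %.1f kcal/mol, 3' run %d)",
      paste0(bad$name1[1], " x ", bad$name2[1]), bad$dG[1],
      bad$three_prime_run[1]), call. = FALSE)
  }
  invisible(scr)
}

new_assay <- function(mode, template, oligos, coords, tfp, helpers = NULL,
                      enzymes = character(), expected_amplicon_len = NA,
                      extra = list(), config = design_config()) {
  structure(
    c(list(mode = mode, template = template, oligos = oligos,
           coords = coords, tfp = tfp, helpers = helpers,
           enzymes = enzymes,
           expected_amplicon_len = as.integer(expected_amplicon_len),
           fr_boundary = coords$c5, config = config),
      extra),
    class = "stem_assay"
  )
}

#' @export
print.stem_assay <- function(x, ...) {
  cat(sprintf("<stem_assay> mode %s on '%s': %d oligo(s), amplicon %s bp\n",
              x$mode, x$template$id, nrow(x$oligos),
              x$expected_amplicon_len))
  invisible(x)
}

#' Design a complete single-site MDRE STEM-PCR assay
#'
#' Produces the cut helper, TFP, artificial primer, target-specific primer
#' (TSP) and hydrolysis probe for methylation detection at one CpG via a
#' methylation-dependent restriction enzyme. The expected amplicon length
#' is `|AP| + |FR| + (TSP 5' offset from the FR 3' boundary)`.
#'
#' @param template A [stem_template] (methylated at the target site).
#' @param cpg_site 0-based position of the target CpG cytosine (top
#'   strand).
#' @param enzyme_name Registry name of the MDRE (e.g. `"GlaI"`).
#' @param conditions A [thermo_conditions] object.
#' @param config A [design_config()] list.
#' @param registry Enzyme registry.
#' @return A `stem_assay` object; `tidy()` returns the oligo table.
#' @export
design_single_site_assay <- function(template, cpg_site, enzyme_name,
                                     conditions = thermo_conditions(),
                                     config = design_config(),
                                     registry = builtin_enzymes()) {
  enz <- get_enzyme(enzyme_name, registry)
  # locate the recognition site whose required cytosine is the target CpG
  sites <- iupac_scan(template, enz$motif, "top",
                      methyl_required_at = enz$methyl_required_at[[1]])
  req <- enz$methyl_required_at[[1]][1]
  site <- sites[sites$start + req == cpg_site, , drop = FALSE]
  if (nrow(site) == 0) {
    stop(sprintf(
      "CpG at %d is not recognizable by %s (motif %s with required 5mC)",
      cpg_site, enz$name, enz$motif), call. = FALSE)
  }
  site <- site[1, ]
  # the cut position is fixed by the motif alone, so FR feasibility can be
  # checked before the (costlier) helper search
  c5_prov <- if (enz$cut_mode == "intra_motif") {
    site$start + enz$intra_offset
  } else {
    site$end + enz$spacer
  }
  if (!isTRUE(config$relax_gc)) {
    lens <- config$fr_len_range[1]:config$fr_len_range[2]
    lens <- lens[c5_prov + lens <= nchar(template$bases)]
    gcs <- vapply(lens, function(len) {
      gc_fraction(subseq_top(template, c5_prov, c5_prov + len))
    }, numeric(1))
    if (!any(gcs >= config$fr_gc_range[1] & gcs <= config$fr_gc_range[2])) {
      stop(paste0("no FR length in 15-20 nt meets the 50-70% GC window ",
                  "(set relax_gc to accept the nearest)"), call. = FALSE)
    }
  }
  helper <- design_cut_helper(template, cpg_site, conditions, config,
                              motif_interval = c(site$start, site$end),
                              strand = "top")
  events <- find_cut_events(template, enz, helpers = helper,
                            registry = registry)
  ev <- events[events$start == site$start & events$strand == "top", ,
               drop = FALSE]
  if (nrow(ev) == 0) {
    stop("no cut event at the target site (cut falls outside the template?)",
         call. = FALSE)
  }
  c5 <- ev$cut_index[1]
  # provisional TFP fixes the FR; probe and TSP are placed 3'-ward of it,
  # then the CR is pushed beyond the TSP window
  tfp0 <- design_tfp(template, c5, conditions = conditions, config = config)
  fr_end <- tfp0$fr$end
  probe <- pick_window_by_tm(template, anchor = fr_end + 2L, side = "left",
                             lengths = 18:30,
                             tm_target = config$probe_tm_target,
                             conditions = conditions, sense = "top")
  tsp <- pick_window_by_tm(template, anchor = probe$end + 2L, side = "left",
                           lengths = 16:28,
                           tm_target = config$tsp_tm_target,
                           conditions = conditions, sense = "revcomp")
  tfp <- design_tfp(template, c5, conditions = conditions, config = config,
                    cr_offset = (tsp$end + config$min_cr_gap) - fr_end)
  amplicon <- nchar(tfp$ap$sequence) + nchar(tfp$fr$sequence) +
    (tsp$end - fr_end)
  oligos <- dplyr::bind_rows(
    oligo_row("TFP", "TFP", tfp$sequence,
              start = tfp$fr$start, end = tfp$cr$end,
              spacer_positions = tfp$spacer_position),
    oligo_row("AP", "AP", tfp$ap$sequence,
              tm = nn_tm(tfp$ap$sequence, conditions)),
    oligo_row("TSP", "TSP", tsp$sequence, tm = tsp$Tm,
              start = tsp$start, end = tsp$end),
    oligo_row("probe", "probe", probe$sequence, tm = probe$Tm,
              start = probe$start, end = probe$end),
    oligo_row("cut_helper", "cut_helper", helper$oligo, tm = helper$Tm,
              start = helper$start, end = helper$end, stage = "digestion")
  )
  assert_design_clean(oligos, config)
  new_assay(
    mode = "single_site_mdre", template = template, oligos = oligos,
    coords = list(c5 = c5, fr_len = nchar(tfp$fr$sequence),
                  cr = c(tfp$cr$start, tfp$cr$end),
                  tsp = c(tsp$start, tsp$end),
                  probe = c(probe$start, probe$end),
                  site = c(site$start, site$end), cpg = cpg_site),
    tfp = tfp, helpers = helper, enzymes = enz$name,
    expected_amplicon_len = amplicon, config = config
  )
}

#' Design a PNA-clamp STEM-PCR assay for a single-base variant
#'
#' A peptide nucleic acid oligo complementary to the mutant allele covers
#' the variant and abuts the FR 5' boundary, stopping TFP extension there
#' for mutant templates only; a single mismatch (the wild-type base)
#' prevents PNA binding, extension runs through, and the run-on product
#' cannot self-prime. No enzymes are involved.
#'
#' @param template Reference (wild-type) [stem_template].
#' @param variant_pos 0-based position of the substitution.
#' @param variant_base Mutant base (must differ from the reference).
#' @param conditions,config,registry As in [design_single_site_assay()].
#' @return A `stem_assay` with mode `"pna_mutation"`; carries the mutant
#'   template as `$mutant_template`.
#' @export
design_pna_assay <- function(template, variant_pos, variant_base,
                             conditions = thermo_conditions(),
                             config = design_config(),
                             registry = builtin_enzymes()) {
  L <- nchar(template$bases)
  variant_base <- toupper(variant_base)
  ref_base <- substr(template$bases, variant_pos + 1L, variant_pos + 1L)
  if (variant_base == ref_base) {
    stop("variant_base equals the reference base", call. = FALSE)
  }
  if (variant_pos < 12L || variant_pos > L - 13L) {
    stop("variant within 12 nt of the template end; no PNA window",
         call. = FALSE)
  }
  mut_bases <- template$bases
  substr(mut_bases, variant_pos + 1L, variant_pos + 1L) <- variant_base
  mutant <- stem_template(paste0(template$id, "_mut"), mut_bases,
                          marks = template$marks)
  flen <- 15L  # mid of the 12-18 window; centered on the variant
  a <- variant_pos - (flen - 1L) %/% 2L
  if (a < 0L) a <- 0L
  c5 <- a + flen
  if (c5 + config$fr_len_range[2] > L) {
    stop("variant too close to the 3' template end for an FR window",
         call. = FALSE)
  }
  pna_target <- substr(mut_bases, a + 1L, c5)
  pna_seq <- revcomp(pna_target)
  tfp0 <- design_tfp(template, c5, conditions = conditions, config = config)
  fr_end <- tfp0$fr$end
  probe <- pick_window_by_tm(template, anchor = fr_end + 2L, side = "left",
                             lengths = 18:30,
                             tm_target = config$probe_tm_target,
                             conditions = conditions, sense = "top")
  tsp <- pick_window_by_tm(template, anchor = probe$end + 2L, side = "left",
                           lengths = 16:28,
                           tm_target = config$tsp_tm_target,
                           conditions = conditions, sense = "revcomp")
  tfp <- design_tfp(template, c5, conditions = conditions, config = config,
                    cr_offset = (tsp$end + config$min_cr_gap) - fr_end)
  amplicon <- nchar(tfp$ap$sequence) + nchar(tfp$fr$sequence) +
    (tsp$end - fr_end)
  oligos <- dplyr::bind_rows(
    oligo_row("TFP", "TFP", tfp$sequence,
              start = tfp$fr$start, end = tfp$cr$end,
              spacer_positions = tfp$spacer_position),
    oligo_row("AP", "AP", tfp$ap$sequence,
              tm = nn_tm(tfp$ap$sequence, conditions)),
    oligo_row("TSP", "TSP", tsp$sequence, tm = tsp$Tm,
              start = tsp$start, end = tsp$end),
    oligo_row("probe", "probe", probe$sequence, tm = probe$Tm,
              start = probe$start, end = probe$end),
    oligo_row("PNA", "PNA", pna_seq,
              tm = pna_duplex_thermo(pna_seq, conditions)$Tm,
              start = a, end = c5, is_pna = TRUE)
  )
  assert_design_clean(oligos, config)
  new_assay(
    mode = "pna_mutation", template = template, oligos = oligos,
    coords = list(c5 = c5, fr_len = nchar(tfp$fr$sequence),
                  cr = c(tfp$cr$start, tfp$cr$end),
                  tsp = c(tsp$start, tsp$end),
                  probe = c(probe$start, probe$end),
                  pna = c(a, c5), variant_pos = variant_pos),
    tfp = tfp, expected_amplicon_len = amplicon,
    extra = list(mutant_template = mutant, variant_base = variant_base,
                 pna_target = pna_target),
    config = config
  )
}

#' Design a co-methylation STEM-PCR assay over two cut sites
#'
#' Two MDREs create the specific 5' and 3' ends of P1 (e.g. GlaI for the
#' 5' end, LpnPI for the 3' end). A 3'-blocked bridge primer
#' (5'-AP1a + CRa-3') captures P1's free 3' end and appends the artificial
#' AP1s tag; the co-mode TFP (AP2a - FR - blocker - AP1a) then builds the
#' self-priming hairpin, and the template-independent primers AP2s/AP3s
#' drive the exponential phase.
#'
#' @param template A [stem_template] methylated at both sites.
#' @param site_5p,site_3p 0-based CpG cytosine positions of the 5'- and
#'   3'-end cut sites (top strand).
#' @param enzyme_5p,enzyme_3p Registry names of the two MDREs.
#' @param conditions,config,registry As in [design_single_site_assay()].
#' @param strand_5p,strand_3p Strand of each site; both must match.
#' @return A `stem_assay` with mode `"comethylation"`.
#' @export
design_comethylation_assay <- function(template, site_5p, site_3p,
                                       enzyme_5p = "GlaI",
                                       enzyme_3p = "LpnPI",
                                       conditions = thermo_conditions(),
                                       config = design_config(),
                                       registry = builtin_enzymes(),
                                       strand_5p = "top",
                                       strand_3p = "top") {
  if (strand_5p != strand_3p) {
    stop("co-methylation sites must lie on the same strand", call. = FALSE)
  }
  enz5 <- get_enzyme(enzyme_5p, registry)
  enz3 <- get_enzyme(enzyme_3p, registry)
  helpers <- NULL
  used <- list()
  locate_site <- function(enz, cpg) {
    sites <- iupac_scan(template, enz$motif, "top",
                        methyl_required_at = enz$methyl_required_at[[1]])
    req <- enz$methyl_required_at[[1]][1]
    site <- sites[sites$start + req == cpg, , drop = FALSE]
    if (nrow(site) == 0) {
      stop(sprintf("CpG at %d is not recognizable by %s", cpg, enz$name),
           call. = FALSE)
    }
    site <- site[1, ]
    cut <- if (enz$cut_mode == "intra_motif") {
      site$start + enz$intra_offset
    } else {
      site$end + enz$spacer
    }
    list(cut = cut, site = site)
  }
  # cut positions are motif-determined, so the supported P1 range can be
  # validated before any helper is designed
  r5 <- locate_site(enz5, site_5p)
  r3 <- locate_site(enz3, site_3p)
  c5 <- r5$cut; c3 <- r3$cut
  if (c3 <= c5) stop("the 3'-end cut must lie 3' of the 5'-end cut",
                     call. = FALSE)
  if (c3 > nchar(template$bases)) {
    stop("cut index falls outside the template", call. = FALSE)
  }
  p1_len <- c3 - c5
  if (p1_len > config$max_p1_len) {
    stop(sprintf(
      "P1 length %d nt exceeds the supported range (up to %d nt)",
      p1_len, config$max_p1_len), call. = FALSE)
  }
  add_helper <- function(enz, cpg, r) {
    if (!isTRUE(enz$needs_helper)) return(NULL)
    design_cut_helper(template, cpg, conditions, config,
                      motif_interval = c(r$site$start, r$site$end),
                      strand = "top")
  }
  helpers <- dplyr::bind_rows(add_helper(enz5, site_5p, r5),
                              add_helper(enz3, site_3p, r3))
  # bridge primer: artificial AP1a tail + capture of P1's 3'-terminal bases
  ap1 <- pick_ap(template)
  ap2 <- pick_ap(template, used = ap1$sequence)
  ap3 <- pick_ap(template, used = c(ap1$sequence, ap2$sequence))
  cra <- pick_window_by_tm(template, anchor = c3, side = "right",
                           lengths = 16:26,
                           tm_target = config$cr_tm_target,
                           conditions = conditions, sense = "revcomp")
  bp_seq <- paste0(ap1$sequence, cra$sequence)
  # co-mode TFP: AP2a tail, FR for the 5'-cut end, blocker, AP1a capture
  lens <- config$fr_len_range[1]:config$fr_len_range[2]
  cand <- purrr::map_dfr(lens, function(len) {
    if (c5 + len > nchar(template$bases)) return(NULL)
    fr_seq <- subseq_top(template, c5, c5 + len)
    tibble::tibble(len = len, sequence = fr_seq, gc = gc_fraction(fr_seq),
                   dG = hairpin_vals(fr_seq, config$loop_ref,
                                       conditions)$dG)
  })
  ok <- cand$gc >= config$fr_gc_range[1] & cand$gc <= config$fr_gc_range[2]
  if (!any(ok)) {
    stop("no FR length in 15-20 nt meets the 50-70% GC window", call. = FALSE)
  }
  sel <- cand[ok, ]; sel <- sel[order(sel$dG, sel$len), ][1, ]
  tfp_seq <- paste0(ap2$sequence, sel$sequence, ap1$sequence)
  tfp <- structure(
    list(ap = ap2,
         fr = list(sequence = sel$sequence, start = c5, end = c5 + sel$len,
                   gc = sel$gc, dG = sel$dG),
         blocker_nt_equiv = as.integer(config$blocker_nt_equiv),
         cr = list(sequence = ap1$sequence, start = NA_integer_,
                   end = NA_integer_, Tm = NA_real_),
         spacer_position = nchar(ap2$sequence) + sel$len,
         sequence = tfp_seq, fr_boundary = c5),
    class = "stem_tfp"
  )
  # probe inside the loop region of P1
  probe <- pick_window_by_tm(template, anchor = c5 + sel$len + 2L,
                             side = "left",
                             lengths = 18:min(30L, max(18L, p1_len - sel$len - 4L)),
                             tm_target = config$probe_tm_target,
                             conditions = conditions, sense = "top")
  amplicon <- nchar(ap2$sequence) + p1_len + nchar(ap1$sequence)
  oligos <- dplyr::bind_rows(
    oligo_row("BP", "BP", bp_seq, start = cra$start, end = cra$end,
              three_prime_blocked = TRUE, stage = "linear"),
    oligo_row("TFP", "TFP", tfp_seq, start = c5, end = c5 + sel$len,
              spacer_positions = tfp$spacer_position, stage = "linear"),
    oligo_row("AP2s", "AP2", revcomp(ap2$sequence),
              tm = nn_tm(ap2$sequence, conditions), stage = "exponential"),
    oligo_row("AP3s", "AP3", ap3$sequence,
              tm = nn_tm(ap3$sequence, conditions), stage = "exponential"),
    oligo_row("probe", "probe", probe$sequence, tm = probe$Tm,
              start = probe$start, end = probe$end, stage = "exponential"),
    if (!is.null(helpers) && nrow(helpers) > 0) {
      dplyr::bind_rows(lapply(seq_len(nrow(helpers)), function(i) {
        oligo_row(paste0("cut_helper_", i), "cut_helper",
                  helpers$oligo[i], tm = helpers$Tm[i],
                  start = helpers$start[i], end = helpers$end[i],
                  stage = "digestion")
      }))
    }
  )
  assert_design_clean(oligos, config)
  new_assay(
    mode = "comethylation", template = template, oligos = oligos,
    coords = list(c5 = c5, c3 = c3, fr_len = sel$len,
                  cra = c(cra$start, cra$end),
                  probe = c(probe$start, probe$end),
                  site_5p = c(r5$site$start, r5$site$end),
                  site_3p = c(r3$site$start, r3$site$end)),
    tfp = tfp, helpers = helpers,
    enzymes = c(enz5$name, enz3$name),
    expected_amplicon_len = amplicon,
    extra = list(p1_len = p1_len, ap1 = ap1, ap2 = ap2, ap3 = ap3),
    config = config
  )
}

#' Design a batch of single-site assays on random synthetic templates
#'
#' Draws seeded CpG-island-like templates with one planted methylated site
#' and designs a complete assay on each. Templates on which no oligo set
#' can satisfy the printed constraints are rejected and redrawn, exactly
#' as undesignable sites are discarded in practice; the draw sequence is
#' fully determined by `seed`.
#'
#' @param n Number of designs to return.
#' @param seed Integer seed.
#' @param enzyme_name MDRE to design for.
#' @param template_len Template length in nt.
#' @param gc_target Background GC fraction.
#' @param site_pos Planted site position (start of the motif).
#' @param conditions,config,registry As in [design_single_site_assay()].
#' @return List with `designs` (list of `stem_assay`) and `summary`
#'   (tibble: one row per design with FR length/GC and helper Tm).
#' @export
design_batch <- function(n = 50L, seed = 1L, enzyme_name = "GlaI",
                         template_len = 220L, gc_target = 0.65,
                         site_pos = 70L,
                         conditions = thermo_conditions(),
                         config = design_config(),
                         registry = builtin_enzymes()) {
  enz <- get_enzyme(enzyme_name, registry)
  req <- enz$methyl_required_at[[1]][1]
  designs <- list()
  attempt <- 0L
  while (length(designs) < n) {
    attempt <- attempt + 1L
    if (attempt > 50L * n) {
      stop("design_batch could not collect enough designable templates",
           call. = FALSE)
    }
    seed_k <- as.integer((as.numeric(seed) * 100000 + attempt) %%
                           .Machine$integer.max)
    tpl <- synth_template(
      template_len,
      planted_sites = list(list(enzyme = enz$name, pos = site_pos)),
      gc_target = gc_target, seed = seed_k,
      id = sprintf("synth_%03d", attempt), registry = registry
    )
    res <- tryCatch(
      design_single_site_assay(tpl, site_pos + req, enz$name,
                               conditions = conditions, config = config,
                               registry = registry),
      error = function(e) NULL
    )
    if (!is.null(res)) designs[[length(designs) + 1L]] <- res
  }
  summary <- purrr::map_dfr(designs, function(a) {
    h <- a$oligos[a$oligos$role == "cut_helper", ]
    tibble::tibble(
      template = a$template$id,
      fr_len = nchar(a$tfp$fr$sequence),
      fr_gc = a$tfp$fr$gc,
      helper_tm = h$Tm[1],
      blocker_nt_equiv = a$tfp$blocker_nt_equiv,
      amplicon_len = a$expected_amplicon_len
    )
  })
  list(designs = designs, summary = summary)
}
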