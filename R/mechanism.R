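# Per-molecule STEM-PCR reaction pathway: digestion -> TFP extension ->
# self-fold/self-prime -> P3 -> exponential phase, with a closed-form Ct.

#' Protocol parameters for reaction simulation
#'
#' Defaults: per-cycle efficiency 0.9, detection threshold 1e10 copies,
#' 50 cycles (the 10 + 40 two-stage protocol), complete digestion, and a
#' hybridization efficiency of 0.5 for the PNA/BP linear steps (restriction
#' digestion is more efficient than blocker/bridge hybridization).
#'
#' @param per_cycle_efficiency Amplification efficiency E in (0, 1].
#' @param detection_threshold Copy number Nq at which the signal crosses
#'   threshold.
#' @param max_cycles Maximum cycle count; later Cts are censored negative.
#' @param digestion_efficiency Per-site cut probability in (0, 1].
#' @param hybridization_efficiency Efficiency of the PNA/BP-mediated linear
#'   steps in (0, 1].
#' @param stochastic Poisson-sample input copy numbers?
#' @param length_decay_rate Optional exponential efficiency decay per nt of
#'   P1 beyond 45 nt (0 disables; co-methylation mode only).
#' @param max_fr_deleted Largest FR deletion that still self-primes.
#' @param seed Integer seed for stochastic sampling.
#' @return A `stem_protocol` list.
#' @export
protocol_params <- function(per_cycle_efficiency = 0.9,
                            detection_threshold = 1e10,
                            max_cycles = 50L,
                            digestion_efficiency = 1,
                            hybridization_efficiency = 0.5,
                            stochastic = FALSE,
                            length_decay_rate = 0,
                            max_fr_deleted = 3L,
                            seed = NULL) {
  stopifnot(per_cycle_efficiency > 0, per_cycle_efficiency <= 1,
            detection_threshold > 0, max_cycles >= 1,
            digestion_efficiency > 0, digestion_efficiency <= 1,
            hybridization_efficiency > 0, hybridization_efficiency <= 1,
            length_decay_rate >= 0)
  structure(
    list(per_cycle_efficiency = per_cycle_efficiency,
         detection_threshold = detection_threshold,
         max_cycles = as.integer(max_cycles),
         digestion_efficiency = digestion_efficiency,
         hybridization_efficiency = hybridization_efficiency,
         stochastic = isTRUE(stochastic),
         length_decay_rate = length_decay_rate,
         max_fr_deleted = as.integer(max_fr_deleted),
         seed = seed),
    class = "stem_protocol"
  )
}

#' Extend the TFP along a template fragment
#'
#' The capture region anneals within the fragment and the polymerase
#' extends from its 3' end toward the fragment's 5' end. The extension
#' stops at the later of the fragment's 5' end and the proximal edge of a
#' bound PNA blocker; a PNA binds only when its footprint is fully present
#' and perfectly matched on the fragment.
#'
#' @param fragment One-row fragment tibble (`parent`, `start`, `end`, ...).
#' @param tfp A `stem_tfp` design.
#' @param blockers Optional list of PNA blockers, each a list with
#'   `start`, `end` (template coordinates) and `target` (the sequence the
#'   PNA is complementary to).
#' @param template The fragment's parent [stem_template] (needed for PNA
#'   match checks).
#' @return A `stem_extension` list: `stop_pos`, `stop_reason`
#'   (`"template_5p_end"`, `"blocker_edge"` or `"ran_off"`), `cr_missing`,
#'   `fr_boundary`, `fr_len`.
#' @export
extend_from_tfp <- function(fragment, tfp, blockers = NULL,
                            template = NULL) {
  s <- fragment$start; e <- fragment$end
  g0 <- tfp$cr$start; g1 <- tfp$cr$end
  overlap <- max(0L, min(g1, e) - max(g0, s))
  if (overlap == 0L) {
    stop("no priming: the capture region is entirely absent from the fragment",
         call. = FALSE)
  }
  cr_missing <- (g1 - g0) - overlap
  stop_pos <- s
  reason <- "template_5p_end"
  if (!is.null(blockers)) {
    for (b in blockers) {
      if (b$start >= s && b$end <= e && !is.null(template)) {
        frag_seq <- substr(template$bases, b$start + 1L, b$end)
        if (frag_seq == b$target && b$end > stop_pos) {
          stop_pos <- b$end
          reason <- "blocker_edge"
        }
      }
    }
  }
  if (stop_pos >= min(g1, e)) reason <- "ran_off"
  structure(
    list(stop_pos = as.integer(stop_pos), stop_reason = reason,
         cr_missing = as.integer(cr_missing),
         fr_boundary = tfp$fr_boundary,
         fr_len = nchar(tfp$fr$sequence),
         fr_sequence = tfp$fr$sequence),
    class = "stem_extension"
  )
}

#' Fold the extension product and attempt self-priming
#'
#' The 3'-terminal FRa of the extension registers against the FRs carried
#' by the TFP. Any bases 3' of that register are a 3' overhang; bases
#' missing from FRa are an FR deletion. Self-priming (P3) requires a zero
#' overhang and an FR deletion within the configured maximum; otherwise
#' the product is the non-amplifiable run-through P4.
#'
#' @param product A `stem_extension`.
#' @param max_fr_deleted Largest FR deletion that still self-primes.
#' @param conditions [thermo_conditions] for the reported fold stability.
#' @param compute_stability Compute the hairpin stem thermodynamics of the
#'   realized register (for reporting)?
#' @return A `stem_fold` list: `foldable`, `overhang3`, `fr_deleted`,
#'   `cr_missing`, `self_primed`, `reduced_yield`, `stability`.
#' @export
self_fold_and_prime <- function(product, max_fr_deleted = 3L,
                                conditions = thermo_conditions(),
                                compute_stability = FALSE) {
  c5 <- product$fr_boundary
  overhang3 <- max(0L, c5 - product$stop_pos)
  fr_deleted <- min(max(0L, product$stop_pos - c5), product$fr_len)
  self_primed <- overhang3 == 0L && fr_deleted <= max_fr_deleted &&
    fr_deleted < product$fr_len && product$stop_reason != "ran_off"
  stability <- NULL
  if (compute_stability && self_primed) {
    stem <- substr(product$fr_sequence, fr_deleted + 1L, product$fr_len)
    if (nchar(stem) >= 3L) {
      stability <- hairpin_thermo(stem, loop_len = 40L, conditions)
    }
  }
  structure(
    list(foldable = self_primed || overhang3 == 0L,
         overhang3 = as.integer(overhang3),
         fr_deleted = as.integer(fr_deleted),
         cr_missing = as.integer(product$cr_missing),
         self_primed = self_primed,
         reduced_yield = self_primed && (fr_deleted > 0L ||
                                           product$cr_missing > 0L),
         stability = stability),
    class = "stem_fold"
  )
}

#' Default truncation-penalty table
#'
#' Multiplicative efficiency penalties from the truncation studies: a
#' single extra 3' base blocks amplification entirely; deleting 2-3 nt
#' from the FR costs ~10-fold; one missing CR base costs 5-fold and two
#' or more block amplification. The 1-nt FR deletion penalty defaults to
#' 1 (no cost) and is configurable.
#'
#' @return Named list of penalty factors.
#' @export
penalty_table <- function() {
  list(fr_del_1 = 1.0, fr_del_23 = 0.1, cr_miss_1 = 0.2)
}

#' P3 yield from a fold outcome
#'
#' Multiplicative lookup: any 3' overhang (>= 1 nt) gives 0; FR deletions
#' of 0-1 nt give the configured factor (default 1), 2-3 nt give 0.1, more
#' give 0; CR losses of 0 nt give 1, 1 nt gives 0.2, >= 2 nt give 0.
#'
#' @param fold A `stem_fold` (or list with `overhang3`, `fr_deleted`,
#'   `cr_missing`).
#' @param penalties A [penalty_table()] list.
#' @return Yield fraction in `[0, 1]`.
#' @examples
#' p3_yield(list(overhang3 = 0, fr_deleted = 2, cr_missing = 0))
#' @export
p3_yield <- function(fold, penalties = penalty_table()) {
  ov <- fold$overhang3; fd <- fold$fr_deleted; cm <- fold$cr_missing
  if (ov < 0 || fd < 0 || cm < 0) {
    stop("overhang/deletion counts must be non-negative", call. = FALSE)
  }
  if (!is.null(fold$self_primed) && !isTRUE(fold$self_primed)) return(0)
  if (ov >= 1) return(0)
  y <- if (fd == 0) 1 else if (fd == 1) penalties$fr_del_1
       else if (fd <= 3) penalties$fr_del_23 else 0
  cr <- if (cm == 0) 1 else if (cm == 1) penalties$cr_miss_1 else 0
  y * cr
}

#' Classify a fragment into the co-methylation scenarios T1-T4
#'
#' T1: no specific ends at the designed cuts; T2: specific 5' end only;
#' T3: specific 3' end only (linear extension starts but the long 3'
#' overhang after self-folding blocks amplification); T4: both specific
#' ends — the only class that amplifies. Fragments not overlapping the
#' target region are `"none"`.
#'
#' @param fragment One-row fragment tibble.
#' @param assay A co-methylation `stem_assay`.
#' @return One of `"T1"`, `"T2"`, `"T3"`, `"T4"`, `"none"`.
#' @export
classify_scenario <- function(fragment, assay) {
  if (assay$mode != "comethylation") {
    stop("classify_scenario() needs a co-methylation assay", call. = FALSE)
  }
  c5 <- assay$coords$c5; c3 <- assay$coords$c3
  s <- fragment$start; e <- fragment$end
  if (min(e, c3) - max(s, c5) <= 0) return("none")
  spec5 <- fragment$end5_type == "specific" && s == c5
  spec3 <- fragment$end3_type == "specific" && e == c3
  if (spec5 && spec3) "T4" else if (spec5) "T2" else if (spec3) "T3" else "T1"
}

#' Closed-form Ct prediction
#'
#' `Ct = ln(Nq / N0) / ln(1 + E)`, clamped at 0; non-positive effective
#' copies return `NA` (censored negative).
#'
#' @param effective_copies Effective amplifiable copies N0.
#' @param E Per-cycle efficiency in (0, 1].
#' @param Nq Detection threshold in copies.
#' @return Ct in cycles, or `NA_real_` when censored.
#' @examples
#' predict_ct(1024, E = 1, Nq = 1024 * 1024)
#' @export
predict_ct <- function(effective_copies, E = 0.9, Nq = 1e10) {
  if (!is.finite(effective_copies) || effective_copies <= 0) {
    return(NA_real_)
  }
  max(0, log(Nq / effective_copies) / log(1 + E))
}

# per-fragment yield trace for one pool against one assay
trace_pool <- function(pool, assay, protocol) {
  templates <- pool_templates(pool)
  tfp <- assay$tfp
  blockers <- NULL
  if (assay$mode == "pna_mutation") {
    blockers <- list(list(start = assay$coords$pna[1],
                          end = assay$coords$pna[2],
                          target = assay$pna_target))
  }
  n <- nrow(pool)
  out <- tibble::tibble(
    parent = pool$parent, start = pool$start, end = pool$end,
    copies = pool$copies,
    scenario = NA_character_, overhang3 = NA_integer_,
    fr_deleted = NA_integer_, cr_missing = NA_integer_,
    yield = 0
  )
  for (i in seq_len(n)) {
    fr <- pool[i, ]
    if (assay$mode == "comethylation") {
      sc <- classify_scenario(fr, assay)
      out$scenario[i] <- sc
      out$yield[i] <- if (sc == "T4") 1 else 0
      next
    }
    ext <- tryCatch(
      extend_from_tfp(fr, tfp, blockers = blockers,
                      template = templates[[fr$parent]]),
      error = function(e) NULL
    )
    if (is.null(ext)) next  # no priming on this fragment class
    fold <- self_fold_and_prime(ext, max_fr_deleted = protocol$max_fr_deleted)
    out$overhang3[i] <- fold$overhang3
    out$fr_deleted[i] <- fold$fr_deleted
    out$cr_missing[i] <- fold$cr_missing
    out$yield[i] <- p3_yield(fold)
  }
  out
}

#' Simulate a STEM-PCR reaction end to end
#'
#' Runs the assay's pathway over a fragment pool: MDRE digestion (for the
#' enzyme-gated modes), per-fragment TFP extension, self-fold and
#' truncation-penalty yield (or T1-T4 classification for co-methylation),
#' then sums effective P3 copies and predicts the Ct. A reaction with no
#' effective copies, or whose Ct exceeds `max_cycles`, is censored
#' negative.
#'
#' @param pool A `stem_pool` whose templates share coordinates with the
#'   assay's design template.
#' @param assay A `stem_assay`.
#' @param protocol A [protocol_params()] list.
#' @param digest Apply the enzymatic digestion step? Disable to model a
#'   no-enzyme control.
#' @return A `stem_reaction` object; `glance()` gives a one-row summary.
#' @export
simulate_reaction <- function(pool, assay, protocol = protocol_params(),
                              digest = TRUE) {
  stopifnot(inherits(assay, "stem_assay"))
  templates <- pool_templates(pool)
  if (nrow(pool) > 0) {
    tlen <- nchar(assay$template$bases)
    plens <- vapply(templates, function(t) nchar(t$bases), integer(1))
    if (!all(plens == tlen)) {
      stop("pool templates do not share coordinates with the assay template",
           call. = FALSE)
    }
  }
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  if (protocol$stochastic && nrow(pool) > 0) {
    pool$copies <- rpois(nrow(pool), pool$copies)
    pool <- pool[pool$copies > 0L, , drop = FALSE]
    pool <- new_fragment_pool(pool, templates)
  }
  linear_eff <- 1
  if (assay$mode %in% c("pna_mutation", "comethylation")) {
    linear_eff <- protocol$hybridization_efficiency
  }
  if (digest && assay$mode %in% c("single_site_mdre", "comethylation")) {
    events <- purrr::map_dfr(templates, function(t) {
      purrr::map_dfr(assay$enzymes, function(enz) {
        h <- assay$helpers
        if (!is.null(h) && nrow(h) > 0) h$seq_id <- t$id
        find_cut_events(t, enz, helpers = h)
      })
    })
    if (nrow(events) > 0) pool <- digest_pool(pool, events)
  }
  trace <- trace_pool(pool, assay, protocol)
  eff <- sum(trace$copies * trace$yield) *
    protocol$digestion_efficiency * linear_eff
  if (assay$mode == "comethylation" && protocol$length_decay_rate > 0) {
    eff <- eff * exp(-protocol$length_decay_rate *
                       max(0, assay$p1_len - 45))
  }
  ct <- predict_ct(eff, protocol$per_cycle_efficiency,
                   protocol$detection_threshold)
  amplifiable <- is.finite(ct) && ct <= protocol$max_cycles
  if (!amplifiable) ct <- NA_real_
  scen <- c(T1 = 0, T2 = 0, T3 = 0, T4 = 0)
  if (assay$mode == "comethylation") {
    tab <- dplyr::summarise(
      dplyr::group_by(trace[!is.na(trace$scenario) &
                              trace$scenario != "none", ], .data$scenario),
      copies = sum(.data$copies), .groups = "drop"
    )
    scen[tab$scenario] <- tab$copies
  }
  total_in <- sum(trace$copies)
  structure(
    list(mode = assay$mode, amplifiable = amplifiable,
         effective_copies = eff,
         p3_yield = if (total_in > 0) {
           sum(trace$copies * trace$yield) / total_in
         } else 0,
         Ct = ct, scenario_counts = scen, trace = trace,
         protocol = protocol),
    class = "stem_reaction"
  )
}

#' @export
print.stem_reaction <- function(x, ...) {
  cat(sprintf("<stem_reaction> %s: %s (effective copies %.3g%s)\n",
              x$mode,
              if (x$amplifiable) sprintf("Ct = %.2f", x$Ct) else "NEGATIVE",
              x$effective_copies,
              if (x$mode == "comethylation") {
                paste0("; T1-T4: ",
                       paste(x$scenario_counts, collapse = "/"))
              } else ""))
  invisible(x)
}

#' Run an in silico dilution series
#'
#' Simulates the assay at each input copy number (optionally Poisson
#' sampled) in a constant unmethylated background, and fits mean Ct
#' against log10 input copies by least squares over the positive levels.
#'
#' @param assay A single-site `stem_assay` built on a methylated template.
#' @param copies_list Input copy numbers (e.g. `c(2500, 1000, 200, 50, 10)`).
#' @param background_copies Unmethylated background copies per reaction.
#' @param replicates Replicates per level.
#' @param protocol A [protocol_params()] list; its `stochastic` flag picks
#'   exact vs Poisson-sampled inputs.
#' @param seed Integer seed for the whole series.
#' @return A `stem_dilution` object with `$results` (tibble: copies,
#'   replicate, sampled_copies, Ct, amplifiable) and `$fit` (slope,
#'   intercept, r.squared), or `fit = NULL` with a warning when every
#'   replicate is negative.
#' @export
run_dilution_series <- function(assay, copies_list,
                                background_copies = 0,
                                replicates = 3L,
                                protocol = protocol_params(),
                                seed = 1L) {
  stopifnot(length(copies_list) >= 1)
  set.seed(seed)
  meth <- assay$template
  unmeth <- unmethylated(meth)
  rows <- list()
  for (cp in copies_list) {
    for (r in seq_len(replicates)) {
      m <- if (protocol$stochastic) rpois(1L, cp) else cp
      pool <- make_mixture(meth, unmeth, m, background_copies)
      run_protocol <- protocol
      run_protocol$stochastic <- FALSE  # inputs already sampled here
      run_protocol$seed <- NULL
      res <- simulate_reaction(pool, assay, run_protocol)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        copies = cp, replicate = r, sampled_copies = m,
        effective_copies = res$effective_copies,
        Ct = res$Ct, amplifiable = res$amplifiable
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  fit <- NULL
  pos <- results[results$amplifiable & results$copies > 0, , drop = FALSE]
  if (nrow(pos) == 0) {
    warning("all replicates negative; regression omitted")
  } else {
    means <- dplyr::summarise(dplyr::group_by(pos, .data$copies),
                              mean_ct = mean(.data$Ct), .groups = "drop")
    if (nrow(means) >= 2) {
      lmfit <- lm(mean_ct ~ log10(copies), data = means)
      fit <- list(
        slope = unname(stats::coef(lmfit)[2]),
        intercept = unname(stats::coef(lmfit)[1]),
        r.squared = suppressWarnings(summary(lmfit)$r.squared),
        n_levels = nrow(means)
      )
    }
  }
  structure(list(results = results, fit = fit, assay_mode = assay$mode),
            class = "stem_dilution")
}

#' @export
print.stem_dilution <- function(x, ...) {
  cat(sprintf("<stem_dilution> %d reactions over %d level(s)",
              nrow(x$results), length(unique(x$results$copies))))
  if (!is.null(x$fit)) {
    cat(sprintf("; Ct = %.2f %+.2f log10(copies), R^2 = %.4f",
                x$fit$intercept, x$fit$slope, x$fit$r.squared))
  }
  cat("\n")
  invisible(x)
}
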