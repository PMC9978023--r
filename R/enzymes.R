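# Methylation-dependent restriction enzyme (MDRE) models and in silico
# digestion. Cuts are modeled as blunt double-strand breaks at the
# recognized strand's cut point; only that strand's 5' end drives the
# STEM-PCR mechanism.

#' Built-in MDRE registry
#'
#' The four enzymes of the assay family, with their degenerate recognition
#' motifs, the pattern position that must carry 5-mC on the recognized
#' strand, and the cut rule:
#' * GlaI  (R(5mC)GY): intra-motif blunt cut, default offset 2 (centered);
#' * MspJI ((5mC)NNR N9): cut 9 nt downstream of the motif;
#' * FspEI (C(5mC) N12): cut 12 nt downstream;
#' * LpnPI (C(5mC)DG N10): cut 10 nt downstream.
#' Downstream-spacer enzymes additionally require a cut helper forming a
#' local hemimethylated duplex over the site.
#'
#' @param extra Optional data frame of additional enzymes with the same
#'   columns; duplicate names raise an error.
#' @return Tibble: `name`, `motif`, `methyl_required_at` (list of 0-based
#'   pattern indices), `cut_mode` (`"downstream_spacer"`/`"intra_motif"`),
#'   `spacer`, `intra_offset`, `needs_helper`.
#' @examples
#' builtin_enzymes()
#' @export
builtin_enzymes <- function(extra = NULL) {
  reg <- tibble::tibble(
    name = c("GlaI", "MspJI", "FspEI", "LpnPI"),
    motif = c("RCGY", "CNNR", "CC", "CCDG"),
    methyl_required_at = list(1L, 0L, 1L, 1L),
    cut_mode = c("intra_motif", "downstream_spacer", "downstream_spacer",
                 "downstream_spacer"),
    spacer = c(NA_integer_, 9L, 12L, 10L),
    intra_offset = c(2L, NA_integer_, NA_integer_, NA_integer_)
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    dup <- intersect(extra$name, reg$name)
    if (length(dup) > 0) {
      stop(sprintf("duplicate enzyme name(s): %s", paste(dup, collapse = ", ")),
           call. = FALSE)
    }
    if (!is.list(extra$methyl_required_at)) {
      extra$methyl_required_at <- as.list(as.integer(extra$methyl_required_at))
    }
    reg <- dplyr::bind_rows(reg, extra)
  }
  reg$needs_helper <- reg$cut_mode == "downstream_spacer"
  reg
}

get_enzyme <- function(enzyme, registry = builtin_enzymes()) {
  if (is.character(enzyme)) {
    row <- registry[registry$name == enzyme, , drop = FALSE]
    if (nrow(row) == 0) {
      stop(sprintf("unknown enzyme '%s'", enzyme), call. = FALSE)
    }
    return(row)
  }
  tibble::as_tibble(enzyme)
}

#' Construct a cut helper record
#'
#' A cut helper is a ~20-bp oligo that hybridizes to the methylated template
#' to form a partial hemimethylated duplex, enabling a downstream-spacer
#' MDRE to cleave at a fixed distance. The helper must be exactly
#' complementary to its target interval on the stated strand of
#' hybridization.
#'
#' @param oligo Helper sequence 5'->3'.
#' @param seq_id Template id.
#' @param start,end Target interval, 0-based half-open, top-strand space.
#' @param strand Strand of hybridization (`"top"` binds the top strand, so
#'   the helper is the reverse complement of the top-strand window).
#' @return One-row tibble usable in the `helpers` argument of
#'   [find_cut_events()].
#' @export
cut_helper <- function(oligo, seq_id, start, end, strand = "top") {
  strand <- match.arg(strand, c("top", "bottom"))
  tibble::tibble(
    oligo = toupper(oligo), seq_id = seq_id,
    start = as.integer(start), end = as.integer(end), strand = strand
  )
}

validate_helpers <- function(template, helpers) {
  if (is.null(helpers) || nrow(helpers) == 0) return(invisible(TRUE))
  for (i in seq_len(nrow(helpers))) {
    h <- helpers[i, ]
    if (h$seq_id != template$id) next
    win <- subseq_top(template, h$start, h$end)
    expect <- if (h$strand == "top") fast_revcomp(win) else win
    if (h$oligo != expect) {
      stop(sprintf(
        "cut helper %d is not complementary to its target [%d,%d) on the %s strand",
        i, h$start, h$end, h$strand), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Find methylation-gated cut events on a template
#'
#' A recognition site yields a cut event iff (i) the motif matches with all
#' required 5-mC marks present on the recognized strand, and (ii) for
#' downstream-spacer enzymes, at least one validated helper hybridizing to
#' that same strand has a target interval fully containing the motif. The
#' strand requirement reflects the digestion protocol: the template is
#' melted and only the helper-bound stretch reforms a (hemimethylated)
#' duplex the enzyme can cleave, so the helper selects both the site and
#' the recognized strand.
#' Cut indices are inter-base template coordinates in top-strand space:
#' `motif_end + spacer` for a top-strand match of a spacer enzyme
#' (`motif_start - spacer` for a bottom-strand match), and
#' `site_start + intra_offset` within the motif for intra-motif cutters.
#' Cuts falling outside `[0, L]` are dropped.
#'
#' @param template A [stem_template].
#' @param enzyme Enzyme name or registry row (see [builtin_enzymes()]).
#' @param helpers Tibble of [cut_helper()] rows (may be `NULL`).
#' @param registry Enzyme registry for name lookup.
#' @return Tibble: `enzyme`, `seq_id`, `start`, `end`, `strand`,
#'   `cut_index`.
#' @export
find_cut_events <- function(template, enzyme, helpers = NULL,
                            registry = builtin_enzymes()) {
  enz <- get_enzyme(enzyme, registry)
  validate_helpers(template, helpers)
  L <- nchar(template$bases)
  out <- list()
  for (strand in c("top", "bottom")) {
    sites <- iupac_scan(template, enz$motif, strand,
                        methyl_required_at = enz$methyl_required_at[[1]])
    if (nrow(sites) == 0) next
    if (isTRUE(enz$needs_helper)) {
      covered <- vapply(seq_len(nrow(sites)), function(i) {
        !is.null(helpers) && nrow(helpers) > 0 &&
          any(helpers$seq_id == template$id &
              helpers$strand == strand &
              helpers$start <= sites$start[i] &
              helpers$end >= sites$end[i])
      }, logical(1))
      sites <- sites[covered, , drop = FALSE]
      if (nrow(sites) == 0) next
    }
    cut_index <- if (enz$cut_mode == "downstream_spacer") {
      if (strand == "top") sites$end + enz$spacer else sites$start - enz$spacer
    } else {
      if (strand == "top") sites$start + enz$intra_offset
      else sites$end - enz$intra_offset
    }
    keep <- cut_index >= 0L & cut_index <= L
    if (!any(keep)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      enzyme = enz$name, seq_id = template$id,
      start = sites$start[keep], end = sites$end[keep],
      strand = strand, cut_index = as.integer(cut_index[keep])
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(enzyme = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), cut_index = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$cut_index)
}

#' Digest a fragment pool at given cut events
#'
#' Every molecule is cleaved at each applicable cut index (those strictly
#' inside its interval) with probability `digestion_efficiency`; at the
#' default efficiency of 1 the digestion is deterministic and idempotent.
#' Ends created by a cut are typed `"specific"`; pre-existing ends keep
#' their type. Total nucleotide content (copies x bases) is conserved.
#'
#' @param pool A [fragment_pool()] tibble.
#' @param events Cut events as returned by [find_cut_events()], per parent
#'   (matched on `seq_id`).
#' @param digestion_efficiency Per-molecule, per-site cut probability in
#'   (0, 1].
#' @param seed Optional integer seed for the stochastic (< 1) case.
#' @return A new fragment pool.
#' @export
digest_pool <- function(pool, events, digestion_efficiency = 1, seed = NULL) {
  stopifnot(digestion_efficiency > 0, digestion_efficiency <= 1)
  if (!is.null(seed)) set.seed(seed)
  templates <- attr(pool, "templates")
  if (nrow(events) == 0 || nrow(pool) == 0) return(pool)
  rows <- list()
  for (r in seq_len(nrow(pool))) {
    fr <- pool[r, ]
    cuts <- sort(unique(events$cut_index[
      events$seq_id == fr$parent &
        events$cut_index > fr$start & events$cut_index < fr$end
    ]))
    if (length(cuts) == 0) {
      rows[[length(rows) + 1L]] <- fr
      next
    }
    if (digestion_efficiency >= 1) {
      rows[[length(rows) + 1L]] <- split_fragment(fr, cuts)
    } else {
      # distribute copies over the 2^k cut subsets
      k <- length(cuts)
      subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
      probs <- apply(subsets, 1, function(s) {
        prod(ifelse(s, digestion_efficiency, 1 - digestion_efficiency))
      })
      alloc <- as.vector(stats::rmultinom(1, fr$copies, probs))
      for (si in which(alloc > 0)) {
        sub <- cuts[unlist(subsets[si, ])]
        piece <- fr
        piece$copies <- alloc[si]
        rows[[length(rows) + 1L]] <-
          if (length(sub) == 0) piece else split_fragment(piece, sub)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$parent, .data$start, .data$end,
                    .data$strand, .data$end5_type, .data$end3_type),
    copies = sum(.data$copies), .groups = "drop"
  )
  new_fragment_pool(out, templates)
}

split_fragment <- function(fr, cuts) {
  bounds <- unname(c(fr$start, cuts, fr$end))
  n <- length(bounds) - 1L
  tibble::tibble(
    parent = fr$parent,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    strand = fr$strand,
    end5_type = c(fr$end5_type, rep("specific", n - 1L)),
    end3_type = c(rep("specific", n - 1L), fr$end3_type),
    copies = fr$copies
  )
}

#' Write a digestion report as TSV
#'
#' @param pool A fragment pool.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_digestion_report <- function(pool, path) {
  readr::write_tsv(tibble::as_tibble(pool), path)
  invisible(path)
}
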