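# Seeded generators for synthetic templates and fragment pools, emulating
# sonicated genomic/cell-free DNA (mean fragment size ~150 bp). Everything
# here is deterministic for a fixed seed so that designs and simulations
# are reproducible with no external data.

new_fragment_pool <- function(df, templates) {
  df <- tibble::as_tibble(df)
  structure(df, templates = templates,
            class = c("stem_pool", class(df)))
}

#' Create a fragment pool from intact templates
#'
#' Each template contributes one full-length double-stranded molecule class
#' with `"native"` ends and the given copy number.
#'
#' @param templates A [stem_template] or (named) list of them.
#' @param copies Copy number per template (recycled).
#' @return A `stem_pool` tibble (`parent`, `start`, `end`, `strand`,
#'   `end5_type`, `end3_type`, `copies`) carrying the templates as an
#'   attribute.
#' @export
fragment_pool <- function(templates, copies = 1L) {
  if (inherits(templates, "stem_template")) templates <- list(templates)
  ids <- vapply(templates, `[[`, "", "id")
  names(templates) <- ids
  copies <- as.integer(rep_len(copies, length(templates)))
  df <- tibble::tibble(
    parent = ids,
    start = 0L,
    end = vapply(templates, function(t) nchar(t$bases), integer(1)),
    strand = "top",
    end5_type = "native",
    end3_type = "native",
    copies = copies
  )
  df <- df[df$copies > 0L, , drop = FALSE]
  new_fragment_pool(df, templates)
}

#' @export
print.stem_pool <- function(x, ...) {
  cat(sprintf("<stem_pool> %d fragment class(es), %d molecules, %d template(s)\n",
              nrow(x), sum(x$copies), length(attr(x, "templates"))))
  NextMethod()
}

pool_templates <- function(pool) attr(pool, "templates")

concretize_motif <- function(motif, methyl_at) {
  expand <- c(A = "A", C = "C", G = "G", T = "T",
              R = "AG", Y = "CT", S = "GC", W = "AT", K = "GT", M = "AC",
              B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  chars <- strsplit(toupper(motif), "")[[1]]
  out <- character(length(chars))
  for (i in seq_along(chars)) {
    opts <- strsplit(expand[[chars[i]]], "")[[1]]
    # put the methyl-required C in CpG context where the motif allows it
    if ((i - 1L) %in% (methyl_at + 1L) && "G" %in% opts) {
      out[i] <- "G"
    } else if (length(opts) == 1L) {
      out[i] <- opts
    } else {
      out[i] <- sample(opts, 1L)
    }
  }
  paste(out, collapse = "")
}

#' Generate a synthetic annotated template
#'
#' Random background at a target GC composition with recognition sites
#' planted verbatim (and marked as 5-methylated where requested). The
#' default GC target of 0.65 mimics the CpG-island promoter context the
#' real assays target.
#'
#' @param length Template length in nt.
#' @param planted_sites List of site descriptors: each a list with `enzyme`
#'   (registry name) or `motif` (IUPAC), `pos` (0-based start),
#'   `methylated_top` / `methylated_bottom` (defaults `TRUE`).
#' @param gc_target Background GC fraction.
#' @param seed Integer seed; the generator is seed-deterministic.
#' @param id Sequence id.
#' @param registry Enzyme registry for motif lookup.
#' @return A [stem_template].
#' @examples
#' synth_template(200, list(list(enzyme = "GlaI", pos = 80)), seed = 1)
#' @export
synth_template <- function(length, planted_sites = list(), gc_target = 0.65,
                           seed = 1L, id = "synth",
                           registry = builtin_enzymes()) {
  stopifnot(length >= 20)
  set.seed(seed)
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  # resolve planted sites, check overlap
  resolved <- lapply(planted_sites, function(s) {
    if (!is.null(s$enzyme)) {
      enz <- get_enzyme(s$enzyme, registry)
      s$motif <- enz$motif
      s$methyl_at <- enz$methyl_required_at[[1]]
    } else {
      if (is.null(s$methyl_at)) s$methyl_at <- integer()
    }
    s$site_seq <- concretize_motif(s$motif, s$methyl_at)
    s$end <- s$pos + nchar(s$site_seq)
    if (s$pos < 0 || s$end > length) {
      stop("planted site outside template bounds", call. = FALSE)
    }
    s
  })
  if (length(resolved) > 1L) {
    iv <- t(vapply(resolved, function(s) c(s$pos, s$end), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("planted sites overlap", call. = FALSE)
    }
  }
  marks <- list()
  for (s in resolved) {
    sv <- strsplit(s$site_seq, "")[[1]]
    bases[(s$pos + 1L):(s$end)] <- sv
    mt <- if (is.null(s$methylated_top)) TRUE else isTRUE(s$methylated_top)
    mb <- if (is.null(s$methylated_bottom)) TRUE else isTRUE(s$methylated_bottom)
    for (j in s$methyl_at) {
      if (mt) {
        marks[[length(marks) + 1L]] <-
          tibble::tibble(pos = s$pos + j, strand = "top", mark = "5mC")
      }
      # bottom-strand cytosine of the CpG sits under the following G
      if (mb && j + 1L < nchar(s$site_seq) && sv[j + 2L] == "G") {
        marks[[length(marks) + 1L]] <-
          tibble::tibble(pos = s$pos + j + 1L, strand = "bottom", mark = "5mC")
      }
    }
  }
  stem_template(id, paste(bases, collapse = ""),
                marks = if (length(marks)) dplyr::bind_rows(marks) else NULL)
}

#' Fragment copies of a template at random inter-base points
#'
#' Emulates sonication: with the default `uniform_breaks` model each copy
#' receives `round(L / mean_len) - 1` breaks placed uniformly without
#' replacement; the `geometric` model breaks each inter-base position
#' independently with probability `1 / mean_len`. Fragments of one copy
#' tile the parent exactly; all break-created ends are typed
#' `"arbitrary"`.
#'
#' @param template A [stem_template].
#' @param n_copies Number of molecules to fragment.
#' @param mean_len Target mean fragment length in nt (default 150).
#' @param model `"uniform_breaks"` or `"geometric"`.
#' @param seed Integer seed.
#' @return A `stem_pool`.
#' @export
fragmentize <- function(template, n_copies, mean_len = 150,
                        model = c("uniform_breaks", "geometric"),
                        seed = 1L) {
  model <- match.arg(model)
  stopifnot(mean_len >= 30, n_copies >= 1)
  L <- nchar(template$bases)
  if (mean_len >= L) {
    warning("mean_len >= template length; molecules left intact")
    return(fragment_pool(list(template), copies = n_copies))
  }
  set.seed(seed)
  nb <- max(0L, as.integer(round(L / mean_len)) - 1L)
  pieces <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    brk <- if (model == "uniform_breaks") {
      if (nb > 0L) sort(sample.int(L - 1L, nb)) else integer()
    } else {
      which(stats::runif(L - 1L) < 1 / mean_len)
    }
    bounds <- c(0L, brk, L)
    n <- length(bounds) - 1L
    pieces[[i]] <- tibble::tibble(
      start = bounds[-length(bounds)], end = bounds[-1],
      end5_type = c("native", rep("arbitrary", n - 1L)),
      end3_type = c(rep("arbitrary", n - 1L), "native")
    )
  }
  df <- dplyr::bind_rows(pieces)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$start, .data$end, .data$end5_type,
                    .data$end3_type),
    copies = dplyr::n(), .groups = "drop"
  )
  df$parent <- template$id
  df$strand <- "top"
  df <- df[, c("parent", "start", "end", "strand", "end5_type", "end3_type",
               "copies")]
  new_fragment_pool(df, setNames(list(template), template$id))
}

#' Mix methylated and unmethylated template copies into one pool
#'
#' The two templates must share coordinates (same bases); marks are present
#' only on the methylated fraction. Copy counts are conserved through the
#' optional fragmentation step.
#'
#' @param methylated_template,unmethylated_template [stem_template]s with
#'   identical bases.
#' @param m_copies,u_copies Copy numbers (either may be 0).
#' @param fragmentation Optional list with `mean_len` and/or `model`,
#'   passed to [fragmentize()].
#' @param seed Integer seed for the fragmentation step.
#' @return A `stem_pool` whose parents are the two template ids.
#' @export
make_mixture <- function(methylated_template, unmethylated_template,
                         m_copies, u_copies, fragmentation = NULL,
                         seed = 1L) {
  if (methylated_template$bases != unmethylated_template$bases) {
    stop("mixture templates must share coordinates (identical bases)",
         call. = FALSE)
  }
  if (methylated_template$id == unmethylated_template$id) {
    stop("mixture templates need distinct ids", call. = FALSE)
  }
  parts <- list()
  tpls <- list(methylated_template, unmethylated_template)
  cps <- c(m_copies, u_copies)
  for (i in 1:2) {
    if (cps[i] <= 0) next
    parts[[length(parts) + 1L]] <- if (is.null(fragmentation)) {
      fragment_pool(list(tpls[[i]]), copies = cps[i])
    } else {
      fragmentize(
        tpls[[i]], n_copies = cps[i],
        mean_len = fragmentation$mean_len %||% 150,
        model = fragmentation$model %||% "uniform_breaks",
        seed = seed + i
      )
    }
  }
  templates <- setNames(tpls, vapply(tpls, `[[`, "", "id"))
  if (length(parts) == 0) {
    return(new_fragment_pool(
      tibble::tibble(parent = character(), start = integer(),
                     end = integer(), strand = character(),
                     end5_type = character(), end3_type = character(),
                     copies = integer()),
      templates
    ))
  }
  df <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
  new_fragment_pool(df, templates)
}

#' Drop all 5-mC marks from a template
#'
#' Convenience for building the unmethylated counterpart of a methylated
#' synthetic template.
#'
#' @param template A [stem_template].
#' @param id Optional new id (default appends `"_unmeth"`).
#' @return An unmethylated [stem_template] with the same bases.
#' @export
unmethylated <- function(template, id = paste0(template$id, "_unmeth")) {
  stem_template(id, template$bases)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
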