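# Sequence and 5-mC mark data model. Coordinates are 0-based, half-open
# throughout the package; cut points are inter-base indices in [0, L].

#' Construct an annotated template sequence
#'
#' An annotated sequence is a double-stranded DNA template given by its top
#' strand (5'->3') together with per-position, per-strand 5-methylcytosine
#' marks. A top-strand mark must sit on a `C`; a bottom-strand mark sits under
#' a top-strand `G` (the complementary cytosine). A "fully methylated" CpG
#' therefore carries two marks: `(p, top)` on the C and `(p + 1, bottom)`
#' under the G.
#'
#' @param id Sequence identifier.
#' @param bases Top strand 5'->3', characters in `A`, `C`, `G`, `T`, `N`
#'   (lower case is accepted and upper-cased).
#' @param marks A data frame with columns `pos` (0-based index), `strand`
#'   (`"top"` or `"bottom"`) and optionally `mark` (only `"5mC"` is
#'   supported). `NULL` means fully unmethylated.
#' @param single_stranded Set to `TRUE` for oligonucleotide-like inputs; the
#'   mechanism simulator treats templates as double-stranded by default.
#' @return An object of class `stem_template`.
#' @examples
#' tpl <- stem_template("t1", "ACGTACGTACGT",
#'   marks = data.frame(pos = 1, strand = "top")
#' )
#' tpl
#' @export
stem_template <- function(id, bases, marks = NULL, single_stranded = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  bases <- toupper(as.character(bases))
  if (!grepl("^[ACGTN]+$", bases)) {
    stop("`bases` may only contain A, C, G, T or N", call. = FALSE)
  }
  marks <- normalize_marks(marks)
  validate_marks(bases, marks, id)
  structure(
    list(id = id, bases = bases, marks = marks,
         single_stranded = isTRUE(single_stranded)),
    class = "stem_template"
  )
}

normalize_marks <- function(marks) {
  if (is.null(marks) || (is.data.frame(marks) && nrow(marks) == 0L)) {
    return(tibble::tibble(pos = integer(), strand = character(),
                          mark = character()))
  }
  marks <- tibble::as_tibble(marks)
  if (!all(c("pos", "strand") %in% names(marks))) {
    stop("marks need `pos` and `strand` columns", call. = FALSE)
  }
  if (!"mark" %in% names(marks)) marks$mark <- "5mC"
  marks <- dplyr::distinct(marks, .data$pos, .data$strand, .data$mark)
  marks$pos <- as.integer(marks$pos)
  dplyr::arrange(marks, .data$pos, .data$strand)
}

validate_marks <- function(bases, marks, id) {
  L <- nchar(bases)
  if (nrow(marks) == 0L) return(invisible(TRUE))
  if (!all(marks$strand %in% c("top", "bottom"))) {
    stop("mark strand must be 'top' or 'bottom'", call. = FALSE)
  }
  if (!all(marks$mark == "5mC")) {
    stop("only 5mC marks are supported", call. = FALSE)
  }
  bad <- marks$pos < 0L | marks$pos >= L
  if (any(bad)) {
    stop(sprintf("mark position %d outside [0, %d) on '%s'",
                 marks$pos[which(bad)[1]], L, id), call. = FALSE)
  }
  base_at <- strsplit(bases, "", fixed = TRUE)[[1]][marks$pos + 1L]
  need <- ifelse(marks$strand == "top", "C", "G")
  bad <- base_at != need
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "5mC mark at position %d (%s strand) of '%s' sits on base %s, expected %s",
      marks$pos[i], marks$strand[i], id, base_at[i], need[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.stem_template <- function(x, ...) {
  cat(sprintf("<stem_template> %s: %d nt, %d 5mC mark(s)%s\n",
              x$id, nchar(x$bases), nrow(x$marks),
              if (x$single_stranded) ", single-stranded" else ""))
  invisible(x)
}

#' @export
length.stem_template <- function(x) nchar(x$bases)

#' Reverse complement of a DNA string
#'
#' @param seq_text A character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(seq_text) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq_text)))
}

complement_dna <- function(seq_text) {
  as.character(Biostrings::complement(Biostrings::DNAStringSet(seq_text)))
}

# character-level complement / reverse complement for plain A/C/G/T hot
# paths (no S4 container construction)
fast_comp <- function(seq_text) chartr("ACGT", "TGCA", seq_text)

fast_revcomp <- function(seq_text) {
  vapply(seq_text, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#'
#' @param seq_text Non-empty string over A/C/G/T.
#' @return `(#G + #C) / length`, in `[0, 1]`.
#' @examples
#' gc_fraction("ATGC")
#' @export
gc_fraction <- function(seq_text) {
  stopifnot(is.character(seq_text), length(seq_text) == 1L)
  seq_text <- toupper(seq_text)
  if (!nzchar(seq_text) || !grepl("^[ACGT]+$", seq_text)) {
    stop("gc_fraction() needs a non-empty A/C/G/T string", call. = FALSE)
  }
  n <- nchar(seq_text)
  (n - nchar(gsub("[GC]", "", seq_text))) / n
}

subseq_top <- function(template, start, end) {
  substr(template$bases, start + 1L, end)
}

#' Load annotated templates from FASTA plus a marks table
#'
#' Reads one or more template sequences from a FASTA file and optionally
#' attaches 5-mC marks from a BED-like five-column TSV
#' (`seq_id`, `start`, `end`, `strand`, `mark`) with `end = start + 1`,
#' strand `+`/`-` mapped to top/bottom. Without a marks file the templates
#' are fully unmethylated.
#'
#' @param fasta_path Path to a FASTA file.
#' @param marks_path Optional path to the marks TSV (no header).
#' @return A named list of [stem_template] objects.
#' @export
load_annotated_template <- function(fasta_path, marks_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  marks <- NULL
  if (!is.null(marks_path)) {
    if (!file.exists(marks_path)) {
      stop(sprintf("marks file not found: %s", marks_path), call. = FALSE)
    }
    marks <- readr::read_tsv(
      marks_path,
      col_names = c("seq_id", "start", "end", "strand", "mark"),
      col_types = "ciicc", comment = "#", progress = FALSE
    )
    if (nrow(marks) > 0 && !all(marks$end == marks$start + 1L)) {
      stop("marks must be single-base intervals (end = start + 1)",
           call. = FALSE)
    }
    unknown <- setdiff(unique(marks$seq_id), names(seqs))
    if (length(unknown) > 0) {
      stop(sprintf("marks reference unknown sequence id(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  out <- lapply(names(seqs), function(id) {
    m <- NULL
    if (!is.null(marks)) {
      mi <- marks[marks$seq_id == id, , drop = FALSE]
      if (nrow(mi) > 0) {
        m <- tibble::tibble(
          pos = as.integer(mi$start),
          strand = ifelse(mi$strand == "+", "top", "bottom"),
          mark = mi$mark
        )
      }
    }
    stem_template(id, as.character(seqs[[id]]), marks = m)
  })
  setNames(out, names(seqs))
}

#' Write annotated templates to FASTA and marks TSV
#'
#' Inverse of [load_annotated_template()]: round-tripping reproduces bases
#' and marks exactly.
#'
#' @param templates A `stem_template` or list of them.
#' @param fasta_path Output FASTA path.
#' @param marks_path Optional output marks TSV path.
#' @return Invisibly, the paths written.
#' @export
write_annotated_template <- function(templates, fasta_path, marks_path = NULL) {
  if (inherits(templates, "stem_template")) templates <- list(templates)
  seqs <- Biostrings::DNAStringSet(vapply(templates, `[[`, "", "bases"))
  names(seqs) <- vapply(templates, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(marks_path)) {
    marks <- purrr::map_dfr(templates, function(t) {
      if (nrow(t$marks) == 0) return(NULL)
      tibble::tibble(
        seq_id = t$id, start = t$marks$pos, end = t$marks$pos + 1L,
        strand = ifelse(t$marks$strand == "top", "+", "-"),
        mark = t$marks$mark
      )
    })
    readr::write_tsv(marks, marks_path, col_names = FALSE)
  }
  invisible(c(fasta_path, marks_path))
}

iupac_ok <- function(pattern) {
  grepl("^[ACGTRYSWKMBDHVN]+$", toupper(pattern))
}

#' Scan a template for a degenerate IUPAC motif with 5-mC requirements
#'
#' Finds every window of the requested strand matching an IUPAC pattern and,
#' if `methyl_required_at` is given, keeps only windows whose flagged pattern
#' positions carry a 5-mC mark on that strand. Bottom-strand scanning
#' operates on the reverse complement; coordinates are always reported in
#' top-strand space (0-based, half-open).
#'
#' @param template A [stem_template].
#' @param pattern IUPAC string, e.g. `"RCGY"`.
#' @param strand `"top"` or `"bottom"`.
#' @param methyl_required_at Integer vector of 0-based pattern indices that
#'   must be 5-methylated on the scanned strand (default none).
#' @return A tibble with columns `seq_id`, `start`, `end`, `strand`.
#' @examples
#' tpl <- stem_template("t", "AACGCTT")
#' iupac_scan(tpl, "RCGY")
#' @export
iupac_scan <- function(template, pattern, strand = "top",
                       methyl_required_at = integer()) {
  stopifnot(inherits(template, "stem_template"))
  pattern <- toupper(pattern)
  if (!nzchar(pattern) || !iupac_ok(pattern)) {
    stop(sprintf("unknown IUPAC code in pattern '%s'", pattern), call. = FALSE)
  }
  strand <- match.arg(strand, c("top", "bottom"))
  methyl_required_at <- as.integer(methyl_required_at)
  if (length(methyl_required_at) > 0 &&
      (min(methyl_required_at) < 0 ||
       max(methyl_required_at) >= nchar(pattern))) {
    stop("methyl_required_at indices must reference pattern positions",
         call. = FALSE)
  }
  L <- nchar(template$bases)
  k <- nchar(pattern)
  subject <- if (strand == "top") template$bases else fast_revcomp(template$bases)
  hits <- Biostrings::matchPattern(
    pattern, Biostrings::DNAString(subject), fixed = FALSE
  )
  if (length(hits) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  st <- Biostrings::start(hits) - 1L  # scanned-strand 0-based starts
  if (strand == "top") {
    start_top <- st
  } else {
    start_top <- L - (st + k)
  }
  keep <- rep(TRUE, length(st))
  if (length(methyl_required_at) > 0) {
    mk <- template$marks[template$marks$strand == strand, , drop = FALSE]
    marked <- mk$pos
    for (i in seq_along(st)) {
      # template coordinate of flagged pattern position j on the scanned strand
      pos <- if (strand == "top") {
        start_top[i] + methyl_required_at
      } else {
        L - 1L - (st[i] + methyl_required_at)
      }
      keep[i] <- all(pos %in% marked)
    }
  }
  out <- tibble::tibble(
    seq_id = template$id,
    start = start_top[keep],
    end = start_top[keep] + k,
    strand = strand
  )
  dplyr::arrange(out, .data$start)
}
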