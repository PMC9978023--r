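# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an assay design into its oligo table
#'
#' @param x A `stem_assay`.
#' @param ... Unused.
#' @return Tibble with one oligo per row (name, role, sequence, Tm, GC,
#'   template coordinates, flags).
#' @export
tidy.stem_assay <- function(x, ...) x$oligos

#' One-row summary of an assay design
#'
#' @param x A `stem_assay`.
#' @param ... Unused.
#' @export
glance.stem_assay <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, template = x$template$id,
    n_oligos = nrow(x$oligos),
    fr_len = nchar(x$tfp$fr$sequence),
    fr_gc = x$tfp$fr$gc,
    blocker_nt_equiv = x$tfp$blocker_nt_equiv,
    expected_amplicon_len = x$expected_amplicon_len
  )
}

#' Per-fragment pathway trace of a simulated reaction
#'
#' @param x A `stem_reaction`.
#' @param ... Unused.
#' @export
tidy.stem_reaction <- function(x, ...) x$trace

#' One-row summary of a simulated reaction
#'
#' @param x A `stem_reaction`.
#' @param ... Unused.
#' @export
glance.stem_reaction <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, amplifiable = x$amplifiable,
    effective_copies = x$effective_copies,
    p3_yield = x$p3_yield, Ct = x$Ct,
    T1 = x$scenario_counts[["T1"]], T2 = x$scenario_counts[["T2"]],
    T3 = x$scenario_counts[["T3"]], T4 = x$scenario_counts[["T4"]]
  )
}

#' Per-reaction table of a dilution series
#'
#' @param x A `stem_dilution`.
#' @param ... Unused.
#' @export
tidy.stem_dilution <- function(x, ...) x$results

#' Regression summary of a dilution series
#'
#' @param x A `stem_dilution`.
#' @param ... Unused.
#' @export
glance.stem_dilution <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          r.squared = NA_real_, n_levels = 0L))
  }
  tibble::as_tibble(x$fit)
}

#' Plot a dilution series (Ct versus log10 input copies)
#'
#' @param object A `stem_dilution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stem_dilution <- function(object, ...) {
  df <- object$results[object$results$amplifiable, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$copies),
                                        y = .data$Ct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 input copies / reaction", y = "Ct") +
    ggplot2::theme_classic()
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_abline(intercept = object$fit$intercept,
                                  slope = object$fit$slope,
                                  linetype = "dashed")
  }
  p
}

#' Plot designed oligo positions along the template
#'
#' @param object A `stem_assay`.
#' @param ... Unused.
#' @return A ggplot showing each positioned oligo as a segment.
#' @export
autoplot.stem_assay <- function(object, ...) {
  df <- object$oligos[!is.na(object$oligos$start), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$name, yend = .data$name,
                                   colour = .data$role)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::geom_vline(xintercept = object$coords$c5, linetype = "dotted") +
    ggplot2::labs(x = sprintf("position on %s (nt)", object$template$id),
                  y = NULL) +
    ggplot2::theme_classic()
}
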