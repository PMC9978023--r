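# Shared fixtures built in code at test time.

# a template with one methylated GlaI site, retrying seeds until the full
# single-site design succeeds (undesignable draws are discarded)
designable_glai_template <- function(seed = 1L, len = 220L, pos = 70L) {
  for (k in 0:200) {
    tpl <- synth_template(len, list(list(enzyme = "GlaI", pos = pos)),
                          seed = seed * 1000L + k,
                          id = sprintf("glai_%d_%d", seed, k))
    assay <- tryCatch(design_single_site_assay(tpl, pos + 1L, "GlaI"),
                      error = function(e) NULL)
    if (!is.null(assay)) return(list(template = tpl, assay = assay))
  }
  stop("no designable template found")
}

# co-methylation template (GlaI 5' site + LpnPI 3' site) with its design
designable_co_template <- function(seed = 1L) {
  for (k in 0:400) {
    tpl <- synth_template(
      300L,
      list(list(enzyme = "GlaI", pos = 80L),
           list(enzyme = "LpnPI", pos = 170L)),
      seed = seed * 1000L + k, id = sprintf("co_%d_%d", seed, k)
    )
    assay <- tryCatch(design_comethylation_assay(tpl, 81L, 171L),
                      error = function(e) NULL)
    if (!is.null(assay)) return(list(template = tpl, assay = assay))
  }
  stop("no designable co-methylation template found")
}

designable_pna_template <- function(seed = 1L) {
  for (k in 0:200) {
    tpl <- synth_template(220L, list(), gc_target = 0.55,
                          seed = seed * 1000L + k,
                          id = sprintf("pna_%d_%d", seed, k))
    ref <- substr(tpl$bases, 101L, 101L)
    vb <- setdiff(c("A", "C", "G", "T"), ref)[1]
    assay <- tryCatch(design_pna_assay(tpl, 100L, vb),
                      error = function(e) NULL)
    if (!is.null(assay)) return(list(template = tpl, assay = assay))
  }
  stop("no designable PNA template found")
}

# tiny independent reverse-complement used when building oracle expectations
fast_revcomp_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# a synthetic fragment row for mechanism-level tests
frag_row <- function(parent, start, end, end5 = "native", end3 = "native",
                     copies = 1L) {
  tibble::tibble(parent = parent, start = as.integer(start),
                 end = as.integer(end), strand = "top",
                 end5_type = end5, end3_type = end3,
                 copies = as.integer(copies))
}
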