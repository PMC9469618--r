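# Packaged reference inputs.

#' The seed list of literature-confirmed CRS-associated cytokines
#'
#' Returns the 20 cytokine symbols used as seed positives for the
#' positive-unlabeled prioritization (interleukins, chemokines, TNF-family
#' members and soluble receptors with confirmed CRS association, e.g. CXCL8,
#' IL17A, TNF, CSF2, ANGPT2).
#'
#' @return Character vector of 20 gene symbols.
#' @export
crs_seed_cytokines <- function() {
  path <- system.file("extdata", "crs_seed_cytokines.txt", package = "crsnet",
                      mustWork = TRUE)
  load_node_list(path)
}
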