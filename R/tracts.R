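#' White matter tract labels
#'
#' Returns the standard set of tract labels used for simulated cohorts: the 42
#' white matter bundles of the TRACULA global probabilistic tractography
#' atlas — 16 bilateral pairs, the middle cerebellar peduncle, the anterior
#' commissure, and 8 corpus callosum subdivisions. Labels are cosmetic: every
#' function in the package accepts arbitrary tract label sets.
#'
#' @param n_tracts Number of labels requested. For `n_tracts <= 42` the first
#'   `n_tracts` atlas labels are returned; beyond 42, generic `Tract<i>` labels
#'   are appended.
#' @return Character vector of length `n_tracts`.
#' @export
#' @examples
#' tracula_tract_labels(5)
tracula_tract_labels <- function(n_tracts = 42L) {
  paired <- c(
    "Acou Rad", "Ant Thal", "Arc Fas", "Cing Bun D", "Cing Bun V",
    "CST", "Ext Cap", "Fornix", "Fron Asl", "ILF", "MLF", "Opt Rad",
    "SLF 1", "SLF 2", "SLF 3", "Unc Fas"
  )
  labels <- c(
    as.vector(t(outer(paired, c("L", "R"), paste))),
    "Mid Cer Ped", "Ant Comm",
    paste("CC", c("Rostrum", "Genu", "Body PF", "Body PM", "Body C",
                  "Body P", "Body T", "Splenium"))
  )
  if (n_tracts <= length(labels)) return(labels[seq_len(n_tracts)])
  c(labels, paste0("Tract", seq.int(length(labels) + 1L, n_tracts)))
}
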