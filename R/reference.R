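#' Reference tables shipped with the package
#'
#' @name reference_data
NULL

#' High-confidence TSS counts for the three solventogenic clostridia
#'
#' Per-strain counts of TSSs called at the high-confidence threshold
#' (25 normalized RPM) in the Capp-Switch study of the three model
#' solventogenic strains (C. beijerinckii DSM 6423 and NCIMB 8052,
#' C. acetobutylicum ATCC 824).  Shipped as a reference point for
#' comparing runs on real data; the counts sum to the study-wide total of
#' 12,114 mapped TSSs.
#'
#' @return data.frame `strain`, `genome_accession`, `tss_high_confidence`.
#' @export
strain_tss_counts <- function() {
  read.table(system.file("extdata", "strain_tss_counts.tsv",
                         package = "capptss"),
             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Example sigma-factor motif list
#'
#' A small set of literature-style consensus motifs (IUPAC) for the
#' housekeeping and alternative sigma factors and the Spo0A box, in the
#' schema expected by [read_motifs()].  Real analyses should supply their
#' own curated list.
#'
#' @return motif data.frame `name`, `iupac`, `max_indels`.
#' @export
example_sigma_motifs <- function() {
  read_motifs(system.file("extdata", "sigma_motifs.tsv",
                          package = "capptss"))
}
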