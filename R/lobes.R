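#' Lobe lookup for Desikan-Killiany region labels
#'
#' Maps a cortical (or mesial temporal) Desikan-Killiany atlas label to one of
#' six lobe-level categories used by the virtual-resection stopping rule.
#' The lookup is total over the label vocabulary the synthetic generator
#' emits; unknown labels are an error, never a silent default.
#'
#' @param region character vector of Desikan-Killiany region labels
#'   (lower-case, no hemisphere prefix, e.g. `"superiortemporal"`).
#' @return character vector with levels
#'   `frontal, temporal, parietal, occipital, insular, cingulate`.
#' @examples
#' region_to_lobe(c("insula", "precentral", "cuneus"))
#' @export
region_to_lobe <- function(region) {
  stopifnot(is.character(region))
  out <- unname(.dk_lobe_table[region])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown Desikan-Killiany region label(s): ",
         paste(unique(region[bad]), collapse = ", "))
  }
  out
}

#' @rdname region_to_lobe
#' @format NULL
#' @export
dk_regions <- function() names(.dk_lobe_table)

.dk_lobe_table <- c(
  superiorfrontal = "frontal", rostralmiddlefrontal = "frontal",
  caudalmiddlefrontal = "frontal", parsopercularis = "frontal",
  parstriangularis = "frontal", parsorbitalis = "frontal",
  lateralorbitofrontal = "frontal", medialorbitofrontal = "frontal",
  precentral = "frontal", paracentral = "frontal", frontalpole = "frontal",
  superiortemporal = "temporal", middletemporal = "temporal",
  inferiortemporal = "temporal", fusiform = "temporal",
  transversetemporal = "temporal", entorhinal = "temporal",
  temporalpole = "temporal", parahippocampal = "temporal",
  bankssts = "temporal", hippocampus = "temporal", amygdala = "temporal",
  superiorparietal = "parietal", inferiorparietal = "parietal",
  supramarginal = "parietal", postcentral = "parietal",
  precuneus = "parietal",
  lateraloccipital = "occipital", lingual = "occipital",
  cuneus = "occipital", pericalcarine = "occipital",
  insula = "insular",
  rostralanteriorcingulate = "cingulate", caudalanteriorcingulate = "cingulate",
  posteriorcingulate = "cingulate", isthmuscingulate = "cingulate"
)
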