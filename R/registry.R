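# The 82-region parcellation registry: 34 Desikan-Killiany cortical labels
# per hemisphere (thickness, mm) plus 7 subcortical structures per
# hemisphere (volume, mm^3), in a frozen deterministic order.

# DK cortical labels in FreeSurfer aparc.stats row order (34 per hemisphere)
DK_CORTICAL <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

# anatomical name -> FreeSurfer aseg StructName stem
SUBCORTICAL_MAP <- c(
  thalamus    = "Thalamus-Proper",
  caudate     = "Caudate",
  putamen     = "Putamen",
  pallidum    = "Pallidum",
  hippocampus = "Hippocampus",
  amygdala    = "Amygdala",
  accumbens   = "Accumbens-area")

#' Build the Desikan-Killiany 82-region registry
#'
#' Returns the fixed parcellation used throughout the package: 68 cortical
#' regions (34 Desikan-Killiany labels x 2 hemispheres, measured as mean
#' cortical thickness in mm) and 14 subcortical regions (thalamus, caudate,
#' putamen, pallidum, hippocampus, amygdala, accumbens x 2 hemispheres,
#' measured as volume in mm^3). Region order is frozen as: left cortical,
#' right cortical, left subcortical, right subcortical.
#'
#' @return a data.frame of class `roi_registry` with columns `roi_id`
#'   (0-based index), `name` (unique column label, e.g. `lh_bankssts` or
#'   `Left-Thalamus-Proper`), `hemisphere` (`left`/`right`), `kind`
#'   (`cortical`/`subcortical`) and `measure` (`thickness-mm`/`volume-mm3`).
#' @examples
#' reg <- build_dk_registry()
#' table(reg$kind)
#' @export
build_dk_registry <- function() {
  cort <- function(hemi, prefix) {
    data.frame(
      name = paste0(prefix, "_", DK_CORTICAL),
      hemisphere = hemi, kind = "cortical", measure = "thickness-mm",
      atlas_label = DK_CORTICAL, stringsAsFactors = FALSE)
  }
  subc <- function(hemi, prefix) {
    data.frame(
      name = paste0(prefix, "-", unname(SUBCORTICAL_MAP)),
      hemisphere = hemi, kind = "subcortical", measure = "volume-mm3",
      atlas_label = names(SUBCORTICAL_MAP), stringsAsFactors = FALSE)
  }
  reg <- rbind(cort("left", "lh"), cort("right", "rh"),
               subc("left", "Left"), subc("right", "Right"))
  reg <- cbind(roi_id = seq_len(nrow(reg)) - 1L, reg)
  rownames(reg) <- NULL
  class(reg) <- c("roi_registry", "data.frame")
  reg
}

#' @export
print.roi_registry <- function(x, ...) {
  cat("ROI registry:", nrow(x), "regions (",
      sum(x$kind == "cortical"), "cortical,",
      sum(x$kind == "subcortical"), "subcortical )\n")
  invisible(x)
}

# names of the covariate/clinical columns a flat morphometry table carries
MORPHOMETRY_META_COLS <- c("subject_id", "group", "timepoint", "age", "sex",
                           "icv", "vas_pre", "vas_post", "pain_duration")
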