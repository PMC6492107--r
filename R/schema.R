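#' Desikan-Killiany cortical region names
#'
#' The 34 gyral-based cortical parcels of the Desikan-Killiany atlas, in the
#' order used by the FreeSurfer `aparcstats2table` export.
#'
#' @return Character vector of 34 region names.
#' @export
dk_region_names <- function() {
  c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula"
  )
}

# 36 segmentation volumes: 14 bilateral pairs + 8 midline structures, named as
# in the FreeSurfer asegstats2table export. The volumetric set in aseg exports
# varies across FreeSurfer versions, so this default is a documented choice and
# can be overridden with read_schema().
aseg_bilateral <- c(
  "Lateral-Ventricle", "Inf-Lat-Vent", "Cerebellum-White-Matter",
  "Cerebellum-Cortex", "Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
  "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC", "vessel",
  "choroid-plexus"
)
aseg_midline <- c(
  "3rd-Ventricle", "4th-Ventricle", "Brain-Stem", "CSF",
  "CC_Posterior", "CC_Mid_Posterior", "CC_Central", "CC_Anterior"
)

#' Default 104-feature morphometry schema
#'
#' The canonical feature set: cortical thickness of the 68 Desikan-Killiany
#' subregions (34 per hemisphere, in mm) followed by the volume of 36
#' neuroanatomical structures from the whole-brain segmentation (in mm^3),
#' for a total of 104 regional features. Thickness features are named
#' `lh_<region>_thickness` / `rh_<region>_thickness`; volumes are named
#' `Left-<structure>` / `Right-<structure>` or by their midline name,
#' following the FreeSurfer table exports.
#'
#' @return A `feature_schema`: a data frame with columns `name`, `kind`
#'   (`"thickness"` or `"volume"`), `hemisphere` (`"left"`, `"right"`,
#'   `"midline"`) and `atlas` (`"desikan_killiany"` or `"aseg"`).
#' @examples
#' sch <- default_schema()
#' nrow(sch)                      # 104
#' table(sch$kind)                # 68 thickness, 36 volume
#' @export
default_schema <- function() {
  dk <- dk_region_names()
  thick <- data.frame(
    name = c(paste0("lh_", dk, "_thickness"), paste0("rh_", dk, "_thickness")),
    kind = "thickness",
    hemisphere = rep(c("left", "right"), each = length(dk)),
    atlas = "desikan_killiany",
    stringsAsFactors = FALSE
  )
  vol <- data.frame(
    name = c(paste0("Left-", aseg_bilateral), paste0("Right-", aseg_bilateral),
             aseg_midline),
    kind = "volume",
    hemisphere = c(rep(c("left", "right"), each = length(aseg_bilateral)),
                   rep("midline", length(aseg_midline))),
    atlas = "aseg",
    stringsAsFactors = FALSE
  )
  as_feature_schema(rbind(thick, vol))
}

#' Validate a feature schema
#'
#' @param x Data frame with columns `name`, `kind`, `hemisphere`, `atlas`.
#' @return The validated schema with class `feature_schema`.
#' @export
as_feature_schema <- function(x) {
  required <- c("name", "kind", "hemisphere", "atlas")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("schema is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(x$name)) {
    stop("schema feature names must be unique")
  }
  if (!all(x$kind %in% c("thickness", "volume"))) {
    stop("schema kind must be 'thickness' or 'volume'")
  }
  if (!all(x$hemisphere %in% c("left", "right", "midline"))) {
    stop("schema hemisphere must be 'left', 'right' or 'midline'")
  }
  x <- x[required]
  rownames(x) <- NULL
  class(x) <- c("feature_schema", "data.frame")
  x
}

#' Read a feature schema from a CSV file
#'
#' Allows the default 104-feature schema to be overridden, e.g. when a
#' different segmentation volume set is exported.
#'
#' @param path CSV file with columns `name`, `kind`, `hemisphere`, `atlas`.
#' @return A `feature_schema`.
#' @export
read_schema <- function(path) {
  as_feature_schema(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Write a feature schema to CSV
#' @param schema A `feature_schema`.
#' @param path Output CSV path.
#' @export
write_schema <- function(schema, path) {
  utils::write.csv(as.data.frame(schema), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d features: %d thickness, %d volume\n",
              nrow(x), sum(x$kind == "thickness"), sum(x$kind == "volume")))
  invisible(x)
}
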