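#' Cortical parcellation atlas
#'
#' A labelled partition of the reference volume into named structures.
#' Four parcellations are used for the cortical location profile, with
#' fixed structure counts: the structural atlas of the reference template
#' (15), the Harvard-Oxford cortical atlas (48), and the 7- and 17-network
#' functional parcellations (7 and 17) -- 87 structures in total.
#'
#' @param labels non-negative integer array (0 = background).
#' @param names named character vector mapping label (as name) to
#'   structure name, e.g. `c("1" = "Frontal_Lobe_left", ...)`.
#' @param atlas_id one of `"MNI-structural"`, `"Harvard-Oxford"`,
#'   `"Schaefer7"`, `"Schaefer17"`.
#' @param geometry a `volume_geometry`.
#' @return an object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, names, atlas_id, geometry) {
  counts <- c("MNI-structural" = 15L, "Harvard-Oxford" = 48L,
              "Schaefer7" = 7L, "Schaefer17" = 17L)
  if (!atlas_id %in% base::names(counts))
    stop("unknown atlas_id: ", atlas_id)
  labels <- array(as.integer(labels), dim = geometry$shape)
  if (any(labels < 0L)) stop("parcellation labels must be non-negative")
  if (length(names) != counts[[atlas_id]])
    stop(sprintf("atlas '%s' must have %d structures, got %d",
                 atlas_id, counts[[atlas_id]], length(names)))
  used <- unique(labels[labels > 0L])
  if (!all(as.character(used) %in% base::names(names)))
    stop("parcellation contains labels missing from the name table")
  structure(list(geometry = geometry, labels = labels, names = names,
                 atlas_id = atlas_id),
            class = "parcellation_atlas")
}

#' Probabilistic subcortical atlas
#'
#' 68 named probability volumes (one per white-matter structure, most
#' disambiguated between left and right hemisphere); stripping the
#' laterality designation yields 40 unique base names. Structure masks are
#' obtained by thresholding at `threshold` (inclusive), 0.5 by default.
#'
#' @param structures named list of 68 probability arrays in [0, 1].
#' @param geometry a `volume_geometry`.
#' @param threshold probability threshold for binarization (default 0.5).
#' @return an object of class `probabilistic_atlas`.
#' @export
probabilistic_atlas <- function(structures, geometry, threshold = 0.5) {
  if (length(structures) != 68L)
    stop("subcortical atlas must have 68 structures, got ", length(structures))
  nm <- names(structures)
  if (is.null(nm) || anyDuplicated(nm))
    stop("subcortical structures must have unique names")
  base <- unique(strip_laterality(nm))
  if (length(base) != 40L)
    stop("subcortical structure names must reduce to 40 base names, got ",
         length(base))
  structures <- lapply(structures, function(s) {
    s <- array(as.numeric(s), dim = geometry$shape)
    if (any(!is.finite(s)) || any(s < 0 | s > 1))
      stop("structure probabilities must lie in [0, 1]")
    s
  })
  structure(list(geometry = geometry, structures = structures,
                 threshold = threshold),
            class = "probabilistic_atlas")
}

#' Strip left/right designation from structure names
#'
#' Removes a leading or trailing `left`/`right` token (underscore-, space-
#' or hyphen-separated, case-insensitive), giving the laterality-agnostic
#' base name.
#'
#' @param x character vector of structure names.
#' @return character vector of base names.
#' @export
strip_laterality <- function(x) {
  out <- gsub("(^|[ _-])(left|right)([ _-]|$)", "\\1", x, ignore.case = TRUE)
  gsub("[ _-]+$", "", gsub("^[ _-]+", "", out))
}

#' Hemisphere laterality mask
#'
#' A total partition of the reference lattice into left and right
#' hemispheres, split at the mid-sagittal world plane x = 0. Voxel centres
#' exactly on the plane are assigned to the left hemisphere.
#'
#' @param left logical array, TRUE for left-hemisphere voxels.
#' @param geometry a `volume_geometry`.
#' @return an object of class `hemisphere_mask`.
#' @export
hemisphere_mask <- function(left, geometry) {
  left <- array(as.logical(left), dim = geometry$shape)
  if (any(is.na(left))) stop("hemisphere assignment must be total")
  structure(list(geometry = geometry, left = left), class = "hemisphere_mask")
}

#' Build the hemisphere mask from a geometry's world frame
#' @param geometry a `volume_geometry`.
#' @return a `hemisphere_mask` split at world x = 0 (x <= 0 is left).
#' @export
hemisphere_from_geometry <- function(geometry) {
  shp <- geometry$shape
  idx <- as.matrix(expand.grid(x = seq_len(shp[1]) - 1,
                               y = seq_len(shp[2]) - 1,
                               z = seq_len(shp[3]) - 1))
  wx <- voxel_to_world(geometry, idx)[, 1]
  hemisphere_mask(array(wx <= 0, dim = shp), geometry)
}

#' Per-hemisphere resection probability heat maps
#'
#' Population-derived probability, per voxel, that tissue at this location
#' is surgically removed; one map per hemisphere.
#'
#' @param left_map,right_map probability arrays in [0, 1].
#' @param geometry a `volume_geometry`.
#' @return an object of class `resection_heatmap`.
#' @export
resection_heatmap <- function(left_map, right_map, geometry) {
  chk <- function(m) {
    m <- array(as.numeric(m), dim = geometry$shape)
    if (any(!is.finite(m)) || any(m < 0 | m > 1))
      stop("heat-map probabilities must lie in [0, 1]")
    m
  }
  structure(list(geometry = geometry, left_map = chk(left_map),
                 right_map = chk(right_map)),
            class = "resection_heatmap")
}

CORTICAL_ATLAS_IDS <- c("MNI-structural", "Harvard-Oxford",
                        "Schaefer7", "Schaefer17")

#' Atlas bundle
#'
#' All reference-space volumes needed by the feature computation:
#' hemisphere mask, the four cortical parcellations, the probabilistic
#' subcortical atlas, and the per-hemisphere resection heat maps, all on
#' one geometry.
#'
#' @param hemisphere a `hemisphere_mask`.
#' @param cortical named list of the four `parcellation_atlas` objects
#'   (names = atlas ids).
#' @param subcortical a `probabilistic_atlas`.
#' @param heatmap a `resection_heatmap`.
#' @return an object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(hemisphere, cortical, subcortical, heatmap) {
  if (!setequal(names(cortical), CORTICAL_ATLAS_IDS))
    stop("cortical atlases must be exactly: ",
         paste(CORTICAL_ATLAS_IDS, collapse = ", "))
  cortical <- cortical[CORTICAL_ATLAS_IDS]
  geom <- hemisphere$geometry
  for (a in cortical)
    if (!same_geometry(a$geometry, geom)) stop("geometry mismatch in bundle")
  if (!same_geometry(subcortical$geometry, geom) ||
      !same_geometry(heatmap$geometry, geom))
    stop("geometry mismatch in bundle")
  structure(list(geometry = geom, hemisphere = hemisphere,
                 cortical = cortical, subcortical = subcortical,
                 heatmap = heatmap),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat("<atlas_bundle>\n")
  print(x$geometry)
  cat(sprintf("  cortical structures: %s (total %d)\n",
              paste(vapply(x$cortical, function(a) length(a$names), 1L),
                    collapse = " + "),
              sum(vapply(x$cortical, function(a) length(a$names), 1L))))
  cat(sprintf("  subcortical structures: %d (%d base names)\n",
              length(x$subcortical$structures),
              length(unique(strip_laterality(names(x$subcortical$structures))))))
  invisible(x)
}

#' Threshold one structure of a probabilistic atlas
#'
#' Voxels with probability greater than or equal to the atlas threshold
#' become foreground.
#'
#' @param atlas a `probabilistic_atlas`.
#' @param structure structure name.
#' @return a `binary_mask`.
#' @export
threshold_probabilistic <- function(atlas, structure) {
  if (!structure %in% names(atlas$structures))
    stop("unknown subcortical structure: ", structure)
  binary_mask(atlas$structures[[structure]] >= atlas$threshold,
              atlas$geometry)
}

# ---- bundle directory I/O --------------------------------------------------
#
# Layout (all members share one geometry):
#   manifest.txt                          key<TAB>filename pairs
#   hemisphere.nii.gz                     uint8, 1 = left, 2 = right
#   cortical_<id>.nii.gz                  int labels, 0 = background
#   cortical_<id>_names.txt               label<TAB>name
#   subcortical.nii.gz                    4D float, one volume per structure
#   subcortical_names.txt                 index<TAB>name
#   heatmap_left.nii.gz, heatmap_right.nii.gz   float in [0,1]

read_name_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "")
  stats::setNames(df[[2]], df[[1]])
}

write_name_table <- function(names, path) {
  utils::write.table(data.frame(id = base::names(names), name = names),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write an atlas bundle to a directory
#' @param bundle an `atlas_bundle`.
#' @param directory output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  geom <- bundle$geometry
  manifest <- character(0)
  add <- function(key, file) manifest <<- c(manifest, paste(key, file, sep = "\t"))

  hemi <- array(ifelse(bundle$hemisphere$left, 1L, 2L), dim = geom$shape)
  write_nifti_array(hemi, geom, file.path(directory, "hemisphere.nii.gz"), "uint8")
  add("hemisphere", "hemisphere.nii.gz")

  for (id in names(bundle$cortical)) {
    a <- bundle$cortical[[id]]
    vol <- sprintf("cortical_%s.nii.gz", id)
    tab <- sprintf("cortical_%s_names.txt", id)
    write_nifti_array(a$labels, geom, file.path(directory, vol), "int16")
    write_name_table(a$names, file.path(directory, tab))
    add(sprintf("cortical.%s.volume", id), vol)
    add(sprintf("cortical.%s.names", id), tab)
  }

  sub <- bundle$subcortical
  arr4 <- array(0, dim = c(geom$shape, length(sub$structures)))
  for (i in seq_along(sub$structures)) arr4[, , , i] <- sub$structures[[i]]
  write_nifti_array(arr4, geom, file.path(directory, "subcortical.nii.gz"), "float")
  write_name_table(stats::setNames(names(sub$structures),
                                   seq_along(sub$structures)),
                   file.path(directory, "subcortical_names.txt"))
  add("subcortical.volume", "subcortical.nii.gz")
  add("subcortical.names", "subcortical_names.txt")

  write_nifti_array(bundle$heatmap$left_map, geom,
                    file.path(directory, "heatmap_left.nii.gz"), "float")
  write_nifti_array(bundle$heatmap$right_map, geom,
                    file.path(directory, "heatmap_right.nii.gz"), "float")
  add("heatmap.left", "heatmap_left.nii.gz")
  add("heatmap.right", "heatmap_right.nii.gz")

  writeLines(manifest, file.path(directory, "manifest.txt"))
  invisible(directory)
}

#' Load an atlas bundle from a directory
#'
#' Reads the manifest and all member volumes, validating geometry
#' consistency and the per-atlas structure counts.
#'
#' @param directory bundle directory containing `manifest.txt`.
#' @return an `atlas_bundle`.
#' @export
load_bundle <- function(directory) {
  mf_path <- file.path(directory, "manifest.txt")
  if (!file.exists(mf_path)) stop("missing bundle manifest: ", mf_path)
  lines <- readLines(mf_path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  manifest <- stats::setNames(vapply(parts, `[`, "", 2),
                              vapply(parts, `[`, "", 1))
  need <- function(key) {
    if (!key %in% names(manifest)) stop("bundle manifest missing entry: ", key)
    p <- file.path(directory, manifest[[key]])
    if (!file.exists(p)) stop("bundle member missing on disk: ", p)
    p
  }
  read_img <- function(path) RNifti::readNifti(path)

  hemi_img <- read_img(need("hemisphere"))
  geom <- geometry_from_nifti(hemi_img)
  hemi_arr <- as.array(hemi_img)
  if (!all(hemi_arr %in% c(1, 2)))
    stop("hemisphere volume must contain only 1 (left) and 2 (right)")
  hemisphere <- hemisphere_mask(hemi_arr == 1, geom)

  check_geom <- function(img, what) {
    g <- geometry_from_nifti(img)
    if (!same_geometry(g, geom, tol = 1e-4))
      stop("geometry mismatch in bundle member: ", what)
  }

  cortical <- lapply(CORTICAL_ATLAS_IDS, function(id) {
    img <- read_img(need(sprintf("cortical.%s.volume", id)))
    check_geom(img, id)
    nm <- read_name_table(need(sprintf("cortical.%s.names", id)))
    parcellation_atlas(as.array(img), nm, id, geom)
  })
  names(cortical) <- CORTICAL_ATLAS_IDS

  sub_img <- read_img(need("subcortical.volume"))
  arr4 <- as.array(sub_img)
  if (length(dim(arr4)) != 4L)
    stop("subcortical atlas must be a 4D volume (one per structure)")
  check_geom(sub_img, "subcortical")
  sub_names <- read_name_table(need("subcortical.names"))
  if (dim(arr4)[4] != length(sub_names))
    stop("subcortical name table does not match the number of volumes")
  structures <- stats::setNames(
    lapply(seq_len(dim(arr4)[4]), function(i) arr4[, , , i]),
    unname(sub_names))
  subcortical <- probabilistic_atlas(structures, geom)

  hl <- read_img(need("heatmap.left")); check_geom(hl, "heatmap.left")
  hr <- read_img(need("heatmap.right")); check_geom(hr, "heatmap.right")
  heatmap <- resection_heatmap(as.array(hl), as.array(hr), geom)

  atlas_bundle(hemisphere, cortical, subcortical, heatmap)
}
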