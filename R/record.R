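#' Assemble the standardized tumor feature record
#'
#' Runs the full feature computation on a refined tumor mask in the
#' reference (atlas) space and assembles the 233-parameter record:
#' volume in patient and reference space (2), laterality (3),
#' multifocality (3), expected resectability (2), cortical location
#' profile (87), and subcortical overlap and distance profiles (2 x 68).
#' All features except the patient-space volume are expressed in the
#' reference space.
#'
#' If the reference-space mask is empty (e.g. everything was removed by
#' refinement), an explicit "no tumor" record is returned rather than a
#' row of silent zeros; `is_empty_record()` detects it.
#'
#' @param mni_mask refined `binary_mask` in the bundle's geometry.
#' @param bundle an `atlas_bundle`.
#' @param patient_mask `binary_mask` in native patient space (defaults to
#'   `mni_mask` when the native mask is unavailable).
#' @param patient_id identifier carried into reports.
#' @return an object of class `tumor_features`.
#' @export
tumor_features <- function(mni_mask, bundle, patient_mask = mni_mask,
                           patient_id = "patient") {
  if (!same_geometry(mni_mask$geometry, bundle$geometry))
    stop("'mni_mask' must be in the bundle's geometry")
  if (!any(mni_mask$voxels)) {
    return(structure(list(patient_id = patient_id, empty = TRUE),
                     class = "tumor_features"))
  }
  lat <- compute_laterality(mni_mask, bundle$hemisphere)
  mf <- compute_multifocality(mni_mask)
  res <- compute_resectability(mni_mask, bundle$heatmap, lat)
  cort <- cortical_profile(mni_mask, bundle$cortical)
  sub <- subcortical_profile(mni_mask, bundle$subcortical)
  structure(list(
    patient_id = patient_id,
    empty = FALSE,
    volume = list(patient_space_ml = compute_volume(patient_mask),
                  mni_space_ml = compute_volume(mni_mask)),
    laterality = lat,
    multifocality = mf[c("multifocal", "focus_count", "satellite_distance_mm")],
    foci = mf$foci,
    resectability = res[c("expected_residual_ml", "resectability_index")],
    cortical = cort,
    subcortical = sub
  ), class = "tumor_features")
}

#' Is this a "no tumor" record?
#' @param record a `tumor_features` object.
#' @return logical.
#' @export
is_empty_record <- function(record) isTRUE(record$empty)

#' Flatten a feature record to the 233 named values
#'
#' Stable registry ordering: volume (2), laterality (3), multifocality
#' (3), resectability (2), cortical profile (87), subcortical overlaps
#' (68), subcortical distances (68). Booleans are encoded as 1/0.
#'
#' @param record a non-empty `tumor_features` object.
#' @return named numeric vector of length 233.
#' @export
feature_vector <- function(record) {
  if (is_empty_record(record))
    stop("cannot flatten a 'no tumor' record")
  c(stats::setNames(
      c(record$volume$patient_space_ml, record$volume$mni_space_ml),
      c("volume.patient_space_ml", "volume.mni_space_ml")),
    stats::setNames(
      c(record$laterality$left_pct, record$laterality$right_pct,
        as.numeric(record$laterality$midline_crossing)),
      c("laterality.left_pct", "laterality.right_pct",
        "laterality.midline_crossing")),
    stats::setNames(
      c(as.numeric(record$multifocality$multifocal),
        record$multifocality$focus_count,
        record$multifocality$satellite_distance_mm),
      c("multifocality.multifocal", "multifocality.focus_count",
        "multifocality.satellite_distance_mm")),
    stats::setNames(
      c(record$resectability$expected_residual_ml,
        record$resectability$resectability_index),
      c("resectability.expected_residual_ml",
        "resectability.resectability_index")),
    record$cortical,
    stats::setNames(record$subcortical$overlap_pct,
                    paste0("subcortical_overlap.BCB.",
                           names(record$subcortical$overlap_pct))),
    stats::setNames(record$subcortical$distance_mm,
                    paste0("subcortical_distance.BCB.",
                           names(record$subcortical$distance_mm))))
}

#' @export
as.data.frame.tumor_features <- function(x, ...) {
  v <- feature_vector(x)
  df <- as.data.frame(as.list(v), check.names = FALSE)
  cbind(data.frame(patient_id = x$patient_id), df)
}

#' @export
print.tumor_features <- function(x, ...) {
  cat("<tumor_features>", x$patient_id, "\n")
  if (is_empty_record(x)) {
    cat("  no tumor detected after refinement\n")
    return(invisible(x))
  }
  cat(sprintf("  volume: %.2f mL (patient), %.2f mL (reference)\n",
              x$volume$patient_space_ml, x$volume$mni_space_ml))
  cat(sprintf("  laterality: %.1f%% left / %.1f%% right, midline crossing: %s\n",
              x$laterality$left_pct, x$laterality$right_pct,
              x$laterality$midline_crossing))
  cat(sprintf("  multifocality: %s (%d focus/foci, satellite distance %.1f mm)\n",
              x$multifocality$multifocal, x$multifocality$focus_count,
              x$multifocality$satellite_distance_mm))
  cat(sprintf("  resectability index: %.3f (expected residual %.2f mL)\n",
              x$resectability$resectability_index,
              x$resectability$expected_residual_ml))
  cat(sprintf("  cortical structures overlapped: %d of %d\n",
              sum(x$cortical > 0), length(x$cortical)))
  cat(sprintf("  subcortical structures overlapped: %d of %d\n",
              sum(x$subcortical$overlap_pct > 0),
              length(x$subcortical$overlap_pct)))
  invisible(x)
}

#' @export
summary.tumor_features <- function(object, ...) {
  print(object)
  if (!is_empty_record(object)) {
    top <- sort(object$cortical[object$cortical > 0], decreasing = TRUE)
    if (length(top)) {
      cat("  top cortical overlaps:\n")
      for (i in seq_len(min(5L, length(top))))
        cat(sprintf("    %-50s %6.2f%%\n", names(top)[i], top[i]))
    }
  }
  invisible(object)
}
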