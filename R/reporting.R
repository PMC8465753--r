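#' Write the standardized text report
#'
#' Renders a `tumor_features` record as a human-readable report, grouped
#' by feature category. Percentages, volumes and distances are printed
#' with two decimals. In the cortical and subcortical sections only
#' structures with a non-null overlap percentage are listed, to avoid
#' visual overload; the CSV output carries the complete set.
#'
#' @param record a `tumor_features` object.
#' @param path output path (.txt); the rendered lines are also returned.
#' @param timestamp header timestamp; defaults to the current time.
#' @return the rendered lines, invisibly.
#' @export
write_text_report <- function(record, path = NULL,
                              timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")) {
  version <- as.character(utils::packageVersion("gliomask"))
  lines <- c(
    "Standardized tumor feature report",
    sprintf("Patient:   %s", record$patient_id),
    sprintf("Generated: %s", timestamp),
    sprintf("Software:  gliomask %s", version),
    strrep("-", 60))
  if (is_empty_record(record)) {
    lines <- c(lines, "", "No tumor detected after mask refinement.")
  } else {
    fmt <- function(x) sprintf("%.2f", x)
    lines <- c(
      lines,
      "",
      "Volume",
      sprintf("  Patient space:   %s mL", fmt(record$volume$patient_space_ml)),
      sprintf("  Reference space: %s mL", fmt(record$volume$mni_space_ml)),
      "",
      "Laterality",
      sprintf("  Left hemisphere:  %s %%", fmt(record$laterality$left_pct)),
      sprintf("  Right hemisphere: %s %%", fmt(record$laterality$right_pct)),
      sprintf("  Midline crossing: %s",
              if (record$laterality$midline_crossing) "True" else "False"),
      "",
      "Multifocality",
      sprintf("  Multifocal:         %s",
              if (record$multifocality$multifocal) "True" else "False"),
      sprintf("  Number of foci:     %d", record$multifocality$focus_count),
      sprintf("  Satellite distance: %s mm",
              fmt(record$multifocality$satellite_distance_mm)),
      "",
      "Resectability",
      sprintf("  Expected residual volume: %s mL",
              fmt(record$resectability$expected_residual_ml)),
      sprintf("  Resectability index:      %s",
              fmt(record$resectability$resectability_index)),
      "",
      "Cortical structure profile (overlap > 0 only)")
    cort <- record$cortical[record$cortical > 0]
    lines <- c(lines, if (length(cort))
      sprintf("  %-52s %6s %%", names(cort), fmt(cort)) else character(0))
    lines <- c(lines, "", "Subcortical structure profile (overlap > 0 only)")
    sub <- record$subcortical$overlap_pct[record$subcortical$overlap_pct > 0]
    lines <- c(lines, if (length(sub))
      sprintf("  %-52s %6s %%", names(sub), fmt(sub)) else character(0))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write feature records as CSV
#'
#' One row per patient, one column per feature plus the patient
#' identifier: 234 columns. All 233 features are always present (no
#' non-null filtering, so the file supports follow-up statistical
#' studies). Booleans are serialized as 1/0; the decimal separator is "."
#' and the delimiter ",". "No tumor" records yield a row of NA features.
#'
#' @param records a `tumor_features` object or a list of them.
#' @param path output path (.csv).
#' @param registry optional character vector of the 233 feature names
#'   (see [feature_names()]), required when no non-empty record is
#'   available to derive it from.
#' @return the written data frame, invisibly.
#' @export
write_feature_csv <- function(records, path, registry = NULL) {
  if (inherits(records, "tumor_features")) records <- list(records)
  cols <- registry
  for (r in records)
    if (!is_empty_record(r)) {
      derived <- names(feature_vector(r))
      if (is.null(cols)) cols <- derived
      else if (!identical(cols, derived))
        stop("records do not match the supplied feature registry")
      break
    }
  if (is.null(cols))
    stop("no non-empty record available; supply 'registry' (see feature_names)")
  rows <- lapply(records, function(r) {
    if (is_empty_record(r)) {
      v <- stats::setNames(rep(NA_real_, length(cols)), cols)
    } else {
      v <- feature_vector(r)
      if (!identical(names(v), cols))
        stop("records do not share the same feature registry")
    }
    cbind(data.frame(patient_id = r$patient_id),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- stats::setNames(
      as.data.frame(matrix(numeric(0), ncol = length(cols) + 1)),
      c("patient_id", cols))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Feature registry names for an atlas bundle
#'
#' The 233 feature names, in the stable registry order used by
#' [feature_vector()] and [write_feature_csv()], derived from the
#' bundle's structure name tables.
#'
#' @param bundle an `atlas_bundle`.
#' @return character vector of length 233.
#' @export
feature_names <- function(bundle) {
  cort <- unlist(lapply(names(bundle$cortical), function(id)
    sprintf("cortical.%s.%s", id, unname(bundle$cortical[[id]]$names))),
    use.names = FALSE)
  sub <- names(bundle$subcortical$structures)
  c("volume.patient_space_ml", "volume.mni_space_ml",
    "laterality.left_pct", "laterality.right_pct",
    "laterality.midline_crossing",
    "multifocality.multifocal", "multifocality.focus_count",
    "multifocality.satellite_distance_mm",
    "resectability.expected_residual_ml",
    "resectability.resectability_index",
    cort,
    paste0("subcortical_overlap.BCB.", sub),
    paste0("subcortical_distance.BCB.", sub))
}

#' Write the report side-product volumes
#'
#' NIfTI side products for visual assessment: the refined tumor mask in
#' patient space and in the reference space.
#'
#' @param patient_mask,mni_mask `binary_mask` objects.
#' @param directory output directory.
#' @return named vector of the written paths, invisibly.
#' @export
write_report_volumes <- function(patient_mask, mni_mask, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patient = file.path(directory, "tumor_mask_patient.nii.gz"),
             mni = file.path(directory, "tumor_mask_mni.nii.gz"))
  write_volume(patient_mask, paths[["patient"]])
  write_volume(mni_mask, paths[["mni"]])
  invisible(paths)
}
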