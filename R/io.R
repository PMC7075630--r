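#' Read a PET volume from disk
#'
#' Reads a NIfTI-1 volume (values assumed already in kBq/ml) with voxel
#' spacing taken from the header. DICOM series are not supported by this
#' build and are rejected with an informative error; convert to NIfTI first.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param format `"auto"`, `"nifti"` or `"dicom_series"`.
#' @return A [pet_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "dicom_series" ||
      (format == "auto" && dir.exists(path)))
    stop("DICOM series reading is not supported; convert the series to ",
         "NIfTI-1 and pass the .nii file")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3) stop("expected a 3-D volume, got ",
                                   length(dim(vals)), " dimensions")
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("header is missing positive voxel spacing (pixdim)")
  pet_volume(vals, spacing)
}

#' Write a VOI or volume as NIfTI-1
#'
#' The voxel spacing is written into the header, so a synthetic VOI written
#' here and re-read with [read_volume()] round-trips exactly; synthetic and
#' real data thereby share one entry point.
#'
#' @param x A [cuboid_voi()] or [pet_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "cuboid_voi") || inherits(x, "pet_volume"))
    x$values else stop("'x' must be a cuboid_voi or pet_volume")
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

report_schema_version <- "1.0"

#' Write a study report to JSON and tidy CSV
#'
#' Writes `<stem>.json` (schema-stamped report table, island intervals,
#' Lilliefors crossings and the config) and `<stem>_curves.csv` (one row per
#' smoothed exposure station per feature curve). A feature with no plateau
#' is written as an explicit JSON `null`, never omitted. Reading the JSON
#' back with [read_report()] reproduces the report table.
#'
#' @param study A [run_study()] result.
#' @param stem Output path stem (directories are created as needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(study, stem) {
  stopifnot(inherits(study, "texstab_study"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, "_curves.csv")
  lill <- lapply(study$lilliefors, function(l)
    list(p_cross_exposure = l$p_cross_exposure,
         median_p = l$median_p))
  payload <- list(
    schema_version = report_schema_version,
    config = unclass(study$config),
    report = study$report,
    islands = study$islands,
    lilliefors = lill)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  curve_rows <- lapply(names(study$curves), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    cbind(archetype = parts[1], scheme = parts[2], G = as.integer(parts[3]),
          feature = parts[4], as.data.frame(study$curves[[k]]))
  })
  utils::write.csv(do.call(rbind, curve_rows), csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}

#' Read back a JSON study report
#'
#' @param path Path to the `.json` written by [write_report()].
#' @return A list with `schema_version`, `config`, `report` (data frame),
#'   `islands` and `lilliefors`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stop("not a study report: missing schema_version")
  obj$report <- as.data.frame(obj$report)
  obj
}
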