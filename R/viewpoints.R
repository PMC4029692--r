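#' Viewpoint definitions
#'
#' A viewpoint is a labelled camera pose around a crop row, described by three
#' numbers: the azimuth angle (degrees; 90 = viewing direction perpendicular to
#' the row, i.e. straight in front of the crop), the zenith angle (degrees
#' between the camera-to-crop viewing vector and vertical up; 90 = horizontal,
#' 60 = looking upward, 120 = looking downward) and a signed horizontal offset
#' along the row axis in metres.
#'
#' @param label integer label(s), unique within a set.
#' @param azimuth_deg azimuth angle in degrees, in `[0, 180]`.
#' @param zenith_deg zenith angle in degrees, in `(0, 180)`.
#' @param offset_m signed horizontal displacement along the row axis (m).
#' @return A `viewpoint_set`: a data.frame with columns `label`, `azimuth_deg`,
#'   `zenith_deg`, `offset_m`, one row per viewpoint.
#' @examples
#' viewpoint_set(label = 1:2, azimuth_deg = 90, zenith_deg = c(60, 120),
#'               offset_m = 0)
#' @export
viewpoint_set <- function(label, azimuth_deg, zenith_deg, offset_m = 0) {
  vp <- data.frame(
    label       = as.integer(label),
    azimuth_deg = as.numeric(azimuth_deg),
    zenith_deg  = as.numeric(zenith_deg),
    offset_m    = as.numeric(offset_m)
  )
  validate_viewpoints(vp)
}

#' Validate a set of viewpoints
#'
#' Checks labels are unique integers, azimuth lies in `[0, 180]` and zenith in
#' the open interval `(0, 180)` (viewing straight along the vertical is outside
#' the supported design).
#'
#' @param vp data.frame with columns `label`, `azimuth_deg`, `zenith_deg`,
#'   `offset_m`.
#' @return `vp`, with class `viewpoint_set`, invisibly usable as a data.frame.
#' @export
validate_viewpoints <- function(vp) {
  required <- c("label", "azimuth_deg", "zenith_deg", "offset_m")
  missing <- setdiff(required, names(vp))
  if (length(missing) > 0)
    stop("viewpoint set lacks column(s): ", paste(missing, collapse = ", "))
  vp <- as.data.frame(vp)[required]
  vp$label <- as.integer(vp$label)
  if (anyNA(vp)) stop("viewpoint set contains missing values")
  if (anyDuplicated(vp$label))
    stop("duplicate viewpoint label(s): ",
         paste(unique(vp$label[duplicated(vp$label)]), collapse = ", "))
  if (any(vp$azimuth_deg < 0 | vp$azimuth_deg > 180))
    stop("azimuth_deg must lie in [0, 180]")
  if (any(vp$zenith_deg <= 0 | vp$zenith_deg >= 180))
    stop("zenith_deg must lie strictly between 0 and 180")
  vp <- vp[order(vp$label), , drop = FALSE]
  rownames(vp) <- NULL
  class(vp) <- c("viewpoint_set", "data.frame")
  vp
}

#' The canonical 14-viewpoint layout
#'
#' The standard recording layout used throughout this package: labels 10-14
#' place the camera at azimuth angles 30, 60, 90, 120 and 150 degrees (zenith
#' 90, no offset); labels 1-3, 4-6 and 7-9 fix the azimuth at 90 degrees and
#' set the zenith to 120, 90 and 60 degrees respectively, each triple recorded
#' at horizontal offsets of -0.15, 0 and +0.15 m along the row. Labels 5 and 12
#' are distinct entries with identical geometry (both front views); they are
#' deliberately kept separate so combination counts treat them as different
#' labelled positions.
#'
#' The offset direction convention (label 1 at -0.15 m, label 3 at +0.15 m) is
#' a package convention; only the magnitude is physically meaningful.
#'
#' @return A `viewpoint_set` with exactly 14 rows.
#' @examples
#' vp <- canonical_viewpoints()
#' nrow(vp)           # 14
#' vp[vp$label == 12, ]
#' @export
canonical_viewpoints <- function() {
  offsets <- c(-0.15, 0, 0.15)
  viewpoint_set(
    label       = 1:14,
    azimuth_deg = c(rep(90, 9), 30, 60, 90, 120, 150),
    zenith_deg  = c(rep(120, 3), rep(90, 3), rep(60, 3), rep(90, 5)),
    offset_m    = c(offsets, offsets, offsets, rep(0, 5))
  )
}

#' Read viewpoint definitions from CSV or YAML
#'
#' CSV files need a header with columns `label`, `azimuth_deg`, `zenith_deg`,
#' `offset_m`. YAML files hold a list of mappings with the same keys.
#'
#' @param path file path; format inferred from the `.yml`/`.yaml` extension,
#'   CSV otherwise.
#' @return A validated `viewpoint_set`.
#' @export
read_viewpoints <- function(path) {
  if (!file.exists(path)) stop("viewpoint file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    vp <- do.call(rbind, lapply(lst, function(v) {
      as.data.frame(v[c("label", "azimuth_deg", "zenith_deg", "offset_m")])
    }))
  } else {
    vp <- utils::read.csv(path)
  }
  validate_viewpoints(vp)
}

#' Write viewpoint definitions to CSV
#'
#' @param vp a `viewpoint_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_viewpoints <- function(vp, path) {
  vp <- validate_viewpoints(vp)
  utils::write.csv(as.data.frame(vp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
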