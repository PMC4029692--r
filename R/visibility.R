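#' The discrete fruit-visibility level set
#'
#' Fruit visibility (FV) — the percentage of a fruit's unoccluded image area
#' that is actually visible — is recorded on a fixed set of discrete levels:
#' 0, 5, 10, 20, 30, ..., 100. Note there is no 15; the scale jumps from 10
#' to 20.
#'
#' @return Numeric vector of the 12 permitted FV levels.
#' @export
fv_levels <- function() {
  c(0, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
}

#' Construct a visibility table
#'
#' A visibility table maps every (plant, fruit, viewpoint) triple to an FV
#' percentage on the discrete level set. It is backed by a fruit registry —
#' the ground-truth census of fruits per plant — so fruits that are completely
#' occluded from every viewpoint still enter the detectability denominator.
#' A registered fruit with no record at some viewpoint is materialised with
#' FV = 0 (completely occluded) rather than treated as missing.
#'
#' @param records data.frame with columns `plant_id`, `fruit_id`,
#'   `viewpoint_label`, `fv_percent`. At most one row per
#'   (plant, fruit, viewpoint); `fv_percent` must be on [fv_levels()].
#' @param registry data.frame with columns `plant_id`, `fruit_id`: the ground
#'   truth census. Every fruit in `records` must appear here.
#' @param viewpoint_labels integer labels the table covers; defaults to the
#'   labels present in `records`. Labels given here but absent from `records`
#'   are filled with FV = 0 for every registered fruit.
#' @return A `visibility_table`: list with elements `records` (dense, sorted
#'   data.frame covering every registered fruit at every label), `registry`,
#'   and `viewpoint_labels`.
#' @examples
#' reg <- data.frame(plant_id = "p1", fruit_id = c("a", "b"))
#' rec <- data.frame(plant_id = "p1", fruit_id = "a",
#'                   viewpoint_label = 12L, fv_percent = 80)
#' tab <- visibility_table(rec, reg)
#' subset(tab$records, fruit_id == "b")$fv_percent  # 0: absent means occluded
#' @export
visibility_table <- function(records, registry, viewpoint_labels = NULL) {
  registry <- as.data.frame(registry)
  if (!all(c("plant_id", "fruit_id") %in% names(registry)))
    stop("registry needs columns plant_id, fruit_id")
  registry$plant_id <- as.character(registry$plant_id)
  registry$fruit_id <- as.character(registry$fruit_id)
  registry <- registry[c("plant_id", "fruit_id")]
  if (anyDuplicated(registry))
    stop("registry lists the same (plant_id, fruit_id) twice")

  records <- as.data.frame(records)
  needed <- c("plant_id", "fruit_id", "viewpoint_label", "fv_percent")
  if (nrow(records) > 0 && !all(needed %in% names(records)))
    stop("visibility records need columns ", paste(needed, collapse = ", "))
  if (nrow(records) == 0)
    records <- data.frame(plant_id = character(), fruit_id = character(),
                          viewpoint_label = integer(), fv_percent = numeric())
  records$plant_id <- as.character(records$plant_id)
  records$fruit_id <- as.character(records$fruit_id)
  records$viewpoint_label <- as.integer(records$viewpoint_label)
  records$fv_percent <- as.numeric(records$fv_percent)
  records <- records[needed]

  bad_fv <- which(!(records$fv_percent %in% fv_levels()))
  if (length(bad_fv) > 0)
    stop("fv_percent not on the permitted level set {0,5,10,20,...,100} in row(s) ",
         paste(utils::head(bad_fv, 5), collapse = ", "),
         " (value ", records$fv_percent[bad_fv[1]], ")")

  key <- function(p, f) paste(p, f, sep = "\r")
  unknown <- !(key(records$plant_id, records$fruit_id) %in%
                 key(registry$plant_id, registry$fruit_id))
  if (any(unknown))
    stop("registry mismatch: visibility record(s) for unregistered fruit in row(s) ",
         paste(utils::head(which(unknown), 5), collapse = ", "))

  trip <- paste(records$plant_id, records$fruit_id, records$viewpoint_label,
                sep = "\r")
  if (anyDuplicated(trip))
    stop("duplicate (plant, fruit, viewpoint) record in row(s) ",
         paste(utils::head(which(duplicated(trip)), 5), collapse = ", "))

  labels <- sort(unique(c(as.integer(viewpoint_labels),
                          records$viewpoint_label)))
  # densify: every registered fruit gets a value at every label (0 if absent)
  if (length(labels) > 0 && nrow(registry) > 0) {
    dense <- merge(registry,
                   data.frame(viewpoint_label = labels))
    dense <- merge(dense, records, all.x = TRUE,
                   by = c("plant_id", "fruit_id", "viewpoint_label"))
    dense$fv_percent[is.na(dense$fv_percent)] <- 0
  } else {
    dense <- data.frame(plant_id = character(), fruit_id = character(),
                        viewpoint_label = integer(), fv_percent = numeric())
  }
  dense <- dense[order(dense$plant_id, dense$fruit_id, dense$viewpoint_label), ]
  rownames(dense) <- NULL
  registry <- registry[order(registry$plant_id, registry$fruit_id), ]
  rownames(registry) <- NULL

  structure(
    list(records = dense, registry = registry, viewpoint_labels = labels),
    class = "visibility_table"
  )
}

#' @export
print.visibility_table <- function(x, ...) {
  cat("Visibility table:",
      length(unique(x$registry$plant_id)), "plant(s),",
      nrow(x$registry), "registered fruit(s),",
      length(x$viewpoint_labels), "viewpoint(s)\n")
  cat("Viewpoint labels:", paste(x$viewpoint_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Read a visibility table and its fruit registry from CSV
#'
#' The visibility file needs header columns `plant_id`, `fruit_id`,
#' `viewpoint_label`, `fv_percent`; the registry file needs `plant_id`,
#' `fruit_id`. Registered fruits absent from the visibility file at some
#' viewpoint are filled in with FV = 0. Values off the discrete level set,
#' duplicated triples and unregistered fruits are rejected with the offending
#' row named.
#'
#' @param path visibility CSV path.
#' @param registry_path registry CSV path.
#' @param viewpoint_labels optional labels the table must cover (see
#'   [visibility_table()]).
#' @return A `visibility_table`.
#' @export
read_visibility_table <- function(path, registry_path, viewpoint_labels = NULL) {
  if (!file.exists(path)) stop("visibility file not found: ", path)
  if (!file.exists(registry_path))
    stop("registry file not found: ", registry_path)
  records <- utils::read.csv(path, colClasses = c(
    plant_id = "character", fruit_id = "character"))
  registry <- utils::read.csv(registry_path, colClasses = c(
    plant_id = "character", fruit_id = "character"))
  visibility_table(records, registry, viewpoint_labels = viewpoint_labels)
}

#' Write a visibility table (and optionally its registry) to CSV
#'
#' Rows are written in deterministic order (plant, fruit, viewpoint ascending)
#' including materialised FV = 0 rows, so [read_visibility_table()] inverts
#' the write exactly.
#'
#' @param table a `visibility_table`.
#' @param path output CSV path for the visibility records.
#' @param registry_path optional output CSV path for the registry.
#' @return `path`, invisibly.
#' @export
write_visibility_table <- function(table, path, registry_path = NULL) {
  stopifnot(inherits(table, "visibility_table"))
  utils::write.csv(table$records, path, row.names = FALSE, quote = FALSE)
  if (!is.null(registry_path))
    utils::write.csv(table$registry, registry_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
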