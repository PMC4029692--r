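#' Is a fruit detected at a visibility threshold?
#'
#' A fruit counts as detected when its visible fraction meets the threshold,
#' inclusively: a 40% threshold admits any fruit occluded by no more than 60%.
#'
#' @param fv fruit visibility percentage(s).
#' @param threshold minimum FV percentage, in `(0, 100]`.
#' @return Logical vector, `TRUE` where `fv >= threshold`.
#' @examples
#' fruit_detected(40, 40)   # TRUE: inclusive comparison
#' fruit_detected(0, 5)     # FALSE
#' @export
fruit_detected <- function(fv, threshold) {
  if (any(threshold <= 0 | threshold > 100))
    stop("threshold must lie in (0, 100]")
  fv >= threshold
}

#' Per-plant fruit detectability for a set of viewpoints
#'
#' Fruit detectability (FD) of a plant is the percentage of its registered
#' (ground-truth) fruits detected, where a fruit is detected if its FV meets
#' the threshold in at least one image of the viewpoint set. The denominator
#' is all registered fruits, including those never visible from any viewpoint.
#'
#' @param table a `visibility_table`.
#' @param plant plant identifier.
#' @param viewpoint_set integer viewpoint labels (non-empty, all present in
#'   the table).
#' @param threshold minimum FV percentage.
#' @return FD percentage in `[0, 100]`.
#' @export
plant_fd <- function(table, plant, viewpoint_set, threshold) {
  stopifnot(inherits(table, "visibility_table"))
  plant <- as.character(plant)
  viewpoint_set <- unique(as.integer(viewpoint_set))
  if (length(viewpoint_set) == 0) stop("viewpoint_set must be non-empty")
  unknown <- setdiff(viewpoint_set, table$viewpoint_labels)
  if (length(unknown) > 0)
    stop("viewpoint label(s) not in table: ", paste(unknown, collapse = ", "))
  fruits <- table$registry$fruit_id[table$registry$plant_id == plant]
  if (length(fruits) == 0)
    stop("FD undefined: plant '", plant, "' has no registered fruits")
  rec <- table$records[table$records$plant_id == plant &
                         table$records$viewpoint_label %in% viewpoint_set, ]
  max_fv <- tapply(rec$fv_percent, rec$fruit_id, max)
  100 * sum(fruit_detected(as.numeric(max_fv), threshold)) / length(fruits)
}

#' Aggregate fruit detectability across plants
#'
#' Computes the per-plant FD for every plant in the registry, their mean, and
#' the sample standard deviation across plants,
#' \eqn{\mathrm{SD} = \sqrt{\sum_i (\mathrm{FD}_i - \overline{\mathrm{FD}})^2 / (n - 1)}}.
#' With a single plant the SD is undefined and reported as `NA`.
#'
#' @inheritParams plant_fd
#' @return An `fd_result`: list with `viewpoint_set`, `threshold`, `per_plant`
#'   (named numeric vector of FD values), `mean_fd`, `sd_fd` (`NA` when
#'   `n_plants < 2`) and `n_plants`.
#' @examples
#' reg <- data.frame(plant_id = c("p1", "p2"), fruit_id = "f1")
#' rec <- data.frame(plant_id = c("p1", "p2"), fruit_id = "f1",
#'                   viewpoint_label = 1L, fv_percent = c(100, 0))
#' r <- aggregate_fd(visibility_table(rec, reg), 1L, 50)
#' r$mean_fd  # 50
#' r$sd_fd    # 70.71068
#' @export
aggregate_fd <- function(table, viewpoint_set, threshold) {
  stopifnot(inherits(table, "visibility_table"))
  plants <- unique(table$registry$plant_id)
  if (length(plants) == 0) stop("no plants in registry")
  fd <- vapply(plants, function(p) plant_fd(table, p, viewpoint_set, threshold),
               numeric(1))
  structure(
    list(
      viewpoint_set = sort(unique(as.integer(viewpoint_set))),
      threshold = threshold,
      per_plant = fd,
      mean_fd = mean(fd),
      sd_fd = if (length(fd) >= 2) stats::sd(fd) else NA_real_,
      n_plants = length(fd)
    ),
    class = "fd_result"
  )
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf(
    "FD for viewpoint set {%s} at FV >= %g%%: mean %.1f%%, SD %s (n = %d plants)\n",
    paste(x$viewpoint_set, collapse = ", "), x$threshold, x$mean_fd,
    if (is.na(x$sd_fd)) "NA" else sprintf("%.1f%%", x$sd_fd), x$n_plants))
  invisible(x)
}

#' Default FV threshold sweep
#'
#' The standard sweep of minimum-FV thresholds: 5, 10, 20, 30, ..., 100
#' (11 values; like the FV level set it skips 15).
#'
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function() {
  c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
}

#' Sweep FV thresholds for one viewpoint set
#'
#' @inheritParams plant_fd
#' @param thresholds thresholds to evaluate, each in `(0, 100]`; defaults to
#'   [default_thresholds()].
#' @return Named list of `fd_result`, one per threshold (names are the
#'   threshold values).
#' @export
threshold_sweep <- function(table, viewpoint_set,
                            thresholds = default_thresholds()) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  if (any(thresholds <= 0 | thresholds > 100))
    stop("thresholds must lie in (0, 100]")
  res <- lapply(thresholds, function(t) aggregate_fd(table, viewpoint_set, t))
  names(res) <- thresholds
  res
}
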