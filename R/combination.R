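#' Enumerate all non-empty viewpoint subsets
#'
#' For m labelled viewpoints there are 2^m - 1 non-empty subsets (the sum of
#' binomial coefficients choose(m, 1) + ... + choose(m, m)); five viewpoints
#' give 31, nine give 511 and fourteen give 16,383. Labels with identical
#' geometry still count as distinct subset members.
#'
#' @param labels integer viewpoint labels (unique).
#' @param cap maximum number of viewpoints enumerated exhaustively (default
#'   20, i.e. about a million subsets); beyond it, refuse and point at
#'   [greedy_cover()].
#' @return List of integer vectors, each a sorted non-empty subset of
#'   `labels`; length `2^length(labels) - 1`.
#' @examples
#' length(enumerate_subsets(1:5))   # 31
#' @export
enumerate_subsets <- function(labels, cap = 20) {
  labels <- unique(as.integer(labels))
  m <- length(labels)
  if (m < 1) stop("need at least one viewpoint label")
  if (m > cap)
    stop(m, " viewpoints exceed the exhaustive-enumeration cap of ", cap,
         " (", cap, " viewpoints = 2^", cap, " - 1 subsets); ",
         "use greedy_cover() for larger sets")
  labels <- sort(labels)
  masks <- seq_len(2^m - 1)
  lapply(masks, function(s) labels[bitwAnd(s, bitwShiftL(1L, 0:(m - 1))) != 0L])
}

#' Canonical string form of a viewpoint subset
#'
#' Labels sorted ascending and joined by dashes, e.g. `"5-7-8-10-13"`.
#'
#' @param labels integer labels.
#' @return Character scalar.
#' @export
subset_key <- function(labels) {
  paste(sort(unique(as.integer(labels))), collapse = "-")
}

# Per-fruit detection across viewpoints: logical matrix (fruit x label),
# plus per-fruit plant and mean-of-plants FD weights.
.detect_matrix <- function(table, labels, threshold) {
  stopifnot(inherits(table, "visibility_table"))
  labels <- sort(unique(as.integer(labels)))
  unknown <- setdiff(labels, table$viewpoint_labels)
  if (length(unknown) > 0)
    stop("viewpoint label(s) not in table: ", paste(unknown, collapse = ", "))
  reg <- table$registry
  if (nrow(reg) == 0) stop("no fruits in registry")
  rec <- table$records[table$records$viewpoint_label %in% labels, ]
  fruit_key <- paste(reg$plant_id, reg$fruit_id, sep = "\r")
  rec_key <- paste(rec$plant_id, rec$fruit_id, sep = "\r")
  det <- matrix(FALSE, nrow = nrow(reg), ncol = length(labels),
                dimnames = list(fruit_key, labels))
  det[cbind(match(rec_key, fruit_key),
            match(rec$viewpoint_label, labels))] <-
    fruit_detected(rec$fv_percent, threshold)
  plant <- reg$plant_id
  n_per_plant <- table(plant)
  # weight such that sum(detected * w) = mean over plants of per-plant FD (%)
  w <- 100 / (as.numeric(n_per_plant[plant]) * length(n_per_plant))
  list(det = det, labels = labels, plant = plant, weights = w)
}

#' Maximum combined FD per subset size (exhaustive)
#'
#' Scans every non-empty subset of the given viewpoints and, for each subset
#' size k, records the maximum combined fruit detectability (mean over plants
#' of per-plant FD, a fruit counting as detected if it meets the threshold at
#' any viewpoint of the subset) together with every subset attaining that
#' maximum. Also reports the global maximum and the smallest subset size that
#' reaches it ("positions needed"); beyond that size, adding positions does
#' not increase the FD.
#'
#' @param table a `visibility_table`.
#' @param viewpoints integer labels or a `viewpoint_set`.
#' @param threshold minimum FV percentage.
#' @param cap exhaustive-mode ceiling on the number of viewpoints (see
#'   [enumerate_subsets()]).
#' @param tol numeric tolerance when comparing FD values for argmax ties.
#' @return A `combination_report`: list with `threshold`, `labels`,
#'   `by_size` (data.frame `k`, `max_fd`, `n_argmax`), `argmax` (per k, list
#'   of label vectors attaining the maximum), `global_max_fd`,
#'   `positions_needed`, `n_subsets`.
#' @export
max_fd_by_size <- function(table, viewpoints, threshold, cap = 20,
                           tol = 1e-9) {
  labels <- if (inherits(viewpoints, "viewpoint_set")) viewpoints$label
            else as.integer(viewpoints)
  labels <- sort(unique(labels))
  m <- length(labels)
  if (m > cap)
    stop(m, " viewpoints exceed the exhaustive cap of ", cap,
         "; use greedy_cover()")
  dm <- .detect_matrix(table, labels, threshold)

  n_subsets <- 2^m - 1
  bit_vals <- 2^(0:(m - 1))
  # per-fruit bitmask of viewpoints where it is detected
  fruit_mask <- as.numeric(dm$det %*% bit_vals)

  chunk <- 65536L
  chunk_starts <- seq(1, n_subsets, by = chunk)
  scan_chunk <- function(start) {
    s <- start:min(start + chunk - 1L, n_subsets)
    member <- outer(s, bit_vals, function(a, b) (a %/% b) %% 2 == 1)
    # subset detects fruit f iff it shares a bit with fruit f's mask
    detected <- outer(s, fruit_mask,
                      function(a, b) bitwAnd(as.integer(a), as.integer(b)) != 0L)
    list(member = member, sizes = rowSums(member),
         fd = as.numeric(detected %*% dm$weights))
  }

  # pass 1: maximum FD per subset size
  max_fd <- rep(-Inf, m)
  for (start in chunk_starts) {
    ch <- scan_chunk(start)
    mk <- tapply(ch$fd, ch$sizes, max)
    k <- as.integer(names(mk))
    max_fd[k] <- pmax(max_fd[k], as.numeric(mk))
  }
  # pass 2: collect every subset attaining the per-size maximum
  argmax <- rep(list(list()), m)
  for (start in chunk_starts) {
    ch <- scan_chunk(start)
    hit <- which(ch$fd >= max_fd[ch$sizes] - tol)
    for (i in hit) {
      k <- ch$sizes[i]
      argmax[[k]] <- c(argmax[[k]], list(labels[ch$member[i, ]]))
    }
  }

  global_max <- max(max_fd)
  positions_needed <- min(which(max_fd >= global_max - tol))
  structure(
    list(
      threshold = threshold,
      labels = labels,
      by_size = data.frame(k = seq_len(m), max_fd = max_fd,
                           n_argmax = vapply(argmax, length, integer(1))),
      argmax = argmax,
      global_max_fd = global_max,
      positions_needed = positions_needed,
      n_subsets = n_subsets
    ),
    class = "combination_report"
  )
}

#' @export
print.combination_report <- function(x, ...) {
  cat(sprintf(
    "Combination report: %d viewpoints, %d subsets scanned, FV >= %g%%\n",
    length(x$labels), x$n_subsets, x$threshold))
  cat(sprintf("Global max FD %.1f%%, reached with %d position(s)\n",
              x$global_max_fd, x$positions_needed))
  df <- x$by_size
  df$example <- vapply(x$argmax,
                       function(a) if (length(a)) subset_key(a[[1]]) else "",
                       character(1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Favourite viewpoint subsets shared across sessions
#'
#' Given combination reports from two or more recording sessions over the same
#' viewpoint label set and the same FV threshold, returns for each subset size
#' k the subsets that attain the maximum FD in every session. An empty
#' intersection is a valid result.
#'
#' @param reports list of `combination_report` objects (one per session).
#' @return List over k of lists of integer label vectors common to all
#'   sessions' argmax sets.
#' @export
favourite_positions <- function(reports) {
  if (length(reports) < 2) stop("need at least two session reports")
  stopifnot(all(vapply(reports, inherits, logical(1), "combination_report")))
  labs <- lapply(reports, `[[`, "labels")
  if (!all(vapply(labs, identical, logical(1), labs[[1]])))
    stop("session reports cover different viewpoint label sets")
  thr <- vapply(reports, `[[`, numeric(1), "threshold")
  if (length(unique(thr)) != 1)
    stop("session reports use different FV thresholds")
  m <- length(labs[[1]])
  out <- vector("list", m)
  for (k in seq_len(m)) {
    keys <- lapply(reports, function(r)
      vapply(r$argmax[[k]], subset_key, character(1)))
    common <- Reduce(intersect, keys)
    first <- reports[[1]]$argmax[[k]]
    out[[k]] <- first[vapply(first, subset_key, character(1)) %in% common]
  }
  out
}

#' Greedy viewpoint selection by fruit coverage
#'
#' A scalable alternative to exhaustive subset enumeration: starting from the
#' empty set, repeatedly add the viewpoint that newly detects the largest
#' number of so-far-undetected registered fruits (ties broken by lowest
#' label), up to `k_max` positions. The FD trajectory is non-decreasing and
#' each value is bounded above by the exhaustive maximum for that subset size.
#'
#' @inheritParams max_fd_by_size
#' @param k_max maximum number of positions to select (>= 1).
#' @return data.frame with one row per step: `k`, `label` (position added),
#'   `new_fruits` (newly detected fruit count), `fd` (combined mean FD after
#'   this step).
#' @export
greedy_cover <- function(table, viewpoints, threshold, k_max = NULL) {
  labels <- if (inherits(viewpoints, "viewpoint_set")) viewpoints$label
            else as.integer(viewpoints)
  labels <- sort(unique(labels))
  if (is.null(k_max)) k_max <- length(labels)
  if (k_max < 1) stop("k_max must be >= 1")
  k_max <- min(k_max, length(labels))
  dm <- .detect_matrix(table, labels, threshold)

  covered <- rep(FALSE, nrow(dm$det))
  remaining <- labels
  out <- data.frame(k = integer(), label = integer(),
                    new_fruits = integer(), fd = numeric())
  for (step in seq_len(k_max)) {
    gains <- vapply(remaining, function(l) {
      sum(dm$det[, as.character(l)] & !covered)
    }, integer(1))
    pick <- remaining[which.max(gains)]  # which.max takes the first = lowest label
    covered <- covered | dm$det[, as.character(pick)]
    out <- rbind(out, data.frame(
      k = step, label = pick, new_fruits = max(gains),
      fd = sum(dm$weights[covered])))
    remaining <- setdiff(remaining, pick)
  }
  out
}
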