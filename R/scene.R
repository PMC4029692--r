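# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministically derive an independent stream seed (< 2^31) from a root
# seed and any number of integer tags, so e.g. changing n_rays never alters
# the scene geometry.
.derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (x in c(...)) h <- (h * 48271 + as.numeric(x) + 1) %% 2147483647
  as.integer(h)
}

#' Default synthetic canopy parameters
#'
#' Parameters for [generate_scene()], calibrated to a commercial sweet-pepper
#' greenhouse row: 10 plants spaced 0.2 m apart, 2-4 ripe fruits per plant
#' (radius 0.04 m) in a 1.00-1.35 m height band, and on average 12 elliptical
#' leaf occluders per plant (semi-axes 0.09 x 0.055 m) whose orientations are
#' biased toward facing upward. These geometric defaults are package
#' calibrations chosen for realism, not measured constants; all are
#' overridable.
#'
#' @param n_plants number of plants in the row.
#' @param plant_spacing_m distance between neighbouring plants along the row.
#' @param fruits_per_plant integer choices the per-plant fruit count is drawn
#'   from, uniformly.
#' @param fruit_radius_m fruit sphere radius (m).
#' @param fruit_z_range height band fruit centres are drawn from (m).
#' @param fruit_xy_spread_m half-width of the fruit scatter around the plant
#'   stem, along the row (x) and in canopy depth (y).
#' @param leaf_density mean number of leaves per plant (Poisson).
#' @param leaf_semi_axes_m semi-major and semi-minor axis of the leaf
#'   ellipse (m).
#' @param leaf_up_bias in `[0, 1)`: 0 gives isotropic leaf normals; values
#'   near 1 orient leaves phototropically — facing upward and toward the
#'   light over the aisle — so they present their face to downward-looking
#'   cameras (zenith > 90) and nearly their edge to upward-looking ones.
#' @param leaf_z_range height band leaf centres are drawn from (m).
#' @param leaf_xy_spread_m half-width of the leaf scatter around the stem.
#' @param capture_width_m,capture_height_m the recorded field of view at the
#'   canopy (m); fruits outside this window centred on the per-plant target
#'   are excluded from the ground-truth registry (but still occlude).
#' @param range_m camera-to-target distance (m).
#' @return Named list of parameters.
#' @export
scene_params <- function(n_plants = 10,
                         plant_spacing_m = 0.2,
                         fruits_per_plant = c(2, 3, 4),
                         fruit_radius_m = 0.04,
                         fruit_z_range = c(1.00, 1.35),
                         fruit_xy_spread_m = c(0.07, 0.06),
                         leaf_density = 12,
                         leaf_semi_axes_m = c(0.09, 0.055),
                         leaf_up_bias = 0.6,
                         leaf_z_range = c(1.05, 1.50),
                         leaf_xy_spread_m = c(0.13, 0.12),
                         capture_width_m = 0.7,
                         capture_height_m = 0.5,
                         range_m = 0.5) {
  p <- list(n_plants = n_plants, plant_spacing_m = plant_spacing_m,
            fruits_per_plant = fruits_per_plant,
            fruit_radius_m = fruit_radius_m, fruit_z_range = fruit_z_range,
            fruit_xy_spread_m = fruit_xy_spread_m,
            leaf_density = leaf_density,
            leaf_semi_axes_m = leaf_semi_axes_m,
            leaf_up_bias = leaf_up_bias, leaf_z_range = leaf_z_range,
            leaf_xy_spread_m = leaf_xy_spread_m,
            capture_width_m = capture_width_m,
            capture_height_m = capture_height_m, range_m = range_m)
  if (p$n_plants < 1) stop("n_plants must be >= 1")
  if (any(p$fruits_per_plant < 0)) stop("fruits_per_plant must be >= 0")
  if (p$leaf_density < 0) stop("leaf_density must be >= 0")
  if (p$leaf_up_bias < 0 || p$leaf_up_bias >= 1)
    stop("leaf_up_bias must lie in [0, 1)")
  if (p$fruit_radius_m <= 0) stop("fruit_radius_m must be positive")
  p
}

# Random leaf normal, pulled by bias b in [0,1) toward the phototropic
# direction: upward and slightly toward the open aisle (-y), where the light
# comes from. Strongly biased leaves present their face to downward-looking
# cameras (zenith > 90) and almost their edge to upward-looking ones.
.leaf_bias_direction <- c(0, -1, 2) / sqrt(5)

.biased_normal <- function(b) {
  raw <- .normalize(stats::rnorm(3))
  .normalize((1 - b) * raw + b * .leaf_bias_direction)
}

#' Generate a synthetic crop-row scene
#'
#' Builds a 3D canopy: plants along the x axis (row axis, centred at x = 0),
#' each carrying fruit spheres and zero-thickness opaque elliptical leaf
#' discs; the aisle (camera side) is at negative y and z points up. Leaf
#' orientations are drawn with a configurable upward-facing (phototropic)
#' bias: strongly biased leaves face upward and toward the light over the
#' aisle, presenting their full face to downward-looking cameras
#' (zenith > 90) and only their edge to upward-looking ones, which depresses
#' fruit detectability for downward views. Leaves also sit slightly above the
#' fruit band, as fruits hang below the foliage that shades them.
#'
#' Per plant, a target point is set at the stem x, canopy face, at the height
#' of the plant's lowest fruit (the lowest fruit centred in the image); fruits
#' outside the capture window around this target are flagged out-of-region
#' and excluded from the ground-truth registry, though they still act as
#' occluders.
#'
#' The scene is fully reproducible from `(params, seed)`.
#'
#' @param params parameter list from [scene_params()].
#' @param seed integer root seed.
#' @return A `canopy_scene`: list with `fruits` (data.frame: `plant_id`,
#'   `fruit_uid`, `x`, `y`, `z`, `radius`, `in_region`), `leaves` (data.frame
#'   of disc centres, unit normals, in-plane major axis and semi-axes),
#'   `targets` (per-plant target points), `params`, `seed`.
#' @export
generate_scene <- function(params = scene_params(), seed = 1) {
  params <- do.call(scene_params, params)  # validate + fill defaults
  .with_seed(.derive_seed(seed, 101L), {
    n <- params$n_plants
    px <- (seq_len(n) - (n + 1) / 2) * params$plant_spacing_m

    fruits <- list(); leaves <- list()
    for (i in seq_len(n)) {
      nf <- if (length(params$fruits_per_plant) == 1) params$fruits_per_plant
            else sample(params$fruits_per_plant, 1)
      if (nf > 0) {
        fruits[[i]] <- data.frame(
          plant_id = sprintf("p%02d", i),
          fruit_uid = sprintf("p%02d_f%d", i, seq_len(nf)),
          x = px[i] + stats::runif(nf, -1, 1) * params$fruit_xy_spread_m[1],
          y = stats::runif(nf, -1, 1) * params$fruit_xy_spread_m[2],
          z = stats::runif(nf, params$fruit_z_range[1], params$fruit_z_range[2]),
          radius = params$fruit_radius_m
        )
      }
      nl <- stats::rpois(1, params$leaf_density)
      if (nl > 0) {
        nrm <- t(vapply(seq_len(nl), function(j)
          .biased_normal(params$leaf_up_bias), numeric(3)))
        # in-plane major axis: random direction orthogonal to the normal
        a1 <- t(vapply(seq_len(nl), function(j) {
          v <- stats::rnorm(3)
          .normalize(v - sum(v * nrm[j, ]) * nrm[j, ])
        }, numeric(3)))
        leaves[[i]] <- data.frame(
          plant_id = sprintf("p%02d", i),
          cx = px[i] + stats::runif(nl, -1, 1) * params$leaf_xy_spread_m[1],
          cy = stats::runif(nl, -1, 1) * params$leaf_xy_spread_m[2],
          cz = stats::runif(nl, params$leaf_z_range[1], params$leaf_z_range[2]),
          nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
          a1x = a1[, 1], a1y = a1[, 2], a1z = a1[, 3],
          semi_a = params$leaf_semi_axes_m[1],
          semi_b = params$leaf_semi_axes_m[2]
        )
      }
    }
    fruits <- if (length(fruits)) do.call(rbind, fruits) else
      data.frame(plant_id = character(), fruit_uid = character(),
                 x = numeric(), y = numeric(), z = numeric(),
                 radius = numeric())
    leaves <- if (length(leaves)) do.call(rbind, leaves) else
      data.frame(plant_id = character(), cx = numeric(), cy = numeric(),
                 cz = numeric(), nx = numeric(), ny = numeric(),
                 nz = numeric(), a1x = numeric(), a1y = numeric(),
                 a1z = numeric(), semi_a = numeric(), semi_b = numeric())

    # per-plant target: stem x, canopy face (y = 0), lowest fruit height
    targets <- data.frame(plant_id = sprintf("p%02d", seq_len(n)),
                          x = px, y = 0, z = NA_real_)
    for (i in seq_len(n)) {
      pid <- targets$plant_id[i]
      fz <- fruits$z[fruits$plant_id == pid]
      targets$z[i] <- if (length(fz)) min(fz) else
        mean(params$fruit_z_range)
    }

    # capture-region clipping relative to the per-plant target
    in_region <- rep(TRUE, nrow(fruits))
    for (i in seq_len(nrow(fruits))) {
      tg <- targets[targets$plant_id == fruits$plant_id[i], ]
      in_region[i] <-
        abs(fruits$x[i] - tg$x) <= params$capture_width_m / 2 &&
        abs(fruits$z[i] - tg$z) <= params$capture_height_m / 2
    }
    fruits$in_region <- in_region
    rownames(fruits) <- NULL
    rownames(leaves) <- NULL

    structure(list(fruits = fruits, leaves = leaves, targets = targets,
                   params = params, seed = seed),
              class = "canopy_scene")
  })
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat("Synthetic canopy scene:", nrow(x$targets), "plant(s),",
      nrow(x$fruits), "fruit(s) (", sum(x$fruits$in_region),
      "in capture region ),", nrow(x$leaves), "leaf occluder(s)\n")
  cat("Seed:", x$seed, "\n")
  invisible(x)
}

#' Export a scene to JSON for inspection
#'
#' @param scene a `canopy_scene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "canopy_scene"))
  jsonlite::write_json(
    list(params = scene$params, seed = scene$seed,
         targets = scene$targets, fruits = scene$fruits,
         leaves = scene$leaves),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a full recording session
#'
#' Generates a canopy scene, then for every plant and every viewpoint places
#' the camera (per-plant target recentred so the plant's lowest fruit sits at
#' the image centre, viewpoint offset applied along the row) and estimates
#' each in-region fruit's visibility by ray casting, quantized to the discrete
#' FV level set. The result is a complete visibility table — every registered
#' fruit has a value at every viewpoint — plus its ground-truth registry.
#'
#' Scene generation and ray sampling use independent streams derived from the
#' root seed, so changing `n_rays` does not change the scene.
#'
#' @param params scene parameters, see [scene_params()].
#' @param viewpoints a `viewpoint_set`; defaults to the canonical 14.
#' @param n_rays rays per (fruit, viewpoint) visibility estimate.
#' @param seed integer root seed.
#' @return List with `table` (a `visibility_table`), `scene`, and
#'   `viewpoints`.
#' @export
simulate_session <- function(params = scene_params(),
                             viewpoints = canonical_viewpoints(),
                             n_rays = 400, seed = 1) {
  viewpoints <- validate_viewpoints(viewpoints)
  scene <- generate_scene(params, seed)
  fr <- scene$fruits[scene$fruits$in_region, , drop = FALSE]
  registry <- data.frame(plant_id = fr$plant_id, fruit_id = fr$fruit_uid)

  recs <- vector("list", nrow(viewpoints))
  for (v in seq_len(nrow(viewpoints))) {
    vp <- viewpoints[v, ]
    fv <- numeric(nrow(fr))
    for (i in seq_len(nrow(fr))) {
      tg <- scene$targets[scene$targets$plant_id == fr$plant_id[i], ]
      pose <- camera_pose(vp$azimuth_deg, vp$zenith_deg, vp$offset_m,
                          target = c(tg$x, tg$y, tg$z),
                          range_m = scene$params$range_m)
      idx <- match(fr$fruit_uid[i], scene$fruits$fruit_uid)
      fv[i] <- fruit_visibility(
        scene, pose, idx, n_rays = n_rays,
        seed = .derive_seed(seed, 202L, v, i))
    }
    recs[[v]] <- data.frame(plant_id = fr$plant_id, fruit_id = fr$fruit_uid,
                            viewpoint_label = vp$label,
                            fv_percent = quantize_fv(fv))
  }
  records <- do.call(rbind, recs)
  table <- visibility_table(records, registry,
                            viewpoint_labels = viewpoints$label)
  list(table = table, scene = scene, viewpoints = viewpoints)
}

#' The three-session recording design
#'
#' The study design this package emulates: three sessions of 10 plants each;
#' the first session records 5 viewpoints per plant (azimuth sweep, labels
#' 10-14), the second and third record all 14 viewpoints. That yields
#' 10 x 5 + 10 x 14 + 10 x 14 = 330 plant-viewpoint recordings of 30 plants.
#'
#' @param n_plants plants per session.
#' @return data.frame with one row per session: `session`, `n_plants`,
#'   `n_viewpoints`, `n_recordings`, plus the viewpoint labels as a list
#'   column `labels`.
#' @examples
#' sum(session_design()$n_recordings)  # 330
#' @export
session_design <- function(n_plants = 10) {
  vp <- canonical_viewpoints()
  labels <- list(10:14, vp$label, vp$label)
  d <- data.frame(session = 1:3, n_plants = n_plants,
                  n_viewpoints = lengths(labels))
  d$n_recordings <- d$n_plants * d$n_viewpoints
  d$labels <- labels
  d
}
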