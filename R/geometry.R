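# Scene coordinate convention: the crop row runs along x, the aisle (where the
# camera stands) is at negative y, and z points up.

.deg2rad <- function(d) d * pi / 180

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Camera pose from azimuth, zenith, offset and target
#'
#' Builds a camera position and unit viewing direction from the spherical
#' placement convention: with azimuth angle a and zenith angle z (degrees),
#' the viewing direction is `v = (sin z cos a, sin z sin a, cos z)` — the row
#' runs along x, the aisle lies at negative y, and z points up. Azimuth 90 is
#' the front view (v = (0, 1, 0)); zenith 60 looks upward (v_z = +0.5) and
#' zenith 120 looks downward. The camera sits at the target point, shifted by
#' `offset_m` along the row, minus `range_m` times the viewing direction.
#'
#' @param azimuth_deg azimuth angle in degrees, strictly inside `(0, 180)`.
#' @param zenith_deg zenith angle in degrees, strictly inside `(0, 180)`
#'   (viewing straight up or down the zenith is rejected).
#' @param offset_m horizontal displacement along the row axis (m).
#' @param target numeric length-3 point the camera looks at (before offset).
#' @param range_m camera-to-target distance (m), default 0.5.
#' @return A `camera_pose`: list with `position`, `direction` (unit vector),
#'   and the defining parameters.
#' @examples
#' p <- camera_pose(90, 90, 0, target = c(0, 0, 1), range_m = 0.5)
#' p$position   # (0, -0.5, 1): front view from the aisle
#' p$direction  # (0, 1, 0)
#' @export
camera_pose <- function(azimuth_deg, zenith_deg, offset_m = 0,
                        target = c(0, 0, 0), range_m = 0.5) {
  if (azimuth_deg <= 0 || azimuth_deg >= 180)
    stop("azimuth_deg must lie strictly inside (0, 180)")
  if (zenith_deg <= 0 || zenith_deg >= 180)
    stop("zenith_deg must lie strictly inside (0, 180): viewing along the ",
         "zenith is degenerate")
  if (range_m <= 0) stop("range_m must be positive")
  stopifnot(length(target) == 3)
  a <- .deg2rad(azimuth_deg)
  z <- .deg2rad(zenith_deg)
  v <- c(sin(z) * cos(a), sin(z) * sin(a), cos(z))
  v <- .normalize(v)
  shifted <- target + c(offset_m, 0, 0)
  structure(
    list(position = shifted - range_m * v, direction = v,
         azimuth_deg = azimuth_deg, zenith_deg = zenith_deg,
         offset_m = offset_m, target = shifted, range_m = range_m),
    class = "camera_pose"
  )
}

# Rays from `origin` to each column of `points` (3 x n); returns logical:
# is the ray blocked strictly between origin and its endpoint by any of the
# discs (elliptical, zero thickness) or spheres?
# discs: data.frame cx,cy,cz,nx,ny,nz,a1x,a1y,a1z,semi_a,semi_b
# spheres: data.frame x,y,z,radius
.rays_blocked <- function(origin, points, discs = NULL, spheres = NULL,
                          eps = 1e-9) {
  n <- ncol(points)
  blocked <- rep(FALSE, n)
  w <- points - origin  # ray: origin + t*w, endpoint at t = 1

  if (!is.null(spheres) && nrow(spheres) > 0) {
    for (i in seq_len(nrow(spheres))) {
      if (all(blocked)) break
      s <- c(spheres$x[i], spheres$y[i], spheres$z[i])
      r <- spheres$radius[i]
      idx <- which(!blocked)
      wi <- w[, idx, drop = FALSE]
      oc <- origin - s
      A <- colSums(wi^2)
      B <- 2 * colSums(wi * oc)
      C <- sum(oc^2) - r^2
      disc <- B^2 - 4 * A * C
      hit <- disc > 0
      if (any(hit)) {
        sq <- sqrt(pmax(disc[hit], 0))
        t1 <- (-B[hit] - sq) / (2 * A[hit])
        t2 <- (-B[hit] + sq) / (2 * A[hit])
        inside <- (t1 > eps & t1 < 1 - eps) | (t2 > eps & t2 < 1 - eps)
        blocked[idx[hit][inside]] <- TRUE
      }
    }
  }

  if (!is.null(discs) && nrow(discs) > 0) {
    for (i in seq_len(nrow(discs))) {
      if (all(blocked)) break
      ctr <- c(discs$cx[i], discs$cy[i], discs$cz[i])
      nrm <- c(discs$nx[i], discs$ny[i], discs$nz[i])
      a1 <- c(discs$a1x[i], discs$a1y[i], discs$a1z[i])
      a2 <- c(nrm[2] * a1[3] - nrm[3] * a1[2],
              nrm[3] * a1[1] - nrm[1] * a1[3],
              nrm[1] * a1[2] - nrm[2] * a1[1])
      idx <- which(!blocked)
      wi <- w[, idx, drop = FALSE]
      denom <- colSums(wi * nrm)
      ok <- abs(denom) > 1e-12
      if (!any(ok)) next
      t <- sum((ctr - origin) * nrm) / denom[ok]
      between <- t > eps & t < 1 - eps
      if (!any(between)) next
      sub <- idx[ok][between]
      q <- origin + w[, sub, drop = FALSE] *
        rep(t[between], each = 3) - ctr
      u <- colSums(q * a1) / discs$semi_a[i]
      v <- colSums(q * a2) / discs$semi_b[i]
      blocked[sub[u^2 + v^2 <= 1]] <- TRUE
    }
  }

  blocked
}

# Conservative occluder prune: every camera->sample ray stays within
# fruit_radius of the segment camera->fruit_centre, so occluders whose centre
# is farther from that segment than (own bounding radius + fruit radius)
# cannot intersect any ray.
.prune_occluders <- function(cam, centre, fruit_radius, centres, bound_radii) {
  if (nrow(centres) == 0) return(logical(0))
  d <- centre - cam
  len2 <- sum(d^2)
  rel <- t(centres) - cam          # 3 x n
  t <- pmin(pmax(colSums(rel * d) / len2, 0), 1)
  closest <- outer(d, t) - rel     # 3 x n (difference to closest segment point)
  dist <- sqrt(colSums(closest^2))
  dist <= bound_radii + fruit_radius + 1e-9
}

#' Monte-Carlo fruit visibility from one camera pose
#'
#' Estimates the fraction of a fruit's unoccluded projected area that the
#' camera actually sees. Sample points are drawn uniformly on the fruit
#' sphere's camera-facing projected disc (the disc through the fruit centre,
#' perpendicular to the camera-to-fruit direction, with the fruit's radius);
#' a ray from the camera to a sample point is blocked if it intersects any
#' leaf disc or any *other* fruit sphere strictly between camera and sample
#' point. The return value is 100 times the unblocked fraction — a continuous
#' percentage; quantize with [quantize_fv()] to mimic observer scoring.
#'
#' @param scene a `canopy_scene` (see [generate_scene()]).
#' @param pose a `camera_pose`.
#' @param fruit fruit identifier: row index into `scene$fruits`, or a fruit
#'   key `"plant\rfruit"`-free identifier matching `scene$fruits$fruit_uid`.
#' @param n_rays number of sample rays (>= 100).
#' @param seed integer seed for the ray sampling stream.
#' @return Visibility percentage in `[0, 100]` (unquantized).
#' @export
fruit_visibility <- function(scene, pose, fruit, n_rays = 1000, seed = 1) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(pose, "camera_pose"))
  if (n_rays < 100) stop("n_rays must be at least 100")
  fruits <- scene$fruits
  if (is.character(fruit)) fruit <- match(fruit, fruits$fruit_uid)
  if (is.na(fruit) || fruit < 1 || fruit > nrow(fruits))
    stop("fruit not found in scene")

  centre <- c(fruits$x[fruit], fruits$y[fruit], fruits$z[fruit])
  radius <- fruits$radius[fruit]
  cam <- pose$position
  d <- centre - cam
  dist <- sqrt(sum(d^2))
  if (dist <= radius)
    stop("camera lies inside the target fruit")
  others <- fruits[-fruit, , drop = FALSE]
  if (nrow(others) > 0) {
    inside <- sqrt((others$x - cam[1])^2 + (others$y - cam[2])^2 +
                     (others$z - cam[3])^2) <= others$radius
    if (any(inside)) stop("camera lies inside an occluding fruit")
  }

  # orthonormal basis of the projected disc
  u <- d / dist
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .normalize(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  pts <- .with_seed(seed, {
    rho <- radius * sqrt(stats::runif(n_rays))
    ang <- 2 * pi * stats::runif(n_rays)
    centre + outer(e1, rho * cos(ang)) + outer(e2, rho * sin(ang))
  })

  discs <- scene$leaves
  if (!is.null(discs) && nrow(discs) > 0) {
    keep <- .prune_occluders(cam, centre, radius,
                             as.matrix(discs[, c("cx", "cy", "cz")]),
                             pmax(discs$semi_a, discs$semi_b))
    discs <- discs[keep, , drop = FALSE]
  }
  if (nrow(others) > 0) {
    keep <- .prune_occluders(cam, centre, radius,
                             as.matrix(others[, c("x", "y", "z")]),
                             others$radius)
    others <- others[keep, , drop = FALSE]
  }

  blocked <- .rays_blocked(cam, pts, discs = discs, spheres = others)
  100 * sum(!blocked) / n_rays
}

#' Quantize a visibility percentage to the discrete FV level set
#'
#' Maps a continuous visibility percentage to the nearest level of
#' [fv_levels()]; exact midpoints round toward the lower level (so 15 maps
#' to 10, and 2.5 to 0).
#'
#' @param fv numeric percentage(s) in `[0, 100]`.
#' @return Value(s) from the level set.
#' @examples
#' quantize_fv(c(47, 15, 100))  # 50, 10, 100
#' @export
quantize_fv <- function(fv) {
  if (any(fv < 0 | fv > 100)) stop("fv must lie in [0, 100]")
  levels <- fv_levels()
  vapply(fv, function(x) {
    d <- abs(levels - x)
    cand <- which(d == min(d))
    levels[cand[1]]  # levels ascending: first tie is the lower level
  }, numeric(1))
}
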