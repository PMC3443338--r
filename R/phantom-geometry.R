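#' Truncated-cone (or cylindrical) phantom specification
#'
#' Constructs the geometric description of a solid scatter phantom: either a
#' truncated cone whose diameter grows linearly along the axis, or a uniform
#' cylinder. The coordinate convention is a right-handed frame with the
#' phantom axis along z and z = 0 at the small end; all lengths are held in
#' cm internally.
#'
#' For a cone the taper angle `theta_deg` (the half-angle between the lateral
#' surface and the axis) ties the length to the end diameters:
#' `L = (max_diameter - min_diameter) / (2 tan theta)`. If `length` is
#' omitted it is derived from that relation; if supplied it must agree with
#' it to within 0.05 cm.
#'
#' Line-source channels are carried as metadata only (`hole_offsets_mm`,
#' `hole_diameter_mm`): geometrically the phantom is solid, matching the
#' study design where unused holes are plugged with solid fillings and the
#' active source is an ideal line.
#'
#' @param shape `"cone"` or `"cylinder"`.
#' @param min_diameter,max_diameter End diameters in cm (equal for a
#'   cylinder).
#' @param theta_deg Taper angle in degrees (cone only; 0 for a cylinder).
#' @param length Axial length in cm; derived from the taper relation when
#'   `NULL` (cone) but required for a cylinder.
#' @param density Material density in g/cm^3 (default: high-density
#'   polyethylene, 0.96).
#' @param hole_offsets_mm Radial offsets (mm) of the line-source channels.
#' @param hole_diameter_mm Channel diameter (mm), metadata only.
#' @return An object of class `phantom_spec`.
#' @seealso [default_cone_phantom()], [diameter_at()], [chord_length()]
#' @export
phantom_spec <- function(shape = c("cone", "cylinder"),
                         min_diameter, max_diameter,
                         theta_deg = NULL, length = NULL,
                         density = 0.96,
                         hole_offsets_mm = c(0, 10, 15, 20),
                         hole_diameter_mm = 4) {
  shape <- match.arg(shape)
  stopifnot(min_diameter > 0, max_diameter >= min_diameter, density > 0)
  if (shape == "cylinder") {
    if (!isTRUE(all.equal(min_diameter, max_diameter)))
      stop("a cylinder must have equal end diameters", call. = FALSE)
    theta_deg <- 0
    if (is.null(length)) stop("cylinder length must be given", call. = FALSE)
  } else {
    if (is.null(theta_deg))
      stop("cone requires a taper angle", call. = FALSE)
    if (theta_deg <= 0 && max_diameter > min_diameter)
      stop("invalid geometry: unequal diameters need a positive taper angle",
           call. = FALSE)
    L_rel <- phantom_length(min_diameter, max_diameter, theta_deg)
    if (is.null(length)) {
      length <- L_rel
    } else if (abs(length - L_rel) > 0.05) {
      stop(sprintf(
        "length %.3f cm inconsistent with taper relation (expected %.3f cm)",
        length, L_rel), call. = FALSE)
    }
  }
  structure(list(
    shape = shape,
    min_diameter = min_diameter,
    max_diameter = max_diameter,
    theta_deg = theta_deg,
    length = length,
    density = density,
    hole_offsets_mm = hole_offsets_mm,
    hole_diameter_mm = hole_diameter_mm
  ), class = "phantom_spec")
}

#' The fabricated cone phantom
#'
#' Default instance: minimum diameter 2 cm, maximum diameter 7 cm, taper
#' angle 9 degrees (length 15.8 cm), high-density polyethylene at
#' 0.96 g/cm^3, line-source channels at 0/10/15/20 mm radial offset with
#' 4 mm bore.
#'
#' @return A `phantom_spec`.
#' @export
default_cone_phantom <- function() {
  phantom_spec("cone", min_diameter = 2, max_diameter = 7, theta_deg = 9)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, d = %.2f-%.2f cm, theta = %g deg, L = %.2f cm, rho = %.2f g/cm^3\n",
              x$shape, x$min_diameter, x$max_diameter, x$theta_deg,
              x$length, x$density))
  invisible(x)
}

#' Phantom length from the taper relation
#'
#' `L = (max_diameter - min_diameter) / (2 tan theta)`: the axial length of a
#' truncated cone with the given end diameters and taper angle. Equal
#' diameters give length 0 for any angle.
#'
#' @param min_diameter,max_diameter End diameters, cm.
#' @param theta_deg Taper angle, degrees, in (0, 90).
#' @return Length in cm.
#' @examples
#' phantom_length(2, 7, 9)   # 15.8 cm phantom
#' @export
phantom_length <- function(min_diameter, max_diameter, theta_deg) {
  stopifnot(max_diameter >= min_diameter)
  if (max_diameter == min_diameter) return(0)
  if (theta_deg <= 0 || theta_deg >= 90)
    stop("invalid geometry: taper angle must lie in (0, 90) degrees",
         call. = FALSE)
  (max_diameter - min_diameter) / (2 * tan(theta_deg * pi / 180))
}

tan_theta <- function(phantom) tan(phantom$theta_deg * pi / 180)

#' Phantom diameter at an axial position
#'
#' Linear cone profile: `min_diameter + 2 z tan(theta)`, clamped to the end
#' diameters; z = 0 at the small end.
#'
#' @param phantom A `phantom_spec`.
#' @param z Axial position(s), cm, in `[0, L]`.
#' @return Diameter(s) in cm.
#' @export
diameter_at <- function(phantom, z) {
  if (any(z < -1e-9 | z > phantom$length + 1e-9))
    stop("z out of range [0, L]", call. = FALSE)
  d <- phantom$min_diameter + 2 * z * tan_theta(phantom)
  pmin(pmax(d, phantom$min_diameter), phantom$max_diameter)
}

#' Axial field-of-view segments of the phantom
#'
#' Splits the phantom into the three acquisition segments used to emulate
#' different animal sizes: `FOV_mouse` starts at the small end,
#' `FOV_rabbit` ends at the large end, and `FOV_rat` is centered on the
#' phantom midpoint (configurable via `rat_center`). Segments overlap when
#' three axial FOVs exceed the phantom length.
#'
#' @param phantom A `phantom_spec`.
#' @param axial_fov Scanner axial field of view, cm; must not exceed the
#'   phantom length.
#' @param rat_center Axial center of the middle segment, cm
#'   (default: phantom midpoint).
#' @return A list of three `fov_segment` objects named `FOV_mouse`,
#'   `FOV_rat`, `FOV_rabbit`.
#' @export
fov_segments <- function(phantom, axial_fov, rat_center = phantom$length / 2) {
  if (axial_fov > phantom$length + 1e-9)
    stop("axial FOV exceeds phantom length", call. = FALSE)
  seg <- function(name, z0) {
    z0 <- min(max(z0, 0), phantom$length - axial_fov)
    fov_segment(name, z0, z0 + axial_fov,
                diameter_at(phantom, z0), diameter_at(phantom, z0 + axial_fov))
  }
  list(
    FOV_mouse  = seg("FOV_mouse", 0),
    FOV_rat    = seg("FOV_rat", rat_center - axial_fov / 2),
    FOV_rabbit = seg("FOV_rabbit", phantom$length - axial_fov)
  )
}

#' Axial segment of a phantom seen by one acquisition
#'
#' @param name Segment label (`FOV_mouse`, `FOV_rat`, `FOV_rabbit` or
#'   custom).
#' @param z_start,z_end Axial bounds in the phantom frame, cm.
#' @param min_diameter,max_diameter Phantom diameters at the two bounds, cm.
#' @return An object of class `fov_segment`.
#' @export
fov_segment <- function(name, z_start, z_end, min_diameter, max_diameter) {
  stopifnot(z_end > z_start, min_diameter > 0,
            max_diameter >= min_diameter)
  structure(list(name = name, z_start = z_start, z_end = z_end,
                 min_diameter = min_diameter, max_diameter = max_diameter),
            class = "fov_segment")
}

#' @export
print.fov_segment <- function(x, ...) {
  cat(sprintf("<fov_segment> %s: z = [%.2f, %.2f] cm, d = %.2f-%.2f cm\n",
              x$name, x$z_start, x$z_end, x$min_diameter, x$max_diameter))
  invisible(x)
}

#' Equivalent-volume cylinder of a segment
#'
#' The EVC phantom is the uniform cylinder whose diameter equals the cone
#' diameter at the middle of the axial FOV (the mean of the segment end
#' diameters) and whose length equals the segment length.
#'
#' @param segment A `fov_segment`.
#' @return A list with `diameter` and `length` (cm), class `evc_spec`.
#' @export
evc_of <- function(segment) {
  stopifnot(inherits(segment, "fov_segment"))
  structure(list(
    diameter = (segment$min_diameter + segment$max_diameter) / 2,
    length = segment$z_end - segment$z_start
  ), class = "evc_spec")
}

#' Build the cylindrical phantom realizing an EVC specification
#'
#' @param evc An `evc_spec` (or a list with `diameter` and `length` in cm).
#' @param density Material density, g/cm^3.
#' @return A `phantom_spec` cylinder.
#' @export
evc_phantom <- function(evc, density = 0.96) {
  phantom_spec("cylinder", min_diameter = evc$diameter,
               max_diameter = evc$diameter, length = evc$length,
               density = density)
}

# Boundary-crossing candidates of a ray with the phantom surface.
# Positions px/py/pz and directions dx/dy/dz are equal-length vectors; the
# solid is {x^2 + y^2 <= r(z)^2, 0 <= z <= L} with r(z) = r0 + z tan(theta),
# which is convex, so the inside set along any line is a single interval.
# Returns an n x 4 matrix of candidate parameters t (NA where absent):
# two lateral-surface (quadric) roots and two cap-plane crossings.
.boundary_candidates <- function(phantom, px, py, pz, dx, dy, dz) {
  m <- tan_theta(phantom)
  r0 <- phantom$min_diameter / 2
  L <- phantom$length
  # lateral surface: (px+t dx)^2 + (py+t dy)^2 = (r0 + (pz+t dz) m)^2
  A <- dx^2 + dy^2 - (m * dz)^2
  B <- 2 * (px * dx + py * dy - m * dz * (r0 + pz * m))
  C <- px^2 + py^2 - (r0 + pz * m)^2
  disc <- B^2 - 4 * A * C
  sq <- sqrt(pmax(disc, 0))
  ok <- disc >= 0 & abs(A) > 1e-14
  t1 <- ifelse(ok, (-B - sq) / (2 * A), NA_real_)
  t2 <- ifelse(ok, (-B + sq) / (2 * A), NA_real_)
  # linear degenerate case (ray parallel to the cone surface direction)
  lin <- abs(A) <= 1e-14 & abs(B) > 1e-14
  t1[lin] <- (-C / B)[lin]
  # cap planes z = 0 and z = L
  tz0 <- ifelse(abs(dz) > 1e-14, (0 - pz) / dz, NA_real_)
  tzL <- ifelse(abs(dz) > 1e-14, (L - pz) / dz, NA_real_)
  cbind(t1, t2, tz0, tzL)
}

.inside_phantom <- function(phantom, x, y, z, tol = 1e-9) {
  r <- phantom$min_diameter / 2 + pmax(z, 0) * tan_theta(phantom)
  z >= -tol & z <= phantom$length + tol & x^2 + y^2 <= (r + tol)^2
}

#' Chord length of a ray through the phantom material
#'
#' Total path length of the ray `origin + t * direction` (t real) inside the
#' solid phantom; 0 if the ray misses. Used for attenuation path lengths.
#' Vectorized over rows when `origin`/`direction` are matrices.
#'
#' @param phantom A `phantom_spec`.
#' @param origin Numeric length-3 vector (or n x 3 matrix), cm.
#' @param direction Unit length-3 vector (or n x 3 matrix).
#' @return Chord length(s) in cm.
#' @export
chord_length <- function(phantom, origin, direction) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  nrm <- sqrt(rowSums(direction^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("direction must be a unit vector", call. = FALSE)
  px <- origin[, 1]; py <- origin[, 2]; pz <- origin[, 3]
  dx <- direction[, 1]; dy <- direction[, 2]; dz <- direction[, 3]
  cand <- .boundary_candidates(phantom, px, py, pz, dx, dy, dz)
  n <- nrow(cand)
  out <- numeric(n)
  # sort candidates per ray; the inside set is one interval, so summing the
  # inside sub-intervals between consecutive candidates is exact
  for (i in seq_len(n)) {
    ts <- sort(cand[i, !is.na(cand[i, ])])
    if (length(ts) < 2) next
    mids <- (ts[-1] + ts[-length(ts)]) / 2
    len <- diff(ts)
    ins <- .inside_phantom(phantom,
                           px[i] + mids * dx[i],
                           py[i] + mids * dy[i],
                           pz[i] + mids * dz[i], tol = 0)
    out[i] <- sum(len[ins])
  }
  if (n == 1) out[[1]] else out
}

# Distance from a point inside the phantom to the surface along direction d.
# Vectorized; the smallest positive boundary candidate whose crossing point
# actually lies on the solid's boundary is the exit (convexity).
.dist_to_exit <- function(phantom, px, py, pz, dx, dy, dz) {
  cand <- .boundary_candidates(phantom, px, py, pz, dx, dy, dz)
  cand[!is.finite(cand) | cand <= 1e-12] <- Inf
  out <- rep(Inf, length(px))
  for (k in 1:4) {
    tk <- cand[, k]
    use <- is.finite(tk) & tk < out
    if (!any(use)) next
    x <- px[use] + tk[use] * dx[use]
    y <- py[use] + tk[use] * dy[use]
    z <- pz[use] + tk[use] * dz[use]
    valid <- .inside_phantom(phantom, x, y, z, tol = 1e-7)
    idx <- which(use)[valid]
    out[idx] <- tk[use][valid]
  }
  out
}
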