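# Dosimetry for unidirectional heavy-ion (broad) beams: fluence/LET/dose
# conversion, parametric depth-LET (Bragg) profiles, ion range scaling, and
# the irradiated band of an oval body cross-section.

# J per keV, and the um*cm^2/kg unit-conversion factor of the dose equation
.KEV_TO_J <- 1.602e-16
.UNIT_FACTOR <- 1.0e7

#' Describe a heavy-ion beam
#'
#' Bundles the constants of an accelerator beam line: ion species, specific
#' energy, surface linear energy transfer (LET) and the dose-rate interval at
#' which exposures were delivered.
#'
#' @param ion_label character label such as `"12C6+"`.
#' @param mass_number mass number A (positive integer).
#' @param atomic_number atomic number Z (positive integer, `<= mass_number`).
#' @param energy_mev_per_u kinetic energy per nucleon in MeV/u (`>= 0`).
#' @param surface_let_kev_um LET at the entry surface in keV/um (`> 0`).
#' @param dose_rate_gy_s numeric length-2, min and max dose rate in Gy/s.
#' @return an object of class `beam_spec`.
#' @examples
#' carbon_beam()
#' @export
beam_spec <- function(ion_label, mass_number, atomic_number,
                      energy_mev_per_u, surface_let_kev_um,
                      dose_rate_gy_s = c(0, 0)) {
  if (!is_count(mass_number) || mass_number <= 0)
    abort_domain("mass_number must be a positive integer")
  if (!is_count(atomic_number) || atomic_number <= 0)
    abort_domain("atomic_number must be a positive integer")
  if (atomic_number > mass_number)
    abort_domain("atomic_number must not exceed mass_number")
  if (!is_scalar_num(energy_mev_per_u) || energy_mev_per_u < 0)
    abort_domain("energy_mev_per_u must be >= 0")
  if (!is_scalar_num(surface_let_kev_um) || surface_let_kev_um <= 0)
    abort_domain("surface_let_kev_um must be > 0")
  dose_rate_gy_s <- as.numeric(dose_rate_gy_s)
  if (length(dose_rate_gy_s) != 2L || any(dose_rate_gy_s < 0) ||
      dose_rate_gy_s[1] > dose_rate_gy_s[2])
    abort_domain("dose_rate_gy_s must be c(min, max) with 0 <= min <= max")
  structure(
    list(ion_label = as.character(ion_label),
         mass_number = as.integer(mass_number),
         atomic_number = as.integer(atomic_number),
         energy_mev_per_u = energy_mev_per_u,
         surface_let_kev_um = surface_let_kev_um,
         dose_rate_gy_s = dose_rate_gy_s),
    class = "beam_spec")
}

#' The 26.7 MeV/u carbon beam used for localized fish irradiation
#'
#' Convenience constructor for a 12C6+ beam with 78.4 keV/um surface LET and
#' a 0.75-1.50 Gy/s dose-rate window.
#'
#' @return a [beam_spec()].
#' @export
carbon_beam <- function() {
  beam_spec("12C6+", 12L, 6L, 26.7, 78.4, c(0.75, 1.50))
}

#' Convert particle fluence to absorbed dose
#'
#' Absorbed dose of a uniform unidirectional beam:
#' dose (Gy = J/kg) = fluence (/cm^2) x LET (keV/um) x 1e7 (um cm^2/kg)
#' x 1.602e-16 (J/keV). Exactly linear in both arguments.
#'
#' @param fluence_per_cm2 particle fluence in particles/cm^2 (`>= 0`).
#' @param let_kev_um LET in keV/um (`> 0`). Vectorised.
#' @return dose in Gy.
#' @examples
#' fluence_to_dose(1.1943e8, 78.4) # ~15 Gy
#' @export
fluence_to_dose <- function(fluence_per_cm2, let_kev_um) {
  if (!is.numeric(fluence_per_cm2) || any(!is.finite(fluence_per_cm2)) ||
      any(fluence_per_cm2 < 0))
    abort_domain("fluence_per_cm2 must be finite and >= 0")
  if (!is.numeric(let_kev_um) || any(!is.finite(let_kev_um)) ||
      any(let_kev_um <= 0))
    abort_domain("let_kev_um must be finite and > 0")
  fluence_per_cm2 * let_kev_um * .UNIT_FACTOR * .KEV_TO_J
}

#' Convert absorbed dose to particle fluence
#'
#' Exact algebraic inverse of [fluence_to_dose()].
#'
#' @param dose_gy dose in Gy (`>= 0`).
#' @param let_kev_um LET in keV/um (`> 0`). Vectorised.
#' @return fluence in particles/cm^2.
#' @examples
#' dose_to_fluence(15, 78.4)
#' @export
dose_to_fluence <- function(dose_gy, let_kev_um) {
  if (!is.numeric(dose_gy) || any(!is.finite(dose_gy)) || any(dose_gy < 0))
    abort_domain("dose_gy must be finite and >= 0")
  if (!is.numeric(let_kev_um) || any(!is.finite(let_kev_um)) ||
      any(let_kev_um <= 0))
    abort_domain("let_kev_um must be finite and > 0")
  dose_gy / (let_kev_um * .UNIT_FACTOR * .KEV_TO_J)
}

#' Parametric depth-LET (Bragg) profile
#'
#' Fit-free interpolant pinned to four beam constants: surface LET, peak LET,
#' range in water-equivalent tissue, and Bragg-peak width. The entrance
#' plateau rises as a power law in residual range with the Bragg-Kleeman
#' exponent (1 - 1/p, p = 1.77), calibrated so it reaches a shoulder value at
#' the peak depth; a Gaussian of FWHM `peak_width_mm`, centred at
#' `range_mm - peak_width_mm / 2`, supplies the rest of the peak. LET is 0
#' beyond the range.
#'
#' @param range_mm particle range in mm (`> peak_width_mm`).
#' @param surface_let_kev_um LET at depth 0 (`< peak_let_kev_um`).
#' @param peak_let_kev_um maximum LET, attained at the Bragg peak.
#' @param peak_width_mm full width at half maximum of the peak, mm.
#' @param n_points number of coarse depth samples over `[0, range_mm]`; a
#'   dense sub-grid is always added around the peak.
#' @param shoulder_frac fraction of the surface-to-peak LET rise carried by
#'   the plateau at the peak depth (the Gaussian carries the remainder).
#' @return an object of class `depth_let_profile` with fields `depth_mm`,
#'   `let_kev_um`, `range_mm`, `peak_depth_mm`.
#' @examples
#' pr <- bragg_profile(2.2, 78.4, 800, 0.010)
#' let_at(pr, c(0, pr$peak_depth_mm, 3))
#' @export
bragg_profile <- function(range_mm, surface_let_kev_um, peak_let_kev_um,
                          peak_width_mm = 0.010, n_points = 512L,
                          shoulder_frac = 0.5) {
  if (!is_scalar_num(range_mm) || range_mm <= 0)
    abort_domain("range_mm must be > 0")
  if (!is_scalar_num(peak_width_mm) || peak_width_mm <= 0 ||
      peak_width_mm >= range_mm)
    abort_domain("peak_width_mm must satisfy 0 < peak_width_mm < range_mm")
  if (!is_scalar_num(surface_let_kev_um) || surface_let_kev_um <= 0)
    abort_domain("surface_let_kev_um must be > 0")
  if (!is_scalar_num(peak_let_kev_um) ||
      peak_let_kev_um <= surface_let_kev_um)
    abort_domain("peak_let_kev_um must exceed surface_let_kev_um")
  if (!is_scalar_num(shoulder_frac) || shoulder_frac <= 0 ||
      shoulder_frac >= 1)
    abort_domain("shoulder_frac must lie in (0, 1)")

  z_peak <- range_mm - peak_width_mm / 2
  q <- 1 - 1 / 1.77  # Bragg-Kleeman: LET ~ (residual range)^(1/p - 1)
  shoulder <- surface_let_kev_um +
    shoulder_frac * (peak_let_kev_um - surface_let_kev_um)
  # effective range such that the capped plateau hits `shoulder` at z_peak
  r <- (shoulder / surface_let_kev_um)^(1 / q)
  r_eff <- z_peak * r / (r - 1)

  depth <- sort(unique(c(
    seq(0, range_mm, length.out = max(16L, as.integer(n_points))),
    seq(max(0, z_peak - 3 * peak_width_mm),
        min(range_mm, z_peak + 3 * peak_width_mm),
        by = peak_width_mm / 20),
    z_peak, range_mm)))
  plateau <- surface_let_kev_um * (r_eff / (r_eff - pmin(depth, z_peak)))^q
  sigma <- peak_width_mm / (2 * sqrt(2 * log(2)))
  amp <- peak_let_kev_um - shoulder
  let <- plateau + amp * exp(-(depth - z_peak)^2 / (2 * sigma^2))
  # append explicit zeros beyond the range so interpolation is closed
  eps <- peak_width_mm / 1e3
  depth <- c(depth, range_mm + eps, range_mm * 1.5)
  let <- c(let, 0, 0)

  structure(
    list(depth_mm = depth, let_kev_um = let,
         range_mm = range_mm, peak_depth_mm = z_peak),
    class = "depth_let_profile")
}

#' Evaluate a depth-LET profile
#'
#' Linear interpolation on the stored grid; 0 beyond the range.
#'
#' @param profile a `depth_let_profile`.
#' @param depth_mm numeric vector of depths in mm (`>= 0`).
#' @return LET in keV/um at each depth.
#' @export
let_at <- function(profile, depth_mm) {
  stopifnot(inherits(profile, "depth_let_profile"))
  if (any(depth_mm < 0)) abort_domain("depth_mm must be >= 0")
  out <- stats::approx(profile$depth_mm, profile$let_kev_um, xout = depth_mm,
                       rule = 2)$y
  out[depth_mm > profile$range_mm] <- 0
  out
}

#' Write / read a depth-LET profile as 2-column CSV
#'
#' @param profile a `depth_let_profile`.
#' @param path CSV path; columns `depth_mm`, `let_kev_um`.
#' @return `write_let_profile` returns `path` invisibly; `read_let_profile`
#'   returns a `depth_let_profile`.
#' @export
write_let_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_let_profile"))
  utils::write.csv(
    data.frame(depth_mm = profile$depth_mm,
               let_kev_um = profile$let_kev_um),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_let_profile
#' @export
read_let_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("depth_mm", "let_kev_um") %in% names(df)))
    abort_domain("profile CSV must have columns depth_mm, let_kev_um")
  rng <- max(df$depth_mm[df$let_kev_um > 0])
  structure(
    list(depth_mm = df$depth_mm, let_kev_um = df$let_kev_um,
         range_mm = rng,
         peak_depth_mm = df$depth_mm[which.max(df$let_kev_um)]),
    class = "depth_let_profile")
}

#' Approximate ion range in water
#'
#' Bragg-Kleeman power law for protons in water, R_p = 0.0022 E^1.77 cm,
#' scaled to a heavier ion of mass number A and charge Z by the A/Z^2
#' velocity-scaling rule. An approximation, accurate to roughly +-15% at the
#' low specific energies used for localized fish irradiation; full
#' energy-loss transport codes remain the reference.
#'
#' @param energy_mev_per_u kinetic energy per nucleon, MeV/u (`>= 0`).
#' @param mass_number mass number A.
#' @param atomic_number atomic number Z.
#' @return range in mm of water.
#' @examples
#' ion_range_water(26.7, 12, 6) # ~2.5 mm; transport-code value ~2.2 mm
#' @export
ion_range_water <- function(energy_mev_per_u, mass_number, atomic_number) {
  if (!is_count(mass_number) || mass_number <= 0 ||
      !is_count(atomic_number) || atomic_number <= 0)
    abort_domain("mass_number and atomic_number must be positive integers")
  if (!is.numeric(energy_mev_per_u) || any(energy_mev_per_u < 0))
    abort_domain("energy_mev_per_u must be >= 0")
  proton_range_cm <- 0.0022 * energy_mev_per_u^1.77
  10 * proton_range_cm * mass_number / atomic_number^2
}

#' Body cross-section geometry
#'
#' The transverse cross-section of the fish, either an ellipse (half-width,
#' half-height) or a simple closed polygon, oriented dorsal side up.
#'
#' @param half_width_mm,half_height_mm ellipse semi-axes in mm (`> 0`).
#' @return an object of class `cross_section`.
#' @export
cross_section_ellipse <- function(half_width_mm, half_height_mm) {
  if (!is_scalar_num(half_width_mm) || half_width_mm <= 0 ||
      !is_scalar_num(half_height_mm) || half_height_mm <= 0)
    abort_domain("ellipse semi-axes must be > 0")
  structure(list(shape = "ellipse", half_width_mm = half_width_mm,
                 half_height_mm = half_height_mm),
            class = "cross_section")
}

#' @rdname cross_section_ellipse
#' @param x_mm,y_mm polygon vertex coordinates in mm (y increases ventrally,
#'   i.e. downwards from the dorsal side); the polygon is closed implicitly.
#' @export
cross_section_polygon <- function(x_mm, y_mm) {
  if (length(x_mm) != length(y_mm) || length(x_mm) < 3L)
    abort_domain("polygon needs >= 3 vertices with equal-length x and y")
  if (.polygon_self_intersects(x_mm, y_mm))
    abort_domain("polygon must be simple (non-self-intersecting)")
  structure(list(shape = "polygon", x_mm = x_mm, y_mm = y_mm),
            class = "cross_section")
}

# brute-force segment pair test; cross-sections have few vertices
.polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, x[c(2:n, 1)], y[c(2:n, 1)])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through closure
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

.cross_section_inside <- function(cs, xx, yy) {
  if (cs$shape == "ellipse") {
    (xx / cs$half_width_mm)^2 + (yy / cs$half_height_mm)^2 <= 1
  } else {
    pts <- cbind(as.vector(xx), as.vector(yy))
    ins <- mgcv::in.out(cbind(c(cs$x_mm, cs$x_mm[1]), c(cs$y_mm, cs$y_mm[1])),
                        pts)
    matrix(ins, nrow = nrow(xx))
  }
}

#' Irradiated region of a body cross-section
#'
#' For a parallel beam entering from one side, marks every grid point that
#' lies inside the cross-section and whose depth along the beam axis,
#' measured from the entry surface on its own ray, is `<=` the particle
#' range (closed interval, so the mask is monotone in range). Row 1 of the
#' returned matrices is the dorsal side.
#'
#' @param cross_section a [cross_section_ellipse()] or
#'   [cross_section_polygon()].
#' @param direction one of `"dorsal"`, `"ventral"`, `"lateral-left"`,
#'   `"lateral-right"` (the side the beam enters from).
#' @param range_mm particle range in mm (`> 0`).
#' @param resolution_mm grid resolution, mm per pixel (`> 0`).
#' @return list with logical matrices `inside` and `irradiated` (rows =
#'   dorsoventral axis, dorsal first), the pixel-centre coordinates `x_mm`
#'   (lateral) and `y_mm` (depth from the dorsal side), and `resolution_mm`.
#' @export
irradiated_mask <- function(cross_section, direction, range_mm,
                            resolution_mm) {
  stopifnot(inherits(cross_section, "cross_section"))
  direction <- match.arg(direction,
                         c("dorsal", "ventral", "lateral-left",
                           "lateral-right"))
  if (!is_scalar_num(range_mm) || range_mm <= 0)
    abort_domain("range_mm must be > 0")
  if (!is_scalar_num(resolution_mm) || resolution_mm <= 0)
    abort_domain("resolution_mm must be > 0")

  if (cross_section$shape == "ellipse") {
    hw <- cross_section$half_width_mm; hh <- cross_section$half_height_mm
  } else {
    hw <- max(abs(cross_section$x_mm)); hh <- max(abs(cross_section$y_mm))
  }
  # symmetric pixel-centre grids about the section centre
  half_grid <- function(h, res) {
    n <- 2L * ceiling(h / res) + 1L
    (seq_len(n) - (n + 1L) / 2L) * res
  }
  x <- half_grid(hw, resolution_mm)           # lateral, left -> right
  y <- half_grid(hh, resolution_mm)           # dorsal -> ventral
  xx <- matrix(x, nrow = length(y), ncol = length(x), byrow = TRUE)
  yy <- matrix(y, nrow = length(y), ncol = length(x))
  inside <- .cross_section_inside(cross_section, xx, yy)
  if (!any(inside)) abort_domain("cross-section contains no grid points")

  depth <- .ray_depth(inside, direction) * resolution_mm
  irr <- inside & !is.na(depth) & depth <= range_mm
  list(inside = inside, irradiated = irr,
       x_mm = x, y_mm = y, resolution_mm = resolution_mm,
       direction = direction, range_mm = range_mm)
}

# per-ray depth in pixels from the first inside pixel along the beam axis
.ray_depth <- function(inside, direction) {
  flip_r <- direction == "ventral"
  transpose <- direction %in% c("lateral-left", "lateral-right")
  m <- inside
  if (transpose) m <- t(m)
  if (flip_r || direction == "lateral-right") m <- m[nrow(m):1, , drop = FALSE]
  d <- matrix(NA_real_, nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) {
    first <- which(m[, j])[1]
    if (!is.na(first)) d[, j] <- seq_len(nrow(m)) - first
  }
  if (flip_r || direction == "lateral-right") d <- d[nrow(d):1, , drop = FALSE]
  if (transpose) d <- t(d)
  d
}

#' Fraction of an organ mask inside the irradiated region
#'
#' @param organ_mask logical matrix marking the organ on the same grid as
#'   `irradiated`.
#' @param irradiated logical matrix from [irradiated_mask()] (its
#'   `$irradiated` field) or any congruent mask.
#' @return fraction of organ pixels that are irradiated, in `[0, 1]`.
#' @export
fraction_irradiated <- function(organ_mask, irradiated) {
  if (is.list(irradiated)) irradiated <- irradiated$irradiated
  if (!identical(dim(organ_mask), dim(irradiated)))
    abort_domain("organ and irradiation masks must share a grid")
  n_organ <- sum(organ_mask)
  if (n_organ == 0) abort_domain("organ mask is empty")
  sum(organ_mask & irradiated) / n_organ
}

#' Write a binary mask as an 8-bit PNG (0 = outside, 255 = marked)
#'
#' @param mask logical or 0/1 matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
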