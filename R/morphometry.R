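# Serial-section 3D morphometry: translation registration of ordered labeled
# sections, anisotropic voxel volumetry, blood-cell composition profiles and
# dorsal/ventral regional comparison.

LABEL_BACKGROUND <- 0L
LABEL_KIDNEY <- 1L
LABEL_BLOOD <- 2L

#' Ordered stack of labeled serial sections
#'
#' @param labels integer array `H x W x S` with labels 0 (background),
#'   1 (kidney tissue), 2 (blood cell; blood pixels lie inside the kidney).
#'   Row 1 is the dorsal side; sections are ordered anterior to posterior.
#' @param pixel_size_um in-plane pixel size, um/pixel (isotropic).
#' @param section_thickness_um section thickness in um (default 5).
#' @return an object of class `section_stack`.
#' @export
section_stack <- function(labels, pixel_size_um, section_thickness_um = 5) {
  d <- dim(labels)
  if (length(d) == 2L) { labels <- array(labels, c(d, 1L)); d <- dim(labels) }
  if (length(d) != 3L) abort_domain("labels must be an H x W x S array")
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad))
    abort_domain("labels outside {0,1,2}: ", paste(bad, collapse = ", "))
  if (!is_scalar_num(pixel_size_um) || pixel_size_um <= 0)
    abort_domain("pixel_size_um must be > 0")
  if (!is_scalar_num(section_thickness_um) || section_thickness_um <= 0)
    abort_domain("section_thickness_um must be > 0")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um),
            class = "section_stack")
}

# integer translation with background padding
.translate_int <- function(m, dr, dc) {
  out <- array(0L, dim(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# shift maximizing the circular cross-correlation of two binary masks,
# via 2-D FFT; returns c(dr, dc) such that translating b by (dr, dc)
# best overlays a. When one mask can slide inside the other the correlation
# peak is a plateau (e.g. concentric sections of different radii); ties are
# broken toward the centroid-difference shift, which is exact for
# concentric shapes.
.mask_shift <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  ties <- which(cc >= max(cc) - 0.5)  # binary overlap counts: integers
  dr <- (ties - 1L) %% nr
  dc <- (ties - 1L) %/% nr
  dr <- ifelse(dr > nr / 2, dr - nr, dr)
  dc <- ifelse(dc > nc / 2, dc - nc, dc)
  cen <- function(m) {
    w <- sum(m)
    c(sum(.row(dim(m)) * m), sum(.col(dim(m)) * m)) / w
  }
  target <- cen(a) - cen(b)
  best <- which.min((dr - target[1])^2 + (dc - target[2])^2)
  c(dr[best], dc[best])
}

#' Register a section stack by translation
#'
#' Translation-only registration of the ordered sections. Each section is
#' registered to its nearest already-aligned non-empty neighbour, propagating
#' cumulative shifts outwards from a reference section (default the middle),
#' by maximizing the cross-correlation of the foreground (non-background)
#' masks. Label images are shifted by the rounded offset with background
#' padding. Sections with empty foreground inherit the shift of their
#' nearest non-empty neighbour and are flagged.
#'
#' @param stack a [section_stack()].
#' @param reference index of the reference section (shift fixed at 0,0);
#'   defaults to the middle section.
#' @return list with `aligned` (a `section_stack`), `shifts` (`S x 2` matrix
#'   of row/col shifts in pixels), `reference_index`, and `flagged` (indices
#'   of empty-foreground sections).
#' @export
align_stack <- function(stack, reference = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  S <- dim(stack$labels)[3]
  if (is.null(reference)) reference <- (S + 1L) %/% 2L
  if (!is_count(reference) || reference < 1L || reference > S)
    abort_domain("reference index out of bounds")
  masks <- lapply(seq_len(S), function(i)
    (stack$labels[, , i] > 0L) * 1.0)
  nonempty <- vapply(masks, function(m) any(m > 0), TRUE)
  if (!nonempty[reference]) {
    cand <- which(nonempty)
    if (length(cand) == 0L) {
      # nothing to register; identity result
      return(list(aligned = stack,
                  shifts = matrix(0, S, 2,
                                  dimnames = list(NULL, c("d_row", "d_col"))),
                  reference_index = reference, flagged = seq_len(S)))
    }
    reference <- cand[which.min(abs(cand - reference))]
  }

  shifts <- matrix(NA_real_, S, 2)
  shifts[reference, ] <- c(0, 0)
  flagged <- integer(0)
  for (dir in c(1L, -1L)) {
    last_idx <- reference
    i <- reference + dir
    while (i >= 1L && i <= S) {
      if (!nonempty[i]) {
        shifts[i, ] <- shifts[last_idx, ]
        flagged <- c(flagged, i)
      } else {
        pair <- .mask_shift(masks[[last_idx]], masks[[i]])
        shifts[i, ] <- shifts[last_idx, ] + pair
        last_idx <- i
      }
      i <- i + dir
    }
  }
  aligned <- stack$labels
  for (i in seq_len(S)) {
    if (shifts[i, 1] != 0 || shifts[i, 2] != 0)
      aligned[, , i] <- .translate_int(stack$labels[, , i],
                                       round(shifts[i, 1]),
                                       round(shifts[i, 2]))
  }
  colnames(shifts) <- c("d_row", "d_col")
  list(aligned = section_stack(aligned, stack$pixel_size_um,
                               stack$section_thickness_um),
       shifts = shifts, reference_index = reference,
       flagged = sort(unique(flagged)))
}

#' Tissue volume from voxel counts
#'
#' Volume of the voxels carrying any of the requested labels, using the
#' anisotropic voxel size `pixel_size^2 x thickness`.
#'
#' @param stack a [section_stack()].
#' @param labels integer labels to count (default kidney + blood, i.e. the
#'   whole organ).
#' @return volume in um^3.
#' @export
tissue_volume <- function(stack, labels = c(LABEL_KIDNEY, LABEL_BLOOD)) {
  stopifnot(inherits(stack, "section_stack"))
  if (length(labels) && !all(labels %in% 0:2))
    abort_domain("unknown label requested: ",
                 paste(setdiff(labels, 0:2), collapse = ", "))
  n <- sum(stack$labels %in% labels)
  n * stack$pixel_size_um^2 * stack$section_thickness_um
}

#' Blood-cell composition profile along the stack
#'
#' Per section, the fraction of organ voxels labeled as blood cells:
#' `blood / (kidney + blood)`. Sections with no organ voxels yield `NA` and
#' are excluded from the voxel-weighted total.
#'
#' @param stack a [section_stack()].
#' @return list with `per_section` (numeric vector, `NA` where the organ is
#'   absent), `total` (voxel-weighted overall fraction),
#'   `blood_voxel_count`, and `organ_voxel_count`.
#' @export
blood_cell_profile <- function(stack) {
  stopifnot(inherits(stack, "section_stack"))
  S <- dim(stack$labels)[3]
  blood <- kidney <- numeric(S)
  for (i in seq_len(S)) {
    sec <- stack$labels[, , i]
    blood[i] <- sum(sec == LABEL_BLOOD)
    kidney[i] <- sum(sec == LABEL_KIDNEY)
  }
  organ <- blood + kidney
  per <- ifelse(organ > 0, blood / organ, NA_real_)
  list(per_section = per,
       total = if (sum(organ) > 0) sum(blood) / sum(organ) else NA_real_,
       blood_voxel_count = sum(blood), organ_voxel_count = sum(organ))
}

#' Dorsal/ventral (and in-field/out-of-field) blood fractions
#'
#' Splits the organ at the horizontal plane through its volumetric centroid
#' row and reports the blood fraction in each half. If a per-section
#' irradiation mask is supplied (e.g. derived from [irradiated_mask()]), the
#' blood fraction inside versus outside the irradiated field is reported as
#' well.
#'
#' @param stack a [section_stack()] (typically the aligned stack).
#' @param irradiated optional logical array of the same `H x W x S` shape
#'   (or an `H x W` matrix recycled over sections) marking irradiated
#'   voxels.
#' @param split_row optional row index overriding the centroid split.
#' @return list with `dorsal_fraction`, `ventral_fraction`, `split_row`,
#'   and, when a mask is given, `infield_fraction` and `outfield_fraction`.
#'   Regions without organ voxels yield `NA`.
#' @export
regional_split <- function(stack, irradiated = NULL, split_row = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  lab <- stack$labels
  organ <- lab == LABEL_KIDNEY | lab == LABEL_BLOOD
  if (!any(organ)) abort_domain("stack contains no organ voxels")
  rows <- slice.index(lab, 1L)
  if (is.null(split_row)) split_row <- sum(rows[organ]) / sum(organ)

  frac_in <- function(sel) {
    n_org <- sum(organ & sel)
    if (n_org == 0) return(NA_real_)
    sum((lab == LABEL_BLOOD) & sel) / n_org
  }
  out <- list(dorsal_fraction = frac_in(rows <= split_row),
              ventral_fraction = frac_in(rows > split_row),
              split_row = split_row)
  if (!is.null(irradiated)) {
    if (is.matrix(irradiated))
      irradiated <- array(irradiated, dim(lab))
    if (!identical(dim(irradiated), dim(lab)))
      abort_domain("irradiation mask shape must match the stack")
    out$infield_fraction <- frac_in(irradiated)
    out$outfield_fraction <- frac_in(!irradiated)
  }
  out
}

#' Full volumetry report
#'
#' Convenience wrapper producing organ volume, blood composition profile and
#' the dorsal/ventral split in one structure.
#'
#' @param stack a [section_stack()] (typically aligned).
#' @param irradiated optional irradiation mask, as in [regional_split()].
#' @return an object of class `volume_report`.
#' @export
volume_report <- function(stack, irradiated = NULL) {
  prof <- blood_cell_profile(stack)
  split <- regional_split(stack, irradiated)
  structure(
    list(kidney_volume_um3 = tissue_volume(stack),
         blood_voxel_count = prof$blood_voxel_count,
         blood_fraction = prof$total,
         per_section_profile = prof$per_section,
         dorsal_fraction = split$dorsal_fraction,
         ventral_fraction = split$ventral_fraction,
         infield_fraction = split$infield_fraction,
         outfield_fraction = split$outfield_fraction,
         pixel_size_um = stack$pixel_size_um,
         section_thickness_um = stack$section_thickness_um),
    class = "volume_report")
}

#' Export an aligned labeled volume as multipage TIFF
#'
#' Writes one 8-bit grayscale page per section (labels stored verbatim as
#' small integers) plus a JSON sidecar `<path>.json` carrying the physical
#' voxel metadata, so the volume can be rendered externally.
#'
#' @param stack a [section_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
export_volume <- function(stack, path) {
  stopifnot(inherits(stack, "section_stack"))
  S <- dim(stack$labels)[3]
  pages <- lapply(seq_len(S), function(i) stack$labels[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         section_thickness_um = stack$section_thickness_um,
         n_sections = S, dorsal_row0 = TRUE),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
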