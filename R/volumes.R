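#' Dose volume
#'
#' A 3D scalar grid of absorbed dose, either in Gy or as a normalized fraction
#' after min-max scaling. The voxel grid is a base-R array with dims
#' `(nx, ny, nz)`; `spacing` gives the physical voxel size in mm per axis.
#'
#' @param values 3D numeric array of dose values, all finite, `>= 0` in Gy
#'   mode and in `[0, 1]` in normalized mode.
#' @param spacing numeric length-3, mm per axis.
#' @param normalized logical; if `TRUE`, `range` records the `(min, max)` used
#'   so the volume can be mapped back to Gy.
#' @param range numeric length-2 `(min, max)` of the original values; required
#'   when `normalized = TRUE`.
#' @return An object of class `dose_volume`.
#' @export
dose_volume <- function(values, spacing = c(1, 1, 1), normalized = FALSE, range = NULL) {
  values <- as_volume_array(values)
  if (!all(is.finite(values))) stop("dose values must all be finite")
  if (normalized) {
    if (is.null(range) || length(range) != 2) {
      stop("a normalized dose_volume requires the (min, max) `range` used")
    }
    if (min(values) < -1e-9 || max(values) > 1 + 1e-9) {
      stop("normalized dose values must lie in [0, 1]")
    }
  } else if (min(values) < 0) {
    stop("dose in Gy must be non-negative")
  }
  structure(
    list(values = values, spacing = as.numeric(spacing),
         normalized = isTRUE(normalized), range = range),
    class = "dose_volume"
  )
}

#' @export
print.dose_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_volume> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              if (x$normalized) sprintf("normalized (range %.3g..%.3g Gy)",
                                        x$range[1], x$range[2])
              else sprintf("Gy (max %.2f)", max(x$values))))
  invisible(x)
}

# Coerce dose_volume or plain array to a 3D array.
as_volume_array <- function(v) {
  if (inherits(v, "dose_volume")) v <- v$values
  if (is.null(dim(v)) || length(dim(v)) != 3) stop("expected a 3D array")
  v
}

#' Structure set
#'
#' Named binary masks on one voxel grid, each tagged as a target volume
#' (PTV/CTV/GTV) or an organ at risk.
#'
#' @param masks named list of 3D arrays with values in `{0, 1}`, all with the
#'   same dims.
#' @param roles named character vector, one of `"target"` or `"oar"` per
#'   structure; defaults to `"target"` for names containing TV (PTV, CTV,
#'   GTV) and `"oar"` otherwise.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, roles = NULL) {
  if (length(masks) == 0) stop("structure_set needs at least one mask")
  if (is.null(names(masks)) || anyDuplicated(names(masks)))
    stop("masks must be uniquely named")
  shp <- dim(masks[[1]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), shp)) stop("mask '", nm, "' is not on the case grid")
    if (!all(m %in% c(0, 1))) stop("mask '", nm, "' has values outside {0, 1}")
    storage.mode(masks[[nm]]) <- "double"
  }
  if (is.null(roles)) {
    roles <- ifelse(grepl("tv", names(masks), ignore.case = TRUE), "target", "oar")
    names(roles) <- names(masks)
  }
  roles <- roles[names(masks)]
  if (!all(roles %in% c("target", "oar"))) stop("roles must be 'target' or 'oar'")
  structure(list(masks = masks, roles = roles), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures (%d target, %d oar)\n",
              length(x$masks), sum(x$roles == "target"), sum(x$roles == "oar")))
  invisible(x)
}

#' Plan case
#'
#' One unit of training/evaluation: a CT-like volume, its delineated
#' structures, the clinically delivered reference dose and the prescription.
#'
#' @param ct 3D scalar array (e.g. HU-like intensities).
#' @param structures a [structure_set()] on the same grid.
#' @param reference_dose a [dose_volume()] (the ground-truth dose), same grid.
#' @param prescription prescribed dose in Gy, `> 0`.
#' @param case_id character identifier.
#' @param spacing mm per axis.
#' @return An object of class `plan_case`.
#' @export
plan_case <- function(ct, structures, reference_dose, prescription,
                      case_id = "case", spacing = c(1, 1, 1)) {
  ct <- as_volume_array(ct)
  if (!inherits(structures, "structure_set")) stop("structures must be a structure_set")
  if (!inherits(reference_dose, "dose_volume"))
    reference_dose <- dose_volume(reference_dose, spacing = spacing)
  shp <- dim(ct)
  if (!identical(dim(structures$masks[[1]]), shp) ||
      !identical(dim(reference_dose$values), shp))
    stop("ct, masks and reference dose must share one grid shape")
  if (!is.numeric(prescription) || prescription <= 0) stop("prescription must be > 0")
  structure(
    list(ct = ct, structures = structures, reference_dose = reference_dose,
         prescription = prescription, case_id = as.character(case_id),
         spacing = as.numeric(spacing)),
    class = "plan_case"
  )
}

#' @export
print.plan_case <- function(x, ...) {
  d <- dim(x$ct)
  cat(sprintf("<plan_case> '%s': %d x %d x %d, %d structures, prescription %.0f Gy\n",
              x$case_id, d[1], d[2], d[3], length(x$structures$masks), x$prescription))
  invisible(x)
}

#' Downscale a volume in-plane
#'
#' Reduces the first two (axial in-plane) axes by an integer factor, the way
#' 512 x 512 planning CTs are brought down to 128 x 128 before training. Scalar
#' volumes are resampled with separable cubic spline interpolation; binary
#' masks should use `mask = TRUE`, which interpolates linearly and thresholds
#' at 0.5 so the output stays binary. The cranio-caudal axis is untouched.
#'
#' @param v 3D array (or [dose_volume()]).
#' @param factor integer `>= 1`; each in-plane axis shrinks to
#'   `ceiling(n / factor)`.
#' @param order interpolation order: 3 (cubic spline, default), 1 (linear) or
#'   0 (nearest).
#' @param mask if `TRUE`, interpolate linearly then threshold at 0.5.
#' @return 3D array with dims `(ceiling(nx/factor), ceiling(ny/factor), nz)`.
#' @export
downscale_volume <- function(v, factor, order = 3, mask = FALSE) {
  v <- as_volume_array(v)
  if (length(factor) != 1 || is.na(factor) || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(v)
  if (mask) order <- 1
  for (axis in 1:2) v <- resample_axis(v, axis, factor, order)
  if (mask) {
    v <- (v >= 0.5) * 1
  }
  v
}

# Resample one axis of a 3D array down by `factor` (target ceiling(n/factor)),
# sampling at destination voxel centres mapped back to source coordinates.
resample_axis <- function(v, axis, factor, order) {
  d <- dim(v)
  n <- d[axis]
  n_out <- ceiling(n / factor)
  coords <- (seq_len(n_out) - 0.5) * factor + 0.5
  coords <- pmin(pmax(coords, 1), n)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(v, perm), nrow = n)
  out <- switch(as.character(order),
    "0" = m[pmin(pmax(round(coords), 1), n), , drop = FALSE],
    "1" = apply(m, 2, function(col) approx(seq_len(n), col, xout = coords)$y),
    apply(m, 2, function(col) splinefun(seq_len(n), col, method = "natural")(coords))
  )
  out <- array(out, c(n_out, d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Min-max normalization
#'
#' Rescales a volume linearly to the exact range `[0, 1]` and records the
#' `(min, max)` needed to invert the mapping.
#'
#' @param v 3D array (or [dose_volume()]).
#' @return A list with `values` (normalized array), `min` and `max`.
#' @seealso [minmax_denormalize()]
#' @export
minmax_normalize <- function(v) {
  v <- as_volume_array(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate input: constant volume cannot be min-max normalized")
  list(values = (v - lo) / (hi - lo), min = lo, max = hi)
}

#' Invert a min-max normalization
#'
#' @param values normalized array in `[0, 1]`.
#' @param min,max the range recorded by [minmax_normalize()].
#' @return Array on the original scale.
#' @export
minmax_denormalize <- function(values, min, max) {
  as_volume_array(values) * (max - min) + min
}

#' Assemble network input channels
#'
#' Stacks the min-max-normalized CT as channel 1 followed by one binary mask
#' channel per requested structure, in the given order. Structures absent from
#' the case become all-zero channels, which keeps the channel count fixed
#' across a cohort with incomplete delineations.
#'
#' @param case a [plan_case()].
#' @param structure_order character vector of structure names (no duplicates).
#' @return 4D array `(nx, ny, nz, 1 + length(structure_order))` with channel
#'   names in `attr(, "channels")`.
#' @export
assemble_channels <- function(case, structure_order) {
  if (anyDuplicated(structure_order)) stop("duplicate structure names in structure_order")
  shp <- dim(case$ct)
  nc <- 1L + length(structure_order)
  x <- array(0, c(shp, nc))
  x[, , , 1] <- minmax_normalize(case$ct)$values
  for (k in seq_along(structure_order)) {
    nm <- structure_order[k]
    if (nm %in% names(case$structures$masks)) {
      x[, , , k + 1L] <- case$structures$masks[[nm]]
    }
  }
  attr(x, "channels") <- c("CT", structure_order)
  x
}
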