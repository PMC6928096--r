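#' Parametric phantom specification
#'
#' Describes the digital two-zone prostate phantom: an outer peripheral
#' zone modelled as a superellipsoid filling a `width_mm` x `depth_mm` x
#' `height_mm` bounding box, a coaxial central zone scaled per axis by
#' `central_zone_scale`, and a cylindrical urethra of radius
#' `urethra_radius_mm` along the slicing (height) axis. The phantom is
#' embedded in an agar block extending `embedding_margin_mm` beyond the
#' bounding box laterally, and sliced perpendicular to the urethra at
#' `slice_spacing_mm`.
#'
#' The default superellipsoid exponent 1.732 makes the default
#' 40 x 32 x 35 mm phantom close to the 20 cm^3 volume of an average
#' prostate (a plain ellipsoid in that box would be 23.5 cm^3).
#'
#' @param width_mm,depth_mm,height_mm outer bounding box of the
#'   peripheral zone (default 40 x 32 x 35)
#' @param central_zone_scale per-axis fraction of the outer semi-axes,
#'   each in (0,1); scalar or length-3 (x, y, z)
#' @param urethra_radius_mm radius of the urethra lumen (default 2)
#' @param slice_spacing_mm spacing between imaging slices (default 0.5)
#' @param pixel_spacing_mm in-plane pixel size (default 0.2)
#' @param n_slices number of imaging slices (default 60, centered on the
#'   phantom)
#' @param embedding_margin_mm agar block margin around the bounding box
#' @param shape_exponent superellipsoid exponent p in
#'   `|x/a|^p + |y/b|^p + |z/c|^p <= 1`; 2 gives an ellipsoid
#' @return object of class `phantom_spec`
#' @export
#' @examples
#' spec <- phantom_spec(n_slices = 20)
#' vol <- build_phantom(spec)
phantom_spec <- function(width_mm = 40, depth_mm = 32, height_mm = 35,
                         central_zone_scale = 0.65,
                         urethra_radius_mm = 2,
                         slice_spacing_mm = 0.5,
                         pixel_spacing_mm = 0.2,
                         n_slices = 60L,
                         embedding_margin_mm = 5,
                         shape_exponent = 1.732) {
  if (length(central_zone_scale) == 1L)
    central_zone_scale <- rep(central_zone_scale, 3L)
  spec <- structure(list(
    width_mm = width_mm, depth_mm = depth_mm, height_mm = height_mm,
    central_zone_scale = central_zone_scale,
    urethra_radius_mm = urethra_radius_mm,
    slice_spacing_mm = slice_spacing_mm,
    pixel_spacing_mm = pixel_spacing_mm,
    n_slices = as.integer(n_slices),
    embedding_margin_mm = embedding_margin_mm,
    shape_exponent = shape_exponent
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  w <- "phantom_spec"
  for (f in c("width_mm", "depth_mm", "height_mm", "urethra_radius_mm",
              "slice_spacing_mm", "pixel_spacing_mm", "shape_exponent"))
    check_positive(spec[[f]], f, w)
  if (spec$embedding_margin_mm < 0)
    stop_invalid(w, "'embedding_margin_mm' must be >= 0")
  s <- spec$central_zone_scale
  if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop_invalid(w, "'central_zone_scale' must be axis-wise in (0,1)")
  semi <- c(spec$width_mm, spec$depth_mm, spec$height_mm) / 2 * s
  if (spec$urethra_radius_mm >= min(semi[1:2]))
    stop_invalid(w, "'urethra_radius_mm' must be smaller than the smallest central semi-axis")
  if (spec$n_slices < 1L)
    stop_invalid(w, "'n_slices' must be >= 1")
  # slices may run into the embedding agar, but not beyond the block
  if (spec$n_slices * spec$slice_spacing_mm >
      spec$height_mm + 2 * spec$embedding_margin_mm)
    stop_invalid(w, "n_slices * slice_spacing_mm exceeds the embedded block height")
  invisible(spec)
}

## Pixel-center coordinate axes (mm, origin at the urethra axis).
grid_axes <- function(spec) {
  psp <- spec$pixel_spacing_mm
  nx <- 2L * ceiling((spec$width_mm / 2 + spec$embedding_margin_mm) / psp)
  ny <- 2L * ceiling((spec$depth_mm / 2 + spec$embedding_margin_mm) / psp)
  list(x = (seq_len(nx) - (nx + 1) / 2) * psp,
       y = (seq_len(ny) - (ny + 1) / 2) * psp)
}

## z coordinate (mm) of each slice, centered on the phantom equator.
slice_z <- function(spec) {
  (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) * spec$slice_spacing_mm
}

## Cross-section semi-axes of a superellipsoid at height z, or NULL when
## the slice misses the body.
cross_section <- function(z, a, b, c, p) {
  m <- 1 - (abs(z) / c)^p
  if (m <= 0) return(NULL)
  list(a = a * m^(1 / p), b = b * m^(1 / p))
}

#' Build the pre-surgery ground-truth label volume
#'
#' Rasterizes the phantom described by a [phantom_spec()] into an ordered
#' stack of label slices. Labels: BACKGROUND (embedding agar or outside
#' the phantom), PERIPHERAL, CENTRAL, CAVITY (the water-filled urethra
#' lumen). A pixel belongs to a region when its center lies inside the
#' continuous boundary. Deterministic: no randomness is involved.
#'
#' @param spec a [phantom_spec()]
#' @return object of class `label_volume`: integer array
#'   `[x, y, slice]` with attributes `pixel_spacing_mm`,
#'   `slice_spacing_mm`, `spec`
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  ax <- grid_axes(spec)
  z <- slice_z(spec)
  p <- spec$shape_exponent
  ao <- spec$width_mm / 2; bo <- spec$depth_mm / 2; co <- spec$height_mm / 2
  s <- spec$central_zone_scale
  nx <- length(ax$x); ny <- length(ax$y)
  X <- matrix(ax$x, nx, ny)
  Y <- matrix(ax$y, nx, ny, byrow = TRUE)
  R2 <- X^2 + Y^2
  vol <- array(LBL[["BACKGROUND"]], dim = c(nx, ny, spec$n_slices))
  for (k in seq_along(z)) {
    sl <- matrix(LBL[["BACKGROUND"]], nx, ny)
    cs_out <- cross_section(z[k], ao, bo, co, p)
    if (!is.null(cs_out)) {
      inside_out <- superellipse_val(X, Y, cs_out$a, cs_out$b, p) <= 1
      sl[inside_out] <- LBL[["PERIPHERAL"]]
      cs_in <- cross_section(z[k], ao * s[1], bo * s[2], co * s[3], p)
      if (!is.null(cs_in)) {
        inside_in <- superellipse_val(X, Y, cs_in$a, cs_in$b, p) <= 1
        sl[inside_in] <- LBL[["CENTRAL"]]
      }
      sl[R2 <= spec$urethra_radius_mm^2 & sl != LBL[["BACKGROUND"]]] <-
        LBL[["CAVITY"]]
    }
    vol[, , k] <- sl
  }
  new_label_volume(vol, spec)
}

new_label_volume <- function(arr, spec, meta = list()) {
  structure(arr,
            pixel_spacing_mm = spec$pixel_spacing_mm,
            slice_spacing_mm = spec$slice_spacing_mm,
            spec = spec, meta = meta,
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cnt <- table(factor(as.vector(x), levels = LBL, labels = names(LBL)))
  cat(sprintf("<label_volume> %d x %d px, %d slices (%.3g x %.3g mm px, %.3g mm spacing)\n",
              d[1], d[2], d[3], attr(x, "pixel_spacing_mm"),
              attr(x, "pixel_spacing_mm"), attr(x, "slice_spacing_mm")))
  print(cnt)
  invisible(x)
}

## Extract one label slice as a plain integer matrix.
label_slice <- function(vol, k) {
  m <- vol[, , k]
  attr(m, "pixel_spacing_mm") <- attr(vol, "pixel_spacing_mm")
  m
}

#' Physical volume of the phantom tissue
#'
#' Voxel count of PERIPHERAL + CENTRAL + CAVITY times the voxel volume,
#' in cm^3. Note this measures only the slices present in the volume.
#'
#' @param vol a `label_volume`
#' @return volume in cm^3
#' @export
phantom_volume_cm3 <- function(vol) {
  psp <- attr(vol, "pixel_spacing_mm")
  ssp <- attr(vol, "slice_spacing_mm")
  sum(vol != LBL[["BACKGROUND"]]) * psp * psp * ssp / 1000
}
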