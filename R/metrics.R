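#' Minimum peripheral-zone thickness of a label slice
#'
#' The thinnest escape path through the peripheral layer: the minimum,
#' over boundary pixels of the inner region (CAVITY plus CENTRAL), of
#' the Euclidean distance to the nearest BACKGROUND pixel, in mm.
#' Returns 0 when the inner region touches BACKGROUND (8-adjacency),
#' i.e. at a perforation, and NA when the slice has no peripheral or no
#' inner pixels (the slice is then invalid for metrics).
#'
#' @param labels integer label matrix
#' @param pixel_spacing_mm pixel size in mm (defaults to the matrix
#'   attribute, else 1)
#' @return thickness in mm (0 at perforation; NA for invalid slices)
#' @export
min_peripheral_thickness <- function(labels,
                                     pixel_spacing_mm = attr(labels, "pixel_spacing_mm")) {
  if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- 1
  bg <- labels == LBL[["BACKGROUND"]]
  inner <- labels == LBL[["CAVITY"]] | labels == LBL[["CENTRAL"]]
  if (!any(labels == LBL[["PERIPHERAL"]]) || !any(inner) || !any(bg))
    return(NA_real_)
  bnd <- mask_boundary(inner)
  d2 <- edt_sq(bg)
  if (min(d2[bnd]) <= 2) return(0)  # 8-adjacent to background
  sqrt(min(d2[bnd])) * pixel_spacing_mm
}

## Shape descriptors of a cavity mask. Circularity is computed from a
## single self-consistent sub-pixel polygon (marching-squares 0.5-level
## contour of the mask, Douglas-Peucker simplified) using that polygon's
## own shoelace area and perimeter; this removes the half-pixel bias
## that makes pixel-count area inconsistent with a sub-pixel perimeter.
## Solidity uses the MATLAB-regionprops "convex image" convention
## (pixel-center hull, rasterized, unioned with the mask), which is
## exactly 1 for rasterizations of convex regions.
cavity_shape <- function(mask, pixel_spacing_mm = 1, simplify_eps_px = 0.9,
                         min_pixels = 5L) {
  out <- list(area_mm2 = NA_real_, conv_area_mm2 = NA_real_,
              perimeter_mm = NA_real_, circularity = NA_real_,
              solidity = NA_real_, valid = FALSE)
  npx <- sum(mask)
  if (npx < min_pixels) return(out)
  polys <- mask_contours(mask)
  if (!length(polys)) return(out)
  outer_poly <- polys[[which.max(vapply(polys, nrow, 1L))]]
  q <- rdp_closed(outer_poly, simplify_eps_px)
  if (nrow(q) < 3L) return(out)
  P <- poly_perimeter(q) * pixel_spacing_mm
  A_poly <- poly_area(q) * pixel_spacing_mm^2
  conv <- convex_image(mask)
  out$area_mm2 <- npx * pixel_spacing_mm^2
  out$conv_area_mm2 <- sum(conv) * pixel_spacing_mm^2
  out$perimeter_mm <- P
  out$circularity <- 4 * pi * A_poly / P^2
  out$solidity <- npx / sum(conv)
  out$valid <- is.finite(out$circularity) && out$circularity > 0
  out
}

#' Circularity of a cavity mask
#'
#' `4 * pi * A / P^2` computed from the simplified sub-pixel contour
#' polygon of the mask (see Details in [evaluate_case()]); 1 for a
#' perfect disc, `pi/4` for a square.
#'
#' @param mask logical matrix (the cavity region)
#' @param pixel_spacing_mm pixel size in mm
#' @return circularity (NA for degenerate regions under 5 pixels)
#' @export
#' @examples
#' m <- matrix(FALSE, 40, 40); m[10:30, 10:30] <- TRUE
#' circularity(m)  # ~ pi/4
circularity <- function(mask, pixel_spacing_mm = 1) {
  cavity_shape(mask, pixel_spacing_mm)$circularity
}

#' Solidity (resection smoothness) of a cavity mask
#'
#' Region pixel count divided by the pixel count of its convex image;
#' exactly 1 for convex regions, below 1 for ragged boundaries.
#'
#' @inheritParams circularity
#' @return solidity in (0, 1] (NA for degenerate regions)
#' @export
solidity <- function(mask, pixel_spacing_mm = 1) {
  cavity_shape(mask, pixel_spacing_mm)$solidity
}

slice_metrics_row <- function(labels, pixel_spacing_mm) {
  cav <- labels == LBL[["CAVITY"]]
  shp <- cavity_shape(cav, pixel_spacing_mm)
  data.frame(T_min_peri_mm = min_peripheral_thickness(labels, pixel_spacing_mm),
             A_uret_mm2 = shp$area_mm2,
             A_conv_mm2 = shp$conv_area_mm2,
             P_uret_mm = shp$perimeter_mm,
             C = shp$circularity,
             solidity = shp$solidity,
             shape_valid = shp$valid)
}

#' Per-slice shape metrics of a label volume
#'
#' @param vol a `label_volume`
#' @param flags optional `segmentation_result` flags data.frame; flagged
#'   slices are marked invalid
#' @return data.frame with one row per slice: minimum peripheral
#'   thickness, cavity area/perimeter, convex area, circularity,
#'   solidity, validity
#' @export
slice_metrics <- function(vol, flags = NULL) {
  psp <- attr(vol, "pixel_spacing_mm")
  n <- dim(vol)[3]
  rows <- vector("list", n)
  for (k in seq_len(n)) rows[[k]] <- slice_metrics_row(vol[, , k], psp)
  df <- do.call(rbind, rows)
  df <- cbind(slice = seq_len(n), df)
  df$valid <- df$shape_valid & !is.na(df$T_min_peri_mm)
  if (!is.null(flags)) df$valid <- df$valid & !flags$flagged
  df
}

#' Preservation ratio of the peripheral zone
#'
#' Mean over paired valid slices of the post/pre ratio of minimum
#' peripheral thickness. 1.0 when no slice's safety margin decreased;
#' 0 contributions from perforated slices.
#'
#' @param pre,post per-slice metrics data.frames from [slice_metrics()]
#' @return list: `R_pres`, `n` (valid slice pairs), `excluded`
#'   (data.frame of excluded slices with reasons)
#' @export
preservation_ratio <- function(pre, post) {
  stopifnot(nrow(pre) == nrow(post))
  reason <- rep(NA_character_, nrow(pre))
  reason[!pre$valid | !post$valid] <- "invalid slice"
  ok <- is.na(reason)
  zero_pre <- ok & pre$T_min_peri_mm <= 0
  reason[zero_pre] <- "zero pre-surgery thickness"
  ok <- is.na(reason)
  if (!any(ok)) stop("no valid slice pairs", call. = FALSE)
  list(R_pres = mean(post$T_min_peri_mm[ok] / pre$T_min_peri_mm[ok]),
       n = sum(ok),
       excluded = data.frame(slice = pre$slice[!ok], reason = reason[!ok]))
}

#' Smoothness of the resection boundary
#'
#' Mean cavity solidity over valid post-surgery slices.
#'
#' @param post per-slice metrics data.frame from [slice_metrics()]
#' @return list: `R_smoo`, `n`
#' @export
smoothness <- function(post) {
  ok <- post$valid & !is.na(post$solidity) & post$A_conv_mm2 > 0
  if (!any(ok)) stop("no valid post-surgery slices", call. = FALSE)
  list(R_smoo = mean(post$solidity[ok]), n = sum(ok))
}

#' Circularity ratio
#'
#' Mean over paired valid slices of post/pre circularity.
#'
#' @inheritParams preservation_ratio
#' @return list: `R_circ`, `n`
#' @export
circularity_ratio <- function(pre, post) {
  stopifnot(nrow(pre) == nrow(post))
  ok <- pre$valid & post$valid & !is.na(pre$C) & !is.na(post$C) & pre$C > 0
  if (!any(ok)) stop("no valid slice pairs", call. = FALSE)
  list(R_circ = mean(post$C[ok] / pre$C[ok]), n = sum(ok))
}

#' Evaluate a pre/post case
#'
#' Computes per-slice metrics for both co-registered label stacks and
#' the three aggregate performance statistics: preservation ratio
#' (mean post/pre minimum peripheral thickness), smoothness (mean
#' cavity solidity after surgery) and circularity ratio (mean post/pre
#' circularity). A slice pair is excluded from all three means when
#' either slice is flagged or degenerate; exclusions are recorded with
#' reasons.
#'
#' @param pre_labels,post_labels co-registered `label_volume`s
#' @param pre_flags,post_flags optional segmentation flag data.frames
#' @param pre_metrics optional precomputed [slice_metrics()] of the pre
#'   stack (the pre-surgery phantom is deterministic, so its metrics can
#'   be shared across cases)
#' @return object of class `case_metrics`: list with `pre`, `post`
#'   per-slice data.frames, aggregates `R_pres`, `R_smoo`, `R_circ`,
#'   `n`, and `excluded`
#' @export
evaluate_case <- function(pre_labels, post_labels,
                          pre_flags = NULL, post_flags = NULL,
                          pre_metrics = NULL) {
  if (!identical(dim(pre_labels), dim(post_labels)))
    stop("pre and post label volumes must share the same grid", call. = FALSE)
  pre <- if (is.null(pre_metrics)) slice_metrics(pre_labels, pre_flags)
         else pre_metrics
  post <- slice_metrics(post_labels, post_flags)
  reason <- rep(NA_character_, nrow(pre))
  reason[is.na(reason) & (!pre$valid | !post$valid)] <- "invalid slice"
  reason[is.na(reason) & !(pre$T_min_peri_mm > 0)] <- "zero pre-surgery thickness"
  reason[is.na(reason) & !(pre$C > 0)] <- "degenerate pre-surgery cavity"
  both <- is.na(reason)
  if (!any(both)) stop("no valid slice pairs in case", call. = FALSE)
  pre$valid <- both
  post$valid <- both
  pres <- preservation_ratio(pre, post)
  smoo <- smoothness(post)
  circ <- circularity_ratio(pre, post)
  structure(list(pre = pre, post = post,
                 R_pres = pres$R_pres, R_smoo = smoo$R_smoo,
                 R_circ = circ$R_circ, n = sum(both),
                 excluded = data.frame(slice = pre$slice[!both],
                                       reason = reason[!both])),
            class = "case_metrics")
}

#' @export
print.case_metrics <- function(x, ...) {
  cat(sprintf("<case_metrics> n = %d valid slice pairs\n", x$n))
  cat(sprintf("  R_pres = %.4f  R_smoo = %.4f  R_circ = %.4f\n",
              x$R_pres, x$R_smoo, x$R_circ))
  invisible(x)
}
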