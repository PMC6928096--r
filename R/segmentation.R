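#' Segmentation parameters
#'
#' Controls the automated per-slice detection of background, peripheral
#' zone, central zone, and urethra/resection cavity.
#'
#' Strategy `"otsu"` picks the two intensity cut-points by exhaustive
#' two-threshold Otsu (maximum between-class variance on a 256-bin
#' histogram of the contrast-stretched slice); `"fixed"` uses the given
#' `thresholds`. Dark pixels connected to the image border become
#' BACKGROUND; the connected enclosed dark component containing (or
#' nearest to) the cavity seed point becomes CAVITY; mid pixels are
#' PERIPHERAL and bright pixels CENTRAL. Masks are cleaned by
#' morphological opening/closing with a Euclidean disc.
#'
#' @param strategy "otsu" or "fixed"
#' @param thresholds ordered pair of cut-points in \[0,1\] (used when
#'   `strategy = "fixed"`)
#' @param cleanup_radius_mm disc radius for morphological cleanup
#' @param min_region_area_mm2 components smaller than this are merged
#'   into their surroundings
#' @param seed_policy cavity seed: "center" (slice center) or
#'   "propagate" (centroid of the previous slice's cavity, falling back
#'   to the slice center)
#' @param stretch_quantiles intensity quantiles mapped to 0 and 1 by the
#'   deterministic contrast stretch applied before thresholding
#' @return object of class `segmentation_params`
#' @export
segmentation_params <- function(strategy = c("otsu", "fixed"),
                                thresholds = c(0.3, 0.68),
                                cleanup_radius_mm = 0.3,
                                min_region_area_mm2 = 1,
                                seed_policy = c("propagate", "center"),
                                stretch_quantiles = c(0.01, 0.99)) {
  strategy <- match.arg(strategy)
  seed_policy <- match.arg(seed_policy)
  sp <- structure(list(strategy = strategy,
                       thresholds = thresholds,
                       cleanup_radius_mm = cleanup_radius_mm,
                       min_region_area_mm2 = min_region_area_mm2,
                       seed_policy = seed_policy,
                       stretch_quantiles = stretch_quantiles),
                  class = "segmentation_params")
  validate_segmentation_params(sp)
  sp
}

validate_segmentation_params <- function(sp) {
  w <- "segmentation_params"
  if (length(sp$thresholds) != 2L || diff(sp$thresholds) <= 0)
    stop_invalid(w, "'thresholds' must be a strictly ordered pair")
  if (sp$cleanup_radius_mm < 0) stop_invalid(w, "'cleanup_radius_mm' must be >= 0")
  if (sp$min_region_area_mm2 < 0) stop_invalid(w, "'min_region_area_mm2' must be >= 0")
  invisible(sp)
}

## Exhaustive two-threshold Otsu on a 256-bin histogram. Returns the two
## cut-points (bin upper edges) maximizing between-class variance.
otsu2 <- function(x, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  P <- cumsum(p)
  M <- cumsum(p * mids)
  mu_t <- M[nbins]
  # class [i+1, j]: weight P[j]-P[i], mean (M[j]-M[i])/w  (P[0]=M[0]=0)
  P0 <- c(0, P); M0 <- c(0, M)
  best <- c(-Inf, 1L, 2L)
  for (i in seq_len(nbins - 2L)) {       # first cut after bin i
    w1 <- P0[i + 1L]
    if (w1 <= 0) next
    m1 <- M0[i + 1L] / w1
    j <- (i + 1L):(nbins - 1L)           # second cut after bin j
    w2 <- P0[j + 1L] - P0[i + 1L]
    w3 <- 1 - P0[j + 1L]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m2 <- (M0[j + 1L] - M0[i + 1L]) / w2
    m3 <- (mu_t - M0[j + 1L]) / w3
    v <- w1 * (m1 - mu_t)^2 + w2 * (m2 - mu_t)^2 + w3 * (m3 - mu_t)^2
    v[!ok] <- -Inf
    jb <- which.max(v)
    if (v[jb] > best[1]) best <- c(v[jb], i, j[jb])
  }
  c(best[2] / nbins, best[3] / nbins)
}

## Deterministic percentile contrast stretch to [0,1].
stretch_contrast <- function(img, q = c(0.01, 0.99)) {
  lo <- quantile(img, q[1], names = FALSE, type = 7)
  hi <- quantile(img, q[2], names = FALSE, type = 7)
  if (hi <= lo) return(img * 0)
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

#' Segment one pseudo-ultrasound slice
#'
#' Three-level intensity classification (dark / mid / bright) after a
#' deterministic contrast stretch, followed by morphological cleanup and
#' digital-topology-aware assignment of dark components: dark components
#' touching the image border become BACKGROUND; the enclosed dark
#' component containing (or nearest to) the cavity seed becomes CAVITY.
#' A slice with no enclosed dark component, or more than one surviving
#' cavity candidate after cleanup, is flagged rather than erroring.
#'
#' @param image numeric matrix, intensities in \[0,1\]
#' @param params a [segmentation_params()]
#' @param pixel_spacing_mm pixel size (defaults to the matrix attribute)
#' @param cavity_seed optional `(row, col)` seed point for the cavity
#'   (defaults to the slice center)
#' @return list: `labels` (integer matrix; NULL when flagged),
#'   `cavity_found`, `central_found`, `flagged`, `thresholds`
#' @export
segment_slice <- function(image, params = segmentation_params(),
                          pixel_spacing_mm = attr(image, "pixel_spacing_mm"),
                          cavity_seed = NULL) {
  validate_segmentation_params(params)
  if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- 1
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0,1]", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(cavity_seed)) cavity_seed <- c((nr + 1) / 2, (nc + 1) / 2)

  img <- stretch_contrast(image, params$stretch_quantiles)
  thr <- if (params$strategy == "otsu") otsu2(img) else params$thresholds

  r_px <- params$cleanup_radius_mm / pixel_spacing_mm
  dark <- img < thr[1]
  bright <- img >= thr[2]
  if (r_px > 0) {
    dark <- close_disc(open_disc(dark, r_px), r_px)
    bright <- close_disc(open_disc(bright, r_px), r_px)
  }
  bright <- bright & !dark

  labels <- matrix(LBL[["PERIPHERAL"]], nr, nc)
  labels[bright] <- LBL[["CENTRAL"]]

  min_px <- params$min_region_area_mm2 / pixel_spacing_mm^2
  # drop small bright islands into the peripheral class
  if (any(bright)) {
    comp_b <- label_components(bright, 8L)
    sizes <- tabulate(comp_b[comp_b > 0L])
    small <- which(sizes < min_px)
    if (length(small))
      labels[matrix(comp_b %in% small, nr, nc)] <- LBL[["PERIPHERAL"]]
  }

  ## Cavity candidates are dark pixels inside the tissue interior. The
  ## interior is the convex image of the tissue mask (the phantom's
  ## outer boundary is convex), which keeps a cavity detectable even
  ## when a peripheral breach connects it to the surrounding dark
  ## water/agar: the portion of the connected dark region that lies
  ## inside the tissue hull stays a cavity candidate.
  cavity_found <- FALSE
  labels[dark] <- LBL[["BACKGROUND"]]
  tissue <- !dark
  if (any(dark) && any(tissue)) {
    interior <- convex_image(tissue)
    cand <- dark & interior
    if (any(cand)) {
      comp <- label_components(cand, 8L)
      ids <- seq_len(attr(comp, "n"))
      sizes <- tabulate(comp, nbins = length(ids))
      ids <- ids[sizes >= max(min_px, 1)]
      if (length(ids)) {
        seed_id <- comp[round(cavity_seed[1]), round(cavity_seed[2])]
        pick <- if (seed_id %in% ids) seed_id else {
          cent <- vapply(ids, function(id) {
            ij <- which(comp == id, arr.ind = TRUE)
            colMeans(ij)
          }, numeric(2))
          ids[which.min((cent[1, ] - cavity_seed[1])^2 +
                        (cent[2, ] - cavity_seed[2])^2)]
        }
        cav <- fill_holes(comp == pick)
        labels[cav] <- LBL[["CAVITY"]]
        cavity_found <- TRUE
      }
    }
  }

  central_found <- any(labels == LBL[["CENTRAL"]])
  flagged <- !cavity_found
  list(labels = if (flagged) NULL else labels,
       cavity_found = cavity_found,
       central_found = central_found,
       flagged = flagged,
       thresholds = thr)
}

#' Segment a slice stack
#'
#' Applies [segment_slice()] to every slice, propagating the cavity seed
#' (previous slice's cavity centroid) along the stack when
#' `seed_policy = "propagate"`. The result is aligned index-to-index
#' with the input stack.
#'
#' @param stack a `slice_stack` (or 3D array in \[0,1\])
#' @param params a [segmentation_params()]
#' @return object of class `segmentation_result`: list with `labels`
#'   (label_volume with flagged slices all-BACKGROUND), `flags`
#'   (data.frame: slice, cavity_found, central_found, flagged) and
#'   `params`
#' @export
segment_stack <- function(stack, params = segmentation_params()) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("stack must be a non-empty 3D array", call. = FALSE)
  psp <- attr(stack, "pixel_spacing_mm")
  if (is.null(psp)) psp <- 1
  seed <- NULL
  labs <- array(LBL[["BACKGROUND"]], dim = d)
  flags <- data.frame(slice = seq_len(d[3]), cavity_found = FALSE,
                      central_found = FALSE, flagged = TRUE)
  for (k in seq_len(d[3])) {
    res <- segment_slice(stack[, , k], params, pixel_spacing_mm = psp,
                         cavity_seed = seed)
    flags$cavity_found[k] <- res$cavity_found
    flags$central_found[k] <- res$central_found
    flags$flagged[k] <- res$flagged
    if (!res$flagged) {
      labs[, , k] <- res$labels
      if (params$seed_policy == "propagate") {
        ij <- which(res$labels == LBL[["CAVITY"]], arr.ind = TRUE)
        seed <- colMeans(ij)
      }
    } else if (params$seed_policy == "propagate") {
      seed <- NULL  # restart from the slice center after a flagged slice
    }
  }
  vol <- structure(labs,
                   pixel_spacing_mm = psp,
                   slice_spacing_mm = attr(stack, "slice_spacing_mm"),
                   spec = NULL,
                   meta = list(segmentation = unclass(params)),
                   class = "label_volume")
  structure(list(labels = vol, flags = flags, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d slices, %d flagged\n",
              nrow(x$flags), sum(x$flags$flagged)))
  invisible(x)
}
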