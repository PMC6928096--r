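## Internal raster / polygon geometry shared by the generator,
## segmentation and metrics modules. All functions work in pixel units
## unless a pixel spacing is passed explicitly.

## Superellipse implicit value (|x/a|^p + |y/b|^p); the boundary is at 1.
superellipse_val <- function(x, y, a, b, p) {
  (abs(x) / a)^p + (abs(y) / b)^p
}

## Distance from interior point (cx, cy) to the superellipse boundary
## along directions theta (vectorized), by bisection. Returns 0 when the
## start point lies outside.
superellipse_ray <- function(cx, cy, theta, a, b, p, iters = 48L) {
  v0 <- superellipse_val(cx, cy, a, b, p)
  tmax <- rep(2 * (a + b), length(theta))
  lo <- rep(0, length(theta))
  hi <- tmax
  ct <- cos(theta); st <- sin(theta)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    inside <- superellipse_val(cx + mid * ct, cy + mid * st, a, b, p) <= 1
    lo <- ifelse(inside, mid, lo)
    hi <- ifelse(inside, hi, mid)
  }
  out <- (lo + hi) / 2
  out[v0 > 1] <- 0
  out
}

## Marching-squares 0.5-level contours of a binary mask, in pixel-center
## coordinates (row, col). Delegates to grDevices::contourLines.
mask_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask + 0
  cl <- contourLines(x = seq_len(nr + 2L) - 1L, y = seq_len(nc + 2L) - 1L,
                     z = padded, levels = 0.5)
  lapply(cl, function(cc) cbind(cc$x, cc$y))
}

## Ramer-Douglas-Peucker simplification of an open polyline.
rdp_open <- function(p, eps) {
  n <- nrow(p)
  if (n <= 2L) return(p)
  a <- p[1L, ]; b <- p[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len == 0) {
    sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2)
  } else {
    abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / len
  }
  i <- which.max(d)
  if (d[i] <= eps) return(p[c(1L, n), , drop = FALSE])
  left <- rdp_open(p[1:i, , drop = FALSE], eps)
  rbind(left[-nrow(left), , drop = FALSE], rdp_open(p[i:n, , drop = FALSE], eps))
}

## Closed-polygon simplification: anchor at two mutually distant
## vertices, simplify the two halves independently. Anchors are chosen
## by centroid distance (a rotation-invariant criterion) so that the
## simplification, and hence the perimeter, is stable under grid
## rotations of the mask.
rdp_closed <- function(p, eps) {
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  if (n <= 3L) return(p)
  ctr <- colMeans(p)
  i1 <- which.max((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  i2 <- which.max((p[, 1] - p[i1, 1])^2 + (p[, 2] - p[i1, 2])^2)
  o <- c(i1:n, seq_len(i1 - 1L))
  p <- p[o, , drop = FALSE]
  j <- which(o == i2)
  h1 <- rdp_open(p[1:j, , drop = FALSE], eps)
  h2 <- rdp_open(rbind(p[j:n, , drop = FALSE], p[1L, , drop = FALSE]), eps)
  rbind(h1[-nrow(h1), , drop = FALSE], h2[-nrow(h2), , drop = FALSE])
}

poly_perimeter <- function(p) {
  q <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

poly_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

## Convex hull of pixel-center coordinates of a mask; returns the hull
## polygon (clockwise, as grDevices::chull orders it) or NULL for < 3 px.
center_hull <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(NULL)
  h <- chull(idx[, 1], idx[, 2])
  idx[h, , drop = FALSE]
}

## Rasterized convex image: pixels whose centers fall inside (or on) the
## convex hull of the mask's pixel centers, unioned with the mask itself
## so the result is always a superset of the mask.
convex_image <- function(mask) {
  hp <- center_hull(mask)
  if (is.null(hp)) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- min(hp[, 1]):max(hp[, 1])
  ci <- min(hp[, 2]):max(hp[, 2])
  X <- matrix(ri, length(ri), length(ci))
  Y <- matrix(ci, length(ri), length(ci), byrow = TRUE)
  inside <- matrix(TRUE, length(ri), length(ci))
  n <- nrow(hp)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hp[j, 1] - hp[i, 1]
    ey <- hp[j, 2] - hp[i, 2]
    cr <- ex * (Y - hp[i, 2]) - ey * (X - hp[i, 1])
    inside <- inside & (cr <= 1e-9)  # chull() returns clockwise order
  }
  out <- mask
  out[ri, ci] <- out[ri, ci] | inside
  out
}

## Does any TRUE pixel of `mask_a` touch a TRUE pixel of `mask_b` under
## 8-connectivity?
masks_touch8 <- function(mask_a, mask_b) {
  if (!any(mask_a) || !any(mask_b)) return(FALSE)
  d <- edt_sq(mask_b)
  min(d[mask_a]) <= 2  # 8-neighbours are at squared distance 1 or 2
}

## Boundary pixels of a mask: TRUE pixels with at least one 4- or
## 8-neighbour outside the mask (8-connectivity of the complement is not
## needed here; any non-member neighbour qualifies).
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inn <- pad[2:(nr + 1L), 2:(nc + 1L)]
  all_n <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)] &
    pad[1:nr, 1:nc] & pad[1:nr, 3:(nc + 2L)] &
    pad[3:(nr + 2L), 1:nc] & pad[3:(nr + 2L), 3:(nc + 2L)]
  inn & !all_n
}

## Binary morphology with a Euclidean disc structuring element, built on
## the exact distance transform.
dilate_disc <- function(mask, r_px) {
  if (r_px <= 0 || !any(mask)) return(mask)
  edt_sq(mask) <= r_px^2
}

erode_disc <- function(mask, r_px) {
  if (r_px <= 0) return(mask)
  if (all(mask)) return(mask)
  edt_sq(!mask) > r_px^2
}

open_disc <- function(mask, r_px) dilate_disc(erode_disc(mask, r_px), r_px)
close_disc <- function(mask, r_px) erode_disc(dilate_disc(mask, r_px), r_px)

## Fill holes: components of the complement not connected to the border
## (4-connectivity for the complement, the standard digital-topology
## pairing with 8-connected foreground).
fill_holes <- function(mask) {
  comp <- label_components(!mask, 4L)
  border_labels <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                            comp[, ncol(comp)]))
  border_labels <- border_labels[border_labels > 0L]
  hole <- !(comp %in% c(0L, border_labels))
  dim(hole) <- dim(comp)
  mask | hole
}

## Separable Gaussian blur with kernel truncated at 3 sigma; kernel rows
## renormalized at the image border.
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  smooth_dim <- function(m) {
    n <- nrow(m)
    band <- matrix(0, n, n)
    for (o in (-half):half) {
      i <- seq_len(n)
      j <- i + o
      keep <- j >= 1L & j <= n
      band[cbind(i[keep], j[keep])] <- band[cbind(i[keep], j[keep])] +
        k[o + half + 1L]
    }
    band <- band / rowSums(band)
    band %*% m
  }
  t(smooth_dim(t(smooth_dim(img))))
}
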