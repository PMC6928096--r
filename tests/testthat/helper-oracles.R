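## Independent brute-force oracles and mask fixtures. Everything here is
## deliberately written without reusing the package's internal geometry
## helpers so that implementation and oracle stay on separate paths.

LBLS <- turp_labels()

## --- mask fixtures (built in code, no files) -------------------------

disc_mask <- function(r_px, n = ceiling(2 * r_px) + 7, cx = (n + 1) / 2,
                      cy = cx) {
  xs <- seq_len(n)
  outer(xs, xs, function(i, j) (i - cx)^2 + (j - cy)^2 <= r_px^2)
}

square_mask <- function(s, pad = 5L) {
  m <- matrix(FALSE, s + 2L * pad, s + 2L * pad)
  m[(pad + 1L):(pad + s), (pad + 1L):(pad + s)] <- TRUE
  m
}

## connected random blob: union of discs with centers on a random walk
blob_mask <- function(n = 64L, n_discs = 4L) {
  m <- matrix(FALSE, n, n)
  cx <- runif(1, n * 0.35, n * 0.65)
  cy <- runif(1, n * 0.35, n * 0.65)
  for (i in seq_len(n_discs)) {
    r <- runif(1, 3, 9)
    xs <- seq_len(n)
    m <- m | outer(xs, xs, function(a, b) (a - cx)^2 + (b - cy)^2 <= r^2)
    ang <- runif(1, 0, 2 * pi)
    step <- runif(1, 2, 7)
    cx <- min(max(cx + step * cos(ang), 12), n - 12)
    cy <- min(max(cy + step * sin(ang), 12), n - 12)
  }
  m
}

## annulus label slice: BACKGROUND outside, PERIPHERAL ring, CAVITY disc
## (optionally offset); pixel spacing psp mm
annulus_labels <- function(r_in_mm, r_out_mm, psp, offset_mm = 0,
                           margin_mm = 3) {
  half <- r_out_mm + margin_mm
  n <- 2L * ceiling(half / psp)
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * psp
  R2 <- outer(xs, xs, function(a, b) a^2 + b^2)
  R2in <- outer(xs, xs, function(a, b) (a - offset_mm)^2 + b^2)
  lab <- matrix(LBLS[["BACKGROUND"]], n, n)
  lab[R2 <= r_out_mm^2] <- LBLS[["PERIPHERAL"]]
  lab[R2in <= r_in_mm^2 & lab == LBLS[["PERIPHERAL"]]] <- LBLS[["CAVITY"]]
  attr(lab, "pixel_spacing_mm") <- psp
  lab
}

## --- oracles ---------------------------------------------------------

## gift-wrapping (Jarvis march) convex hull of a point matrix; scans all
## points for every hull edge
jarvis_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- integer()
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == n) 1L else p + 1L
    for (r in seq_len(n)) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    p <- q
    if (p == start) break
  }
  pts[hull, , drop = FALSE]
}

## pixel count of the convex image under the package's stated
## convention (pixel-center hull, rasterized at centers, union mask),
## via an independent point-in-polygon test
oracle_convex_count <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(sum(mask))
  hp <- jarvis_hull(cbind(as.numeric(idx[, 1]), as.numeric(idx[, 2])))
  all_idx <- which(mask | !mask, arr.ind = TRUE)
  x <- all_idx[, 1]; y <- all_idx[, 2]
  nh <- nrow(hp)
  inside <- rep(TRUE, length(x))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    # jarvis_hull above returns counter-clockwise order in (row, col)
    cr <- (hp[j, 1] - hp[i, 1]) * (y - hp[i, 2]) -
      (hp[j, 2] - hp[i, 2]) * (x - hp[i, 1])
    inside <- inside & cr >= -1e-9
  }
  sum(inside | mask[cbind(x, y)])
}

## independent marching-squares tracer: walks the 0.5-level cell edges
## of the padded mask and emits edge-midpoint polygons. Standard lookup
## table, no use of grDevices.
oracle_trace_contours <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0L, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask + 0L
  segs <- list()
  for (i in seq_len(nr + 1L)) for (j in seq_len(nc + 1L)) {
    a <- z[i, j]; b <- z[i + 1L, j]; cc <- z[i + 1L, j + 1L]; d <- z[i, j + 1L]
    code <- a + 2L * b + 4L * cc + 8L * d
    # cell corner (i, j) has pixel-center coordinates (i-1, j-1);
    # edge midpoints of the cell:
    top <- c(i - 0.5, j - 1)
    bottom <- c(i - 0.5, j)
    left <- c(i - 1, j - 0.5)
    right <- c(i, j - 0.5)
    add <- function(p, q) segs[[length(segs) + 1L]] <<- c(p, q)
    if (code %in% c(1L, 14L)) add(left, top)
    if (code %in% c(2L, 13L)) add(top, right)
    if (code %in% c(3L, 12L)) add(left, right)
    if (code %in% c(4L, 11L)) add(right, bottom)
    if (code == 5L) { add(left, top); add(right, bottom) }
    if (code %in% c(6L, 9L)) add(top, bottom)
    if (code %in% c(7L, 8L)) add(left, bottom)
    if (code == 10L) { add(top, right); add(left, bottom) }
  }
  if (!length(segs)) return(list())
  segm <- do.call(rbind, segs)
  # chain segments into closed polygons
  key <- function(p) sprintf("%.1f_%.1f", p[1], p[2])
  ends <- new.env()
  for (s in seq_len(nrow(segm))) {
    for (side in list(segm[s, 1:2], segm[s, 3:4])) {
      k <- key(side)
      ends[[k]] <- c(ends[[k]], s)
    }
  }
  used <- rep(FALSE, nrow(segm))
  polys <- list()
  for (s0 in seq_len(nrow(segm))) {
    if (used[s0]) next
    poly <- list(segm[s0, 1:2], segm[s0, 3:4])
    used[s0] <- TRUE
    repeat {
      tailp <- poly[[length(poly)]]
      cand <- ends[[key(tailp)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      s <- cand[1]
      used[s] <- TRUE
      nxt <- if (all(abs(segm[s, 1:2] - tailp) < 1e-9)) segm[s, 3:4] else segm[s, 1:2]
      poly[[length(poly) + 1L]] <- nxt
    }
    polys[[length(polys) + 1L]] <- do.call(rbind, poly)
  }
  polys
}

## independent recursive simplifier (same epsilon semantics as the
## implementation, separately coded, iterative stack instead of
## recursion)
oracle_simplify <- function(p, eps) {
  if (all(abs(p[1, ] - p[nrow(p), ]) < 1e-12)) p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  if (n <= 3L) return(p)
  ctr <- c(mean(p[, 1]), mean(p[, 2]))
  anchor1 <- which.max((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  d2 <- (p[, 1] - p[anchor1, 1])^2 + (p[, 2] - p[anchor1, 2])^2
  anchor2 <- which.max(d2)
  ord <- c(anchor1:n, seq_len(anchor1 - 1L))
  p <- p[ord, , drop = FALSE]
  j <- which(ord == anchor2)
  simp_open <- function(q) {
    keep <- rep(FALSE, nrow(q))
    keep[c(1L, nrow(q))] <- TRUE
    stack <- list(c(1L, nrow(q)))
    while (length(stack)) {
      seg <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i0 <- seg[1]; i1 <- seg[2]
      if (i1 - i0 < 2L) next
      a <- q[i0, ]; b <- q[i1, ]
      ab <- b - a
      len <- sqrt(sum(ab^2))
      ii <- (i0 + 1L):(i1 - 1L)
      dd <- if (len == 0) sqrt((q[ii, 1] - a[1])^2 + (q[ii, 2] - a[2])^2)
      else abs((q[ii, 1] - a[1]) * ab[2] - (q[ii, 2] - a[2]) * ab[1]) / len
      im <- ii[which.max(dd)]
      if (max(dd) > eps) {
        keep[im] <- TRUE
        stack <- c(stack, list(c(i0, im)), list(c(im, i1)))
      }
    }
    q[keep, , drop = FALSE]
  }
  h1 <- simp_open(p[1:j, , drop = FALSE])
  h2 <- simp_open(rbind(p[j:n, , drop = FALSE], p[1, , drop = FALSE]))
  rbind(h1[-nrow(h1), , drop = FALSE], h2[-nrow(h2), , drop = FALSE])
}

oracle_poly_len <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

oracle_poly_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

## largest-contour circularity under the package's stated convention,
## through the independent tracer + simplifier
oracle_circularity <- function(mask, eps = 0.9) {
  polys <- oracle_trace_contours(mask)
  sizes <- vapply(polys, nrow, 1L)
  q <- oracle_simplify(polys[[which.max(sizes)]], eps)
  4 * pi * oracle_poly_area(q) / oracle_poly_len(q)^2
}

oracle_perimeter <- function(mask, eps = 0.9) {
  polys <- oracle_trace_contours(mask)
  sizes <- vapply(polys, nrow, 1L)
  oracle_poly_len(oracle_simplify(polys[[which.max(sizes)]], eps))
}

## all-pairs minimum thickness: min over inner-boundary pixels of the
## distance to the nearest background pixel (0 if 8-adjacent)
oracle_min_thickness <- function(labels, psp) {
  bg <- which(labels == LBLS[["BACKGROUND"]], arr.ind = TRUE)
  inner <- labels == LBLS[["CENTRAL"]] | labels == LBLS[["CAVITY"]]
  if (!any(inner) || !nrow(bg)) return(NA_real_)
  idx <- which(inner, arr.ind = TRUE)
  nbr <- function(i, j) {
    ii <- pmin(pmax(i + rep(-1:1, 3), 1), nrow(labels))
    jj <- pmin(pmax(j + rep(-1:1, each = 3), 1), ncol(labels))
    any(!inner[cbind(ii, jj)])
  }
  on_b <- vapply(seq_len(nrow(idx)),
                 function(k) nbr(idx[k, 1], idx[k, 2]), TRUE)
  bpix <- idx[on_b, , drop = FALSE]
  best <- Inf
  for (k in seq_len(nrow(bpix))) {
    d2 <- (bg[, 1] - bpix[k, 1])^2 + (bg[, 2] - bpix[k, 2])^2
    m <- min(d2)
    if (m <= 2) return(0)
    best <- min(best, m)
  }
  sqrt(best) * psp
}

## tiny phantom spec used across tests (keeps suites fast)
small_spec <- function(...) {
  phantom_spec(n_slices = 10L, pixel_spacing_mm = 0.4, ...)
}
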