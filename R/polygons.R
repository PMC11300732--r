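# Binary mask <-> COCO polygon segmentation.
#
# Polygons are traced along pixel boundaries (vertices on the integer corner
# lattice, 0-based), so hole-free masks survive a trace/rasterize roundtrip
# exactly. Holes are dropped: COCO polygon segmentation cannot encode them
# without crowd/RLE annotations, and nuclei footprints are simply connected.

#' Trace the boundary polygon(s) of a binary mask
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param offset_x,offset_y 0-based image coordinates of `mask[1,1]`, added to
#'   every vertex.
#' @return list of numeric vectors, each a flat COCO polygon
#'   `c(x1, y1, x2, y2, ...)`; one polygon per connected component (holes
#'   omitted).
#' @export
mask_to_polygons <- function(mask, offset_x = 0, offset_y = 0) {
  if (!any(mask)) mcp_stop("cannot trace an empty mask", "empty_mask_error")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  filled <- which(pad, arr.ind = TRUE)
  ix <- filled[, 2] - 2L  # 0-based pixel x
  iy <- filled[, 1] - 2L  # 0-based pixel y

  # Directed boundary unit edges, interior kept on the right of travel.
  edges_from <- list(); edges_to <- list()
  nb_empty <- function(dr, dc) !pad[cbind(filled[, 1] + dr, filled[, 2] + dc)]
  n <- nb_empty(-1L, 0L); e <- nb_empty(0L, 1L)
  s <- nb_empty(1L, 0L);  wv <- nb_empty(0L, -1L)
  fx <- c(ix[n], ix[e] + 1L, ix[s] + 1L, ix[wv])
  fy <- c(iy[n], iy[e],      iy[s] + 1L, iy[wv] + 1L)
  tx <- c(ix[n] + 1L, ix[e] + 1L, ix[s], ix[wv])
  ty <- c(iy[n],      iy[e] + 1L, iy[s] + 1L, iy[wv])

  n_edges <- length(fx)
  key <- function(x, y) x + y * (w + 2L)  # unique corner key
  from_key <- key(fx, fy)
  by_from <- split(seq_len(n_edges), from_key)
  used <- logical(n_edges)
  loops <- list()

  for (start in seq_len(n_edges)) {
    if (used[start]) next
    cur <- start
    vx <- fx[start]; vy <- fy[start]
    xs <- vx; ys <- vy
    repeat {
      used[cur] <- TRUE
      nx <- tx[cur]; ny <- ty[cur]
      if (nx == xs[1] && ny == ys[1]) break
      xs <- c(xs, nx); ys <- c(ys, ny)
      cand <- by_from[[as.character(key(nx, ny))]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break  # defensive; closed loops guaranteed
      if (length(cand) > 1L) {
        # Pinch corner: prefer the sharpest right turn to stay on one
        # component (interior is on the right of travel).
        din <- c(tx[cur] - fx[cur], ty[cur] - fy[cur])
        cross <- vapply(cand, function(j) {
          dj <- c(tx[j] - fx[j], ty[j] - fy[j])
          din[1] * dj[2] - din[2] * dj[1]
        }, numeric(1))
        cand <- cand[which.max(cross)]
      }
      cur <- cand
    }
    loops[[length(loops) + 1L]] <- cbind(xs, ys)
  }

  shoelace <- function(v) {
    x <- v[, 1]; y <- v[, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }
  keep <- Filter(function(v) shoelace(v) > 0, loops)  # outer loops only
  lapply(keep, function(v) {
    v <- drop_collinear(v)
    as.numeric(t(cbind(v[, 1] + offset_x, v[, 2] + offset_y)))
  })
}

drop_collinear <- function(v) {
  n <- nrow(v)
  if (n <= 4L) return(v)
  prev <- rbind(v[n, ], v[-n, ])
  nxt <- rbind(v[-1, ], v[1, ])
  d1 <- v - prev; d2 <- nxt - v
  turn <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  out <- v[turn != 0, , drop = FALSE]
  if (nrow(out) >= 3L) out else v
}

#' Rasterize COCO polygon(s) into a binary mask
#'
#' A pixel is inside when its center falls inside any polygon (even-odd rule,
#' scanline at pixel centers). Exact inverse of [mask_to_polygons()] for
#' hole-free masks.
#'
#' @param polygons list of flat `c(x1, y1, ...)` vectors (or a single vector).
#' @param height,width output dimensions in pixels.
#' @return logical height x width matrix.
#' @export
polygons_to_mask <- function(polygons, height, width) {
  if (is.numeric(polygons)) polygons <- list(polygons)
  out <- matrix(FALSE, height, width)
  for (poly in polygons) {
    if (length(poly) < 6L || length(poly) %% 2L != 0L)
      mcp_stop("polygon must hold >= 3 (x, y) pairs", "polygon_error")
    px <- poly[seq(1, length(poly), by = 2)]
    py <- poly[seq(2, length(poly), by = 2)]
    qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
    y_lo <- max(0L, floor(min(py)))
    y_hi <- min(height - 1L, ceiling(max(py)) - 1L)
    if (y_hi < y_lo) next
    for (iy in y_lo:y_hi) {
      yc <- iy + 0.5
      hit <- (py - yc) * (qy - yc) < 0
      if (!any(hit)) next
      xc <- px[hit] + (yc - py[hit]) * (qx[hit] - px[hit]) / (qy[hit] - py[hit])
      xc <- sort(xc)
      for (k in seq(1, length(xc) - 1, by = 2)) {
        lo <- max(0L, ceiling(xc[k] - 0.5 + 1e-9))
        hi <- min(width - 1L, floor(xc[k + 1] - 0.5 - 1e-9))
        if (hi >= lo) out[iy + 1L, (lo:hi) + 1L] <- TRUE
      }
    }
  }
  out
}
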