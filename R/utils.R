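# Internal geometry and array helpers shared across modules.

# Positive scalar check with a consistent error message.
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Coerce a movie given as list of matrices or a (t, y, x) array to a list of
# matrices, validating that all frames share one shape.
as_frame_list <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1L]), function(i) frames[i, , ])
  }
  if (!is.list(frames) || length(frames) == 0L) {
    stop("`frames` must be a non-empty list of matrices or a (t, y, x) array",
         call. = FALSE)
  }
  shp <- dim(frames[[1L]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), shp),
               logical(1))
  if (!all(ok)) stop("all frames must be matrices of identical shape", call. = FALSE)
  frames
}

# Matrix of center-of-pixel distances (in micrometres) from `center`
# (0-based (row, col)), for an image of `dim` = c(nrow, ncol).
pixel_distances_um <- function(dims, center, pixel_size) {
  rows <- matrix(0:(dims[1L] - 1L), dims[1L], dims[2L])
  cols <- matrix(0:(dims[2L] - 1L), dims[1L], dims[2L], byrow = TRUE)
  sqrt((rows - center[1L])^2 + (cols - center[2L])^2) * pixel_size
}

# Integer-offset circular roll of a matrix (wraps around).
roll2 <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

# Integer-offset shift with constant fill (content moves down by dy, right
# by dx); also returns the validity mask of pixels that originated inside.
shift2 <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  keep_r <- src_r >= 1L & src_r <= nr
  keep_c <- src_c >= 1L & src_c <= nc
  if (any(keep_r) && any(keep_c)) {
    out[which(keep_r), which(keep_c)] <- m[src_r[keep_r], src_c[keep_c]]
    valid[which(keep_r), which(keep_c)] <- TRUE
  }
  list(image = out, valid = valid)
}

# 4-connected line rasterization between 0-based (row, col) endpoints.
# Diagonal moves are decomposed into two axis steps so the path stays
# 4-connected; returns an n x 2 matrix of 0-based (row, col).
ras_line4 <- function(p0, p1) {
  d <- p1 - p0
  n <- max(abs(d))
  if (n == 0) return(matrix(p0, 1L, 2L))
  ts <- seq(0, 1, length.out = n + 1L)
  pts <- cbind(round(p0[1L] + ts * d[1L]), round(p0[2L] + ts * d[2L]))
  out <- matrix(NA_real_, 0L, 2L)
  cur <- pts[1L, ]
  acc <- list(cur)
  for (i in 2:nrow(pts)) {
    nxt <- pts[i, ]
    step <- nxt - cur
    if (all(abs(step) == 1)) {            # diagonal: insert elbow pixel
      acc[[length(acc) + 1L]] <- c(nxt[1L], cur[2L])
    }
    acc[[length(acc) + 1L]] <- nxt
    cur <- nxt
  }
  m <- do.call(rbind, acc)
  m[!duplicated(m), , drop = FALSE]
}

# Midpoint-circle rasterization: 0-based integer offsets of the discrete
# circle of integer radius R, ordered by angle. Consecutive entries (and the
# seam pair) are 8-adjacent for all R >= 1.
midpoint_circle <- function(R) {
  stopifnot(R >= 1)
  x <- R; y <- 0L; err <- 1L - R
  pts <- list()
  while (x >= y) {
    pts[[length(pts) + 1L]] <- c(x, y)
    y <- y + 1L
    if (err < 0) {
      err <- err + 2L * y + 1L
    } else {
      x <- x - 1L
      err <- err + 2L * (y - x) + 1L
    }
  }
  oct <- do.call(rbind, pts)                 # x >= y >= 0 octant
  all8 <- rbind(
    cbind(oct[, 1L],  oct[, 2L]), cbind(oct[, 2L],  oct[, 1L]),
    cbind(-oct[, 2L], oct[, 1L]), cbind(-oct[, 1L], oct[, 2L]),
    cbind(-oct[, 1L], -oct[, 2L]), cbind(-oct[, 2L], -oct[, 1L]),
    cbind(oct[, 2L],  -oct[, 1L]), cbind(oct[, 1L],  -oct[, 2L])
  )
  all8 <- all8[!duplicated(all8), , drop = FALSE]
  ang <- atan2(all8[, 1L], all8[, 2L])
  all8[order(ang), , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling of foreground components in a 2D mask
#' (4- or 8-connectivity) or a 3D mask (6- or 26-connectivity). 3D masks are
#' indexed (z, y, x). Written in-package because the engulfment rule needs
#' 26-connectivity across z-planes.
#'
#' @param mask logical matrix or 3D logical array.
#' @param connectivity 4 or 8 (2D); 6 or 26 (3D).
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3L) 26L else 8L) {
  dims <- dim(mask)
  nd <- length(dims)
  if (!(nd %in% c(2L, 3L))) stop("`mask` must be 2D or 3D", call. = FALSE)
  mask <- mask > 0
  offs <- switch(as.character(connectivity),
    "4"  = rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)),
    "8"  = as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5L, , drop = FALSE],
    "6"  = rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1)),
    "26" = {
      g <- as.matrix(expand.grid(dz = -1:1, dr = -1:1, dc = -1:1))
      g[rowSums(abs(g)) > 0, , drop = FALSE]
    },
    stop("unsupported connectivity", call. = FALSE)
  )
  if (ncol(offs) != nd) stop("connectivity does not match mask dimensionality", call. = FALSE)
  labels <- array(0L, dims)
  todo <- which(mask)
  if (length(todo) == 0L) return(labels)
  seen <- array(FALSE, dims)
  lab <- 0L
  for (seed in todo) {
    if (seen[seed]) next
    lab <- lab + 1L
    frontier <- matrix(arrayInd(seed, dims), 1L)
    seen[seed] <- TRUE
    labels[seed] <- lab
    while (nrow(frontier) > 0L) {
      # expand every frontier pixel by all offsets at once
      n <- nrow(frontier)
      cand <- frontier[rep(seq_len(n), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = n), , drop = FALSE]
      inb <- rep(TRUE, nrow(cand))
      for (d in seq_len(nd)) inb <- inb & cand[, d] >= 1L & cand[, d] <= dims[d]
      cand <- cand[inb, , drop = FALSE]
      if (nrow(cand) == 0L) break
      lin <- cand[, 1L]
      if (nd >= 2L) lin <- lin + (cand[, 2L] - 1L) * dims[1L]
      if (nd == 3L) lin <- lin + (cand[, 3L] - 1L) * dims[1L] * dims[2L]
      keep <- mask[lin] & !seen[lin]
      lin <- unique(lin[keep])
      if (length(lin) == 0L) break
      seen[lin] <- TRUE
      labels[lin] <- lab
      frontier <- arrayInd(lin, dims)
    }
  }
  labels
}

# Remove foreground components smaller than `min_size` pixels (8-connectivity).
filter_small_components <- function(mask, min_size) {
  if (min_size <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim(mask))
}
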