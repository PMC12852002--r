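# Gray-level texture matrices over a quantized image.
#
# Coordinate convention (used everywhere): the image is a numeric matrix
# with the row index y growing downward from the top-left origin and the
# column index x growing rightward; an offset (dx, dy) moves dx columns and
# dy rows.  Directions are the four standard 2-D angles:
#   0 deg  -> (dx, dy) = ( 1,  0)
#   45 deg -> (dx, dy) = ( 1, -1)
#   90 deg -> (dx, dy) = ( 0,  1)
#   135deg -> (dx, dy) = ( 1,  1)

texture_directions <- function() {
  list(`0` = c(1L, 0L), `45` = c(1L, -1L), `90` = c(0L, 1L), `135` = c(1L, 1L))
}

# ascending integer span, empty when lo > hi (never descending)
span <- function(lo, hi) if (lo > hi) integer(0) else lo:hi

#' Quantize a gray image to integer levels
#'
#' Equal-width binning of the image range \[min, max\] into `n_levels`
#' bins mapped to `1..n_levels`; the minimum maps to 1 and the maximum to
#' `n_levels`. A constant image maps entirely to level 1.
#'
#' @param image Numeric matrix.
#' @param n_levels Number of gray levels (>= 2).
#' @return Integer matrix with attribute `n_levels`.
#' @export
quantize_image <- function(image, n_levels = 32) {
  if (n_levels < 2) {
    rlang::abort("n_levels must be >= 2.", class = "pcgstack_invalid_config")
  }
  rng <- range(image)
  if (rng[2] - rng[1] < 1e-300) {
    q <- matrix(1L, nrow(image), ncol(image))
  } else {
    q <- pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L,
              as.integer(n_levels))
    q <- matrix(as.integer(q), nrow(image), ncol(image))
  }
  attr(q, "n_levels") <- as.integer(n_levels)
  q
}

q_levels <- function(q, n_levels) {
  if (is.null(n_levels)) n_levels <- attr(q, "n_levels")
  if (is.null(n_levels)) n_levels <- max(q)
  as.integer(n_levels)
}

#' Gray-level co-occurrence matrix
#'
#' Counts pixel pairs at spatial offset `(dx, dy)` with gray levels
#' `(gi, gj)`; symmetric mode also counts the reversed pair. The matrix is
#' normalized to sum to one.
#'
#' @param q Quantized image from [quantize_image()].
#' @param offset Integer `c(dx, dy)`, nonzero.
#' @param symmetric Count both pair orders.
#' @param n_levels Number of gray levels (defaults to the `q` attribute).
#' @return `n_levels x n_levels` matrix summing to 1.
#' @export
glcm <- function(q, offset = c(1L, 0L), symmetric = TRUE, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  if (dx == 0L && dy == 0L) {
    rlang::abort("offset must be nonzero.", class = "pcgstack_invalid_config")
  }
  nr <- nrow(q); nc <- ncol(q)
  rows <- span(max(1L, 1L - dy), min(nr, nr - dy))
  cols <- span(max(1L, 1L - dx), min(nc, nc - dx))
  if (length(rows) == 0 || length(cols) == 0) {
    rlang::abort("offset larger than the image; no pixel pairs.",
                 class = "pcgstack_empty_pairs")
  }
  g1 <- q[rows, cols, drop = FALSE]
  g2 <- q[rows + dy, cols + dx, drop = FALSE]
  counts <- matrix(tabulate((g1 - 1L) * ng + g2, nbins = ng * ng),
                   ng, ng, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

#' Gray-level run-length matrix
#'
#' Entry `(g, r)` counts the maximal runs of length `r` at level `g` along
#' the given direction. Implemented as one ordered scan: pixels are sorted
#' by (line id, position along the line) and maximal runs are the stretches
#' where neither the line id nor the gray level changes.
#'
#' @inheritParams glcm
#' @param direction One of `0`, `45`, `90`, `135` (degrees).
#' @return `n_levels x Rmax` count matrix.
#' @export
glrlm <- function(q, direction = 0, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  rw <- row(q); cl <- col(q)
  direction <- as.character(direction)
  key <- switch(direction,
    `0` = rw,
    `90` = cl,
    `45` = rw + cl,
    `135` = cl - rw,
    rlang::abort("direction must be one of 0, 45, 90, 135.",
                 class = "pcgstack_invalid_config")
  )
  o <- order(key, cl, rw)
  vals <- as.integer(q)[o]
  line <- as.integer(key)[o]
  n <- length(vals)
  new_run <- c(TRUE, vals[-1L] != vals[-n] | line[-1L] != line[-n])
  starts <- which(new_run)
  rs <- diff(c(starts, n + 1L))
  gs <- vals[starts]
  rmax <- max(rs)
  matrix(tabulate((gs - 1L) * rmax + rs, nbins = ng * rmax),
         ng, rmax, byrow = TRUE)
}

#' Gray-level size-zone matrix
#'
#' A zone is a maximal 8-connected set of pixels sharing one gray level;
#' entry `(g, s)` counts zones of size `s` at level `g`.
#'
#' @inheritParams glcm
#' @return `n_levels x Smax` count matrix.
#' @export
glszm <- function(q, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  nr <- nrow(q); nc <- ncol(q)
  npix <- nr * nc
  id <- function(r, c) (c - 1L) * nr + r # column-major pixel index
  edges <- integer(0)
  for (off in texture_directions()) {
    dx <- off[1]; dy <- off[2]
    rows <- span(max(1L, 1L - dy), min(nr, nr - dy))
    cols <- span(max(1L, 1L - dx), min(nc, nc - dx))
    if (length(rows) == 0 || length(cols) == 0) next
    a <- as.vector(outer(rows, cols, id))
    b <- as.vector(outer(rows + dy, cols + dx, id))
    same <- q[a] == q[b]
    if (any(same)) edges <- c(edges, rbind(a[same], b[same]))
  }
  g <- igraph::make_graph(edges, n = npix, directed = FALSE)
  comp <- igraph::components(g)
  zone_level <- q[match(seq_len(comp$no), comp$membership)]
  zone_size <- comp$csize
  smax <- max(zone_size)
  matrix(tabulate((zone_level - 1L) * smax + zone_size, nbins = ng * smax),
         ng, smax, byrow = TRUE)
}

#' Gray-level dependence matrix
#'
#' For every pixel, the dependence is the number of neighbors within
#' Chebyshev distance `distance` whose gray-level difference from the
#' pixel is at most `delta`. Entry `(g, d)` (column `d + 1`) counts pixels
#' at level `g` with dependence `d`; entries sum to the pixel count.
#'
#' @inheritParams glcm
#' @param delta Gray-level tolerance.
#' @param distance Chebyshev neighborhood radius.
#' @return `n_levels x (Dmax + 1)` count matrix; column `j` holds
#'   dependence `d = j - 1`.
#' @export
gldm <- function(q, delta = 0, distance = 1, n_levels = NULL) {
  ng <- q_levels(q, n_levels)
  nr <- nrow(q); nc <- ncol(q)
  D <- matrix(0L, nr, nc)
  offs <- expand.grid(dx = -distance:distance, dy = -distance:distance)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    rows <- span(max(1L, 1L - dy), min(nr, nr - dy))
    cols <- span(max(1L, 1L - dx), min(nc, nc - dx))
    if (length(rows) == 0 || length(cols) == 0) next
    ok <- abs(q[rows, cols, drop = FALSE] -
              q[rows + dy, cols + dx, drop = FALSE]) <= delta
    D[rows, cols] <- D[rows, cols] + ok
  }
  dmax <- max(D)
  matrix(tabulate((q - 1L) * (dmax + 1L) + D + 1L, nbins = ng * (dmax + 1L)),
         ng, dmax + 1L, byrow = TRUE)
}

#' All texture matrices of a quantized image
#'
#' GLCM and GLRLM are computed for the four standard directions; GLSZM and
#' GLDM are direction-free.
#'
#' @inheritParams glcm
#' @param delta GLDM gray-level tolerance.
#' @param distance GLDM Chebyshev radius.
#' @return List with `glcm` (list of 4), `glrlm` (list of 4), `glszm`,
#'   `gldm`, `n_levels`, `n_pixels`.
#' @export
texture_matrices <- function(q, n_levels = NULL, delta = 0, distance = 1) {
  ng <- q_levels(q, n_levels)
  dirs <- texture_directions()
  list(
    glcm = lapply(dirs, function(o) glcm(q, o, symmetric = TRUE, n_levels = ng)),
    glrlm = lapply(names(dirs), function(d) glrlm(q, d, n_levels = ng)),
    glszm = glszm(q, n_levels = ng),
    gldm = gldm(q, delta = delta, distance = distance, n_levels = ng),
    n_levels = ng,
    n_pixels = length(q)
  )
}
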