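#' Nuclear area in square micrometres
#'
#' Foreground pixel count times the squared calibration.
#'
#' @param n a [nucleus_image()]
#' @return area in um^2
#' @export
nuclear_area <- function(n) {
  stopifnot(inherits(n, "nucleus_image"))
  sum(n$mask) * n$calibration^2
}

# Moore-neighbor boundary tracing (8-connected, Jacob's stopping criterion).
# Returns the closed boundary as a two-column matrix of (row, col) pixels.
trace_boundary <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  m <- matrix(FALSE, n + 2L, p + 2L)
  m[2:(n + 1L), 2:(p + 1L)] <- mask
  # start: first foreground pixel in raster (row-major) order
  start <- NULL
  for (r in seq_len(n + 2L)) {
    cc <- which(m[r, ])
    if (length(cc)) { start <- c(r, cc[1L]); break }
  }
  # Moore neighborhood clockwise starting east: E SE S SW W NW N NE
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  # entry backtrack: the pixel west of start is background by construction
  b <- start
  dir <- 5L # index of W in the (E,SE,S,SW,W,NW,N,NE) list
  bnd <- matrix(0L, 0L, 2L)
  first_move <- NA_integer_
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir - 1L + 1L + k) %% 8L) + 1L # scan clockwise from backtrack+1
      r2 <- b[1L] + dr[d]; c2 <- b[2L] + dc[d]
      if (m[r2, c2]) {
        bnd <- rbind(bnd, b)
        if (nrow(bnd) == 1L) first_move <- d
        # Jacob's criterion: stop on re-entering start with the first move
        if (nrow(bnd) > 2L && all(b == start) && d == first_move) {
          return(bnd[-nrow(bnd), , drop = FALSE])
        }
        b <- c(r2, c2)
        dir <- ((d + 3L) %% 8L) + 1L # backtrack = opposite of arrival, +1 scan
        found <- TRUE
        break
      }
    }
    if (!found) return(matrix(start, 1L, 2L)) # isolated pixel
    if (nrow(bnd) > 8L * (n * p)) stop("boundary tracing failed to close")
  }
}

# perimeter of the 8-connected boundary chain code.
# corner_correction applies the Vossepoel-Smeulders estimator
# (0.980 per axial step, 1.406 per diagonal step, -0.091 per corner) plus
# the half-pixel convex-offset term pi: the chain connects pixel centers
# while the object outline runs half a pixel outside, and offsetting a
# convex contour outward by t lengthens it by 2*pi*t. The raw chain code
# (1 / sqrt(2) steps) overestimates smooth perimeters by ~5-6% and carries
# no offset term.
chain_perimeter <- function(boundary, corner_correction = TRUE) {
  nb <- nrow(boundary)
  if (nb < 2L) return(4) # single pixel: unit square
  nxt <- rbind(boundary[-1L, , drop = FALSE], boundary[1L, , drop = FALSE])
  step <- nxt - boundary
  diag <- step[, 1L] != 0L & step[, 2L] != 0L
  if (!corner_correction) {
    return(sum(!diag) + sqrt(2) * sum(diag))
  }
  prv <- rbind(step[nrow(step), , drop = FALSE], step[-nrow(step), , drop = FALSE])
  corners <- sum(step[, 1L] != prv[, 1L] | step[, 2L] != prv[, 2L])
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * corners + pi
}

#' Form factor (circularity) of the nucleus
#'
#' `4 * pi * A / P^2` with `A` the foreground pixel count and `P` the
#' perimeter of the 8-connected boundary chain code (axial step 1, diagonal
#' step sqrt(2), Vossepoel-Smeulders digitization correction so a large
#' digitized disk scores ~1). Values slightly above 1 can occur on digitized
#' shapes. Lower values indicate lobulated (variant-morphology) nuclei.
#'
#' @param n a [nucleus_image()]
#' @param largest_component if `TRUE`, silently measure the largest
#'   4-connected component instead of erroring on fragmented masks
#' @param corner_correction apply the digitization perimeter correction
#'   (default `TRUE`); `FALSE` gives the raw (1, sqrt(2)) chain length
#' @return circularity (dimensionless)
#' @export
form_factor <- function(n, largest_component = FALSE, corner_correction = TRUE) {
  stopifnot(inherits(n, "nucleus_image"))
  mask <- n$mask
  if (count_components4(mask) != 1L) {
    if (!largest_component) {
      stop("mask has multiple 4-connected components; ",
           "set largest_component = TRUE to measure the largest")
    }
    mask <- keep_largest_component(mask)
  }
  A <- sum(mask)
  P <- chain_perimeter(trace_boundary(mask), corner_correction)
  4 * pi * A / P^2
}

keep_largest_component <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  todo <- mask
  best <- integer(0)
  while (any(todo)) {
    seen <- which(todo)[1L]
    todo[seen] <- FALSE
    frontier <- seen
    while (length(frontier)) {
      r <- (frontier - 1L) %% n + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < n] + 1L,
              frontier[frontier > n] - n, frontier[frontier <= n * (p - 1L)] + n)
      nb <- unique(nb[todo[nb]])
      todo[nb] <- FALSE
      seen <- c(seen, nb)
      frontier <- nb
    }
    if (length(seen) > length(best)) best <- seen
  }
  out <- matrix(FALSE, n, p)
  out[best] <- TRUE
  out
}

#' Within-mask gray-level mean and standard deviation
#'
#' Arithmetic mean and population SD (divisor N) over foreground pixels
#' only; background pixels never contribute.
#'
#' @param n a [nucleus_image()]
#' @return named numeric vector `c(mean_gray, sd_gray)`
#' @export
gray_stats <- function(n) {
  stopifnot(inherits(n, "nucleus_image"))
  v <- n$gray[n$mask]
  if (length(v) < 2L) stop("gray_stats needs at least 2 foreground pixels")
  m <- mean(v)
  c(mean_gray = m, sd_gray = sqrt(mean((v - m)^2)))
}

#' All geometric morphometry features of one nucleus
#'
#' @param n a [nucleus_image()]
#' @inheritParams form_factor
#' @return named numeric vector: `area_um2`, `form_factor`, `mean_gray`,
#'   `sd_gray`
#' @export
morphometry_features <- function(n, largest_component = FALSE) {
  gs <- gray_stats(n)
  c(area_um2 = nuclear_area(n),
    form_factor = form_factor(n, largest_component),
    gs)
}
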