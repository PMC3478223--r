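#' Gray-level co-occurrence matrix over the nuclear mask
#'
#' Counts pairs of gray values at unit distance along the four standard
#' orientations (horizontal, vertical and both diagonals), keeping only
#' pairs whose BOTH endpoints lie inside the mask, counts each pair in both
#' directions (symmetric matrix), pools all orientations into one matrix
#' and normalizes to sum 1. Full 256-level dynamics, no re-quantization.
#'
#' @param n a [nucleus_image()] (or a plain integer matrix with a `mask`)
#' @param offsets integer matrix of (drow, dcol) offsets; default the four
#'   unit-distance orientations `(0,1), (1,0), (1,1), (1,-1)`
#' @param mask optional logical matrix when `n` is a plain matrix
#' @return object of class `glcm`: 256 x 256 probability matrix `p` with
#'   marginal means `mu_x`, `mu_y` as attributes
#' @export
compute_glcm <- function(n, offsets = NULL,
                         mask = NULL) {
  if (inherits(n, "nucleus_image")) {
    g <- n$gray; mask <- n$mask
  } else {
    g <- n
    if (is.null(mask)) mask <- matrix(TRUE, nrow(g), ncol(g))
  }
  if (is.null(offsets)) {
    offsets <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  }
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  # crop to the mask bounding box: pairs outside cannot qualify
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  g <- g[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mask <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  nr <- nrow(g); nc <- ncol(g)

  counts <- numeric(65536L)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1L]; dc <- offsets[k, 2L]
    if (max(1L, 1L - dr) > min(nr, nr - dr) ||
        max(1L, 1L - dc) > min(nc, nc - dc)) next
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    i <- g[r1, c1, drop = FALSE][ok]
    j <- g[r1 + dr, c1 + dc, drop = FALSE][ok]
    counts <- counts + tabulate(i * 256L + j + 1L, 65536L) +
      tabulate(j * 256L + i + 1L, 65536L)
  }
  tot <- sum(counts)
  if (tot == 0) stop("mask yields no valid co-occurring pixel pairs")
  p <- matrix(counts / tot, 256L, 256L, byrow = TRUE) # p[i+1, j+1] = P(i, j)
  lev <- 0:255
  structure(p, class = "glcm",
            mu_x = sum(rowSums(p) * lev), mu_y = sum(colSums(p) * lev))
}

#' Texture features of a gray-level co-occurrence matrix
#'
#' Entropy `-sum p log(p)` (bits by default), contrast
#' `sum (i-j)^2 p`, local homogeneity (inverse difference moment)
#' `sum p / (1 + (i-j)^2)`, and cluster prominence
#' `sum (i + j - mu_x - mu_y)^4 p`.
#'
#' @param c a `glcm` from [compute_glcm()]
#' @param base logarithm base for entropy (default 2, i.e. bits)
#' @return named numeric vector: `entropy`, `contrast`,
#'   `local_homogeneity`, `cluster_prominence`
#' @export
glcm_features <- function(c, base = 2) {
  stopifnot(inherits(c, "glcm"))
  p <- unclass(c)
  lev <- 0:255
  i <- matrix(rep(lev, times = 256L), 256L)
  j <- matrix(rep(lev, each = 256L), 256L)
  pos <- p > 0
  entropy <- -sum(p[pos] * log(p[pos], base = base))
  d2 <- (i - j)^2
  contrast <- sum(d2 * p)
  homog <- sum(p / (1 + d2))
  mu <- attr(c, "mu_x") + attr(c, "mu_y")
  prom <- sum((i + j - mu)^4 * p)
  c(entropy = entropy, contrast = contrast,
    local_homogeneity = homog, cluster_prominence = prom)
}
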