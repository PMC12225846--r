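#' 2-D Perlin (lattice-gradient) coherent noise
#'
#' Classic Perlin noise: unit gradients are drawn at the nodes of a
#' \code{periods x periods} lattice spanning the grid, and each pixel value
#' is the quintic-faded bilinear interpolation of the dot products between
#' the corner gradients and the pixel offset vectors. Produces smooth,
#' blob-like fields used to emulate large spurious segmentation regions.
#'
#' Both dimensions must be divisible by \code{periods} (callers pad and crop
#' otherwise). Gradient angles are drawn from the current R RNG stream, so
#' the field is reproducible under \code{set.seed()}.
#'
#' @param nrow,ncol grid dimensions, each divisible by \code{periods}.
#' @param periods number of lattice periods per axis (>= 1).
#' @return numeric \code{nrow x ncol} matrix, approximately in \[-1, 1\].
#' @examples
#' set.seed(1)
#' field <- perlinNoise(64, 64, 4)
#' range(field)
#' @export
perlinNoise <- function(nrow, ncol, periods) {
  periods <- as.integer(periods)
  if (periods < 1L) stop("periods must be >= 1")
  if (nrow %% periods != 0L || ncol %% periods != 0L) {
    stop("grid dimensions must be divisible by periods")
  }
  theta <- matrix(stats::runif((periods + 1L)^2, 0, 2 * pi),
                  periods + 1L, periods + 1L)
  gx <- cos(theta)
  gy <- sin(theta)

  u <- ((seq_len(nrow) - 0.5) / (nrow / periods))  # in (0, periods)
  v <- ((seq_len(ncol) - 0.5) / (ncol / periods))
  i0 <- pmin(floor(u), periods - 1L)
  j0 <- pmin(floor(v), periods - 1L)
  fu <- u - i0   # offsets within the cell, in (0, 1)
  fv <- v - j0

  FU <- matrix(fu, nrow, ncol)
  FV <- matrix(fv, nrow, ncol, byrow = TRUE)
  I0 <- matrix(i0 + 1L, nrow, ncol)
  J0 <- matrix(j0 + 1L, nrow, ncol, byrow = TRUE)

  corner <- function(di, dj) {
    idx <- cbind(as.vector(I0) + di, as.vector(J0) + dj)
    gxm <- matrix(gx[idx], nrow, ncol)
    gym <- matrix(gy[idx], nrow, ncol)
    gxm * (FU - di) + gym * (FV - dj)
  }
  n00 <- corner(0L, 0L)
  n10 <- corner(1L, 0L)
  n01 <- corner(0L, 1L)
  n11 <- corner(1L, 1L)

  fade <- function(t) t^3 * (t * (t * 6 - 15) + 10)
  wu <- fade(FU)
  wv <- fade(FV)
  nx0 <- n00 * (1 - wu) + n10 * wu
  nx1 <- n01 * (1 - wu) + n11 * wu
  sqrt(2) * (nx0 * (1 - wv) + nx1 * wv)
}
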