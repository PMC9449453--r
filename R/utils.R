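# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a per-module seed from a global seed
#'
#' Deterministic hash of (seed, name) kept below 2^31 so different modules of
#' one run draw from unrelated streams.
#' @noRd
derive_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Shift a matrix by integer offsets with zero fill
#' @param m matrix
#' @param dr,dc row/column shift; positive moves content down/right
#' @noRd
shift_matrix <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  H <- nrow(m); W <- ncol(m)
  sr <- max(1, 1 + dr):min(H, H + dr)
  sc <- max(1, 1 + dc):min(W, W + dc)
  if (length(sr) == 0 || length(sc) == 0) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Otsu threshold of a numeric matrix (256-bin histogram)
#' @noRd
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Binary erosion with a 3x3 square element, repeated `iter` times
#' @noRd
erode_mask <- function(mask, iter = 1L) {
  m <- mask
  for (i in seq_len(iter)) {
    H <- nrow(m); W <- ncol(m)
    padded <- matrix(FALSE, H + 2L, W + 2L)
    padded[2:(H + 1L), 2:(W + 1L)] <- m
    out <- matrix(TRUE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      out <- out & padded[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
    }
    m <- out
  }
  m
}

#' Inner boundary ring of a binary mask
#'
#' The 1-2 px ring used as the "nuclear membrane" stand-in: mask pixels whose
#' `width`-fold erosion is empty.
#' @param mask logical matrix
#' @param width ring width in pixels (default 2)
#' @return logical matrix
#' @export
mask_boundary <- function(mask, width = 2L) {
  mask & !erode_mask(mask, as.integer(width))
}

#' Bilinear upsampling of a matrix to a target size
#' @noRd
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # map output pixel centers into input coordinates (align centers)
  ri <- (seq_len(H) - 0.5) * h / H + 0.5
  ci <- (seq_len(W) - 0.5) * w / W + 0.5
  r0 <- pmin(pmax(floor(ri), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(ci), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc)
  b <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc)
  d <- m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  e <- m[r1, c1, drop = FALSE] * outer(fr, fc)
  a + b + d + e
}

#' Fill an ellipse into a logical matrix
#' @noRd
ellipse_mask <- function(H, W, cr, cc, a, b, theta = 0) {
  rr <- matrix(seq_len(H) - 1, H, W) - cr
  cc_ <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cc
  u <- cos(theta) * rr + sin(theta) * cc_
  v <- -sin(theta) * rr + cos(theta) * cc_
  (u / a)^2 + (v / b)^2 <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
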