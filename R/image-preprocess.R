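# Local-statistics image preprocessing operators.

# Box-window sum of a matrix with replicated edges, via a summed-area table.
box_sum <- function(m, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq(1L - r, nr + r), 1L), nr)
  ci <- pmin(pmax(seq(1L - r, nc + r), 1L), nc)
  p <- m[ri, ci, drop = FALSE]
  s <- apply(apply(p, 2L, cumsum), 1L, cumsum)   # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  i2 <- seq_len(nr) + 2L * r; i1 <- seq_len(nr)
  j2 <- seq_len(nc) + 2L * r; j1 <- seq_len(nc)
  s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
    s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

box_stats <- function(m, w) {
  n <- w * w
  mu <- box_sum(m, w) / n
  v <- pmax(box_sum(m * m, w) / n - mu^2, 0)
  list(mean = mu, var = v)
}

# Apply a matrix operator to each slice of a 2D matrix or 3D stack.
per_slice <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  if (length(dim(img)) == 3L) {
    out <- img
    for (s in seq_len(dim(img)[1])) out[s, , ] <- f(img[s, , ])
    return(out)
  }
  stop("image must be a matrix or a 3D slice stack")
}

#' Adaptive Wiener denoising
#'
#' Local-statistics Wiener estimate: with local mean m and local variance v
#' over the window, and the noise variance nv estimated as the mean of the
#' local variances, each pixel becomes
#' m + max(0, v - nv) / max(v, nv) * (x - m).  Flat regions shrink fully to
#' the local mean; high-variance structure is preserved.  Output is clipped
#' to [0, 255].
#'
#' @param img matrix or 3D slice stack of 8-bit intensities.
#' @param window odd window size >= 3.
#' @return denoised image of the same shape.
#' @export
wiener_denoise <- function(img, window = 3L) {
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  per_slice(img, function(m) {
    if (window > min(dim(m))) stop("window larger than image")
    st <- box_stats(m, window)
    nv <- mean(st$var)
    den <- pmax(st$var, nv)
    den[den == 0] <- 1                        # constant image: keep mean
    out <- st$mean + pmax(st$var - nv, 0) / den * (m - st$mean)
    pmin(pmax(out, 0), 255)
  })
}

#' Fuzzy contrast enhancement
#'
#' Maps intensities to fuzzy memberships mu = x/255 and applies the
#' intensification operator about the crossover membership c:
#' mu <- mu^2 / c for mu <= c, 1 - (1 - mu)^2 / (1 - c) otherwise (for the
#' default crossover 127.5 this is the classical 2 mu^2 / 1 - 2(1-mu)^2
#' pair), iterated \code{iterations} times, then maps back to [0, 255].
#' Memberships 0, c and 1 are fixed points; contrast about the crossover is
#' non-decreasing.
#'
#' @param img matrix or 3D slice stack of 8-bit intensities.
#' @param crossover crossover intensity in (0, 255); default 127.5.
#' @param iterations number of applications (default 1).
#' @return enhanced image of the same shape.
#' @export
fuzzy_enhance <- function(img, crossover = 127.5, iterations = 1L) {
  if (crossover <= 0 || crossover >= 255) stop("crossover must be in (0, 255)")
  cc <- crossover / 255
  per_slice(img, function(m) {
    mu <- m / 255
    for (i in seq_len(iterations)) {
      lo <- mu <= cc
      mu[lo] <- mu[lo]^2 / cc
      mu[!lo] <- 1 - (1 - mu[!lo])^2 / (1 - cc)
    }
    pmin(pmax(mu * 255, 0), 255)
  })
}
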