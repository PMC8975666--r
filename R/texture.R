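#' Gray-level co-occurrence matrix
#'
#' Re-quantizes the image to \code{levels} gray bins and counts ordered
#' level pairs at the given pixel offset, symmetrized over both directions
#' and normalized to sum 1.
#'
#' @param img matrix of 8-bit intensities.
#' @param offset integer (delta-row, delta-col) displacement; must fit
#'   inside the image.
#' @param levels number of quantization levels (>= 2, default 8).
#' @return object of class \code{"glcm"}: list with \code{p} (levels x
#'   levels joint-frequency matrix), \code{levels}, \code{offset}.
#' @examples
#' chk <- matrix(c(0, 255, 255, 0), 2)
#' glcm(chk, offset = c(0, 1), levels = 2)$p   # 0.5 off-diagonal
#' @export
glcm <- function(img, offset = c(0L, 1L), levels = 8L) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (levels < 2L) stop("levels must be >= 2")
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (abs(dr) >= nrow(img) || abs(dc) >= ncol(img))
    stop("offset lies beyond the image extent")
  q <- pmin(floor(img / 256 * levels), levels - 1L) + 1L
  rs <- seq_len(nrow(img) - abs(dr))
  cs <- seq_len(ncol(img) - abs(dc))
  a <- q[rs + max(0L, -dr), cs + max(0L, -dc), drop = FALSE]
  b <- q[rs + max(0L, dr), cs + max(0L, dc), drop = FALSE]
  cnt <- matrix(tabulate((as.vector(a) - 1L) * levels + as.vector(b),
                         nbins = levels * levels),
                levels, levels, byrow = TRUE)
  cnt <- cnt + t(cnt)                         # symmetrize: both directions
  structure(list(p = cnt / sum(cnt), levels = levels, offset = c(dr, dc)),
            class = "glcm")
}

#' Texture features from a co-occurrence matrix
#'
#' Two evaluation forms are provided.  \code{"standard"} (default) computes
#' the conventional GLCM features: contrast (inertia)
#' sum (i-j)^2 p(i,j), mean sum i p(i,j), and entropy
#' -sum p(i,j) log2 p(i,j) in bits.  \code{"printed"} evaluates the
#' formula set exactly as typeset in the source material
#' (tf1 = sum (i-j) p(i,j)^2, tf8 = sum p(i,j)/(M N),
#' tf10 = sum (i-j) p(i,j) lg p(i,j), with 0 lg 0 = 0); that form is kept
#' for fidelity but its inertia vanishes on symmetric matrices, which is why
#' \code{"standard"} is the default (see the methods vignette).
#'
#' @param m a [glcm()] result (or a normalized matrix).
#' @param form \code{"standard"} or \code{"printed"}.
#' @return object of class \code{"texture_features"}: list with
#'   \code{inertia}, \code{mean}, \code{entropy}, \code{form}.
#' @export
texture_features <- function(m, form = c("standard", "printed")) {
  form <- match.arg(form)
  p <- if (inherits(m, "glcm")) m$p else as.matrix(m)
  if (abs(sum(p) - 1) > 1e-6) stop("co-occurrence matrix is not normalized")
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  if (form == "standard") {
    lg2 <- ifelse(p > 0, log2(p), 0)
    out <- list(inertia = sum((i - j)^2 * p),
                mean = sum(i * p),
                entropy = -sum(p * lg2))
  } else {
    lg10 <- ifelse(p > 0, log10(p), 0)
    out <- list(inertia = sum((i - j) * p^2),
                mean = sum(p) / (n * n),
                entropy = sum((i - j) * p * lg10))
  }
  structure(c(out, form = form), class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf("Texture features (%s form): inertia = %.4f, mean = %.4f, entropy = %.4f\n",
              x$form, x$inertia, x$mean, x$entropy))
  invisible(x)
}
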