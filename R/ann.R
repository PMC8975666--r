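# From-scratch backpropagation pixel classifier (single hidden layer,
# sigmoid units, squared-error objective, per-sample gradient-descent
# updates).  Bias terms are realized as weights from an always-on constant
# unit appended to each layer's output.

sigmoid <- function(h) 1 / (1 + exp(-h))

# Initialize a network: weights uniform in [-0.5, 0.5].
nn_init <- function(n_in, n_hidden, n_out = 1L, seed = 1L) {
  with_seed(seed, {
    structure(list(
      sizes = as.integer(c(n_in, n_hidden, n_out)),
      w1 = matrix(stats::runif((n_in + 1L) * n_hidden, -0.5, 0.5),
                  n_in + 1L, n_hidden),
      w2 = matrix(stats::runif((n_hidden + 1L) * n_out, -0.5, 0.5),
                  n_hidden + 1L, n_out)
    ), class = "pixel_classifier")
  })
}

# Forward pass; X is samples x n_in.
nn_forward <- function(net, x) {
  x <- as.matrix(x)
  h <- sigmoid(cbind(x, 1) %*% net$w1)
  o <- sigmoid(cbind(h, 1) %*% net$w2)
  list(hidden = h, output = o)
}

# Analytic gradient of E = 0.5 * sum((output - target)^2) for a batch.
# Output deltas (V - T) V (1 - V); hidden deltas backpropagate through w2.
nn_gradient <- function(net, x, target) {
  x <- as.matrix(x); target <- as.matrix(target)
  fw <- nn_forward(net, x)
  o <- fw$output; h <- fw$hidden
  d_out <- (o - target) * o * (1 - o)
  nh <- ncol(h)
  d_hid <- (h * (1 - h)) * (d_out %*% t(net$w2[seq_len(nh), , drop = FALSE]))
  list(g1 = t(cbind(x, 1)) %*% d_hid,
       g2 = t(cbind(h, 1)) %*% d_out,
       error = 0.5 * sum((o - target)^2))
}

# Hidden-layer size bounds: lower = rounded mean of input and output widths,
# upper = N_s / (alpha * (N_i + N_o)) with alpha in 2..10.
hidden_bounds <- function(n_in, n_out, n_samples, alpha = 5) {
  list(lower = max(1L, round((n_in + n_out) / 2)),
       upper = floor(n_samples / (alpha * (n_in + n_out))))
}

#' Train the backpropagation pixel classifier
#'
#' Single-hidden-layer sigmoid network trained by per-sample (online)
#' gradient descent on the squared-error objective, visiting samples in a
#' seeded shuffled order each epoch.  The hidden-layer width must respect
#' the overfitting guard N_h <= N_s / (alpha (N_i + N_o)) with the rounded
#' mean of N_i and N_o as lower bound.
#'
#' @param features numeric matrix, one row per pixel sample.
#' @param labels 0/1 vector (non-target / target).
#' @param hidden hidden-unit count; default: the lower bound.
#' @param rate learning rate in (0, 1] (default 0.3); 0 leaves the weights
#'   untouched.
#' @param epochs training epochs (default 200).
#' @param alpha overfitting-guard constant in 2..10 (default 5).
#' @param seed RNG seed for initialization and shuffling.
#' @return object of class \code{"pixel_classifier"} with the weight
#'   matrices, \code{epoch_error} (summed squared error per epoch) and the
#'   training layout.
#' @export
train_pixel_classifier <- function(features, labels, hidden = NULL,
                                   rate = 0.3, epochs = 200L, alpha = 5,
                                   seed = 1L) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (length(labels) != nrow(features)) stop("labels must match feature rows")
  if (rate < 0 || rate > 1) stop("learning rate must lie in [0, 1]")
  n_in <- ncol(features); n_out <- 1L; n_s <- nrow(features)
  b <- hidden_bounds(n_in, n_out, n_s, alpha)
  if (is.null(hidden)) hidden <- b$lower
  if (hidden < b$lower || hidden > b$upper)
    stop(sprintf(paste0("hidden-unit count %d violates the bound ",
                        "[%d, %d] = [mean(N_i, N_o), N_s/(alpha(N_i+N_o))]"),
                 hidden, b$lower, b$upper))
  net <- nn_init(n_in, hidden, n_out, seed = seed)
  epoch_error <- numeric(epochs)
  with_seed(derive_seed(seed, 1L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_s)
      err <- 0
      for (ii in ord) {
        g <- nn_gradient(net, features[ii, , drop = FALSE], labels[ii])
        net$w1 <- net$w1 - rate * g$g1
        net$w2 <- net$w2 - rate * g$g2
        err <- err + g$error
      }
      epoch_error[ep] <- err
    }
  })
  net$epoch_error <- epoch_error
  net$rate <- rate
  net$alpha <- alpha
  net$n_samples <- n_s
  net
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("Backprop pixel classifier: %d-%d-%d (sigmoid)\n",
              x$sizes[1], x$sizes[2], x$sizes[3]))
  if (!is.null(x$epoch_error))
    cat(sprintf("  trained %d epochs, final squared error %.4f\n",
                length(x$epoch_error), x$epoch_error[length(x$epoch_error)]))
  invisible(x)
}

#' @export
predict.pixel_classifier <- function(object, newdata,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- nn_forward(object, as.matrix(newdata))$output[, 1]
  if (type == "prob") p else as.integer(p >= 0.5)
}

# Window extrema via shift-stack comparison (radius r, replicated edges).
local_extrema <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  mx <- m; mn <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
            pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
    mx <- pmax(mx, sh); mn <- pmin(mn, sh)
  }
  list(min = mn, max = mx)
}

#' Per-pixel feature channels for segmentation
#'
#' The default channels feeding the pixel classifier, all scaled to [0, 1]:
#' normalized intensity, local mean, local standard deviation, a local
#' texture-entropy channel (Shannon entropy of the quantized gray levels in
#' the window, in bits, divided by its maximum), and a local roughness
#' channel (the differential box count of the window's gray span at the
#' window scale, normalized).
#'
#' @param img matrix of 8-bit intensities (a 3D stack is processed per
#'   slice and the rows stacked).
#' @param radius neighborhood radius in pixels (default 2).
#' @param levels quantization levels for the entropy channel (default 8).
#' @return numeric matrix with one row per pixel (column-major pixel order,
#'   slices concatenated) and 5 feature columns.
#' @export
pixel_features <- function(img, radius = 2L, levels = 8L) {
  one <- function(m) {
    w <- 2L * radius + 1L
    st <- box_stats(m, w)
    ex <- local_extrema(m, radius)
    q <- pmin(floor(m / 256 * levels), levels - 1L)
    tot <- w * w
    ent <- 0
    for (l in 0:(levels - 1L)) {
      cl <- box_sum((q == l) * 1, w) / tot
      ent <- ent - ifelse(cl > 0, cl * log2(cl), 0)
    }
    h <- w * 256 / nrow(m)                 # window-scale gray box height
    nboxes <- floor(ex$max / h) - floor(ex$min / h) + 1
    cbind(intensity = as.vector(m) / 255,
          local_mean = as.vector(st$mean) / 255,
          local_sd = as.vector(sqrt(st$var)) / 255,
          local_entropy = as.vector(ent) / log2(levels),
          local_roughness = as.vector(nboxes) / (256 / h + 1))
  }
  if (is.matrix(img)) return(one(img))
  do.call(rbind, lapply(seq_len(dim(img)[1]), function(s) one(img[s, , ])))
}

#' Segment a lesion with a trained pixel classifier
#'
#' Classifies every pixel (output unit thresholded at 0.5) and retains the
#' largest connected component (8-connectivity in 2D, 26-connectivity in
#' 3D) as the lesion mask.
#'
#' @param img matrix or 3D slice stack.
#' @param classifier a trained [train_pixel_classifier()] model.
#' @param radius,levels feature-extraction settings; must match training.
#' @return logical mask of the image shape (empty with a warning when no
#'   pixel is classified as target).
#' @export
segment <- function(img, classifier, radius = 2L, levels = 8L) {
  feats <- pixel_features(img, radius = radius, levels = levels)
  lab <- predict(classifier, feats, type = "class")
  if (is.matrix(img)) {
    mask <- matrix(lab == 1L, nrow(img), ncol(img))
  } else {
    d <- dim(img)
    mask <- array(FALSE, d)
    per <- d[2] * d[3]
    for (s in seq_len(d[1]))
      mask[s, , ] <- matrix(lab[(s - 1L) * per + seq_len(per)] == 1L,
                            d[2], d[3])
  }
  if (!any(mask)) {
    warning("no pixel classified as target: empty mask", call. = FALSE)
    return(mask)
  }
  keep_largest_component(mask)
}

# Connected-component labelling by iterative minimum-label propagation
# (8-neighborhood for matrices, 26-neighborhood for 3D arrays).
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  lab[mask] <- seq_len(sum(mask))
  shifts <- if (length(d) == 2L) {
    expand.grid(dr = -1:1, dc = -1:1, ds = 0)
  } else {
    expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  }
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0 & shifts$ds == 0), ]
  idx <- function(n, dlt) pmin(pmax(seq_len(n) + dlt, 1L), n)
  repeat {
    new <- lab
    for (k in seq_len(nrow(shifts))) {
      if (length(d) == 2L) {
        sh <- lab[idx(d[1], shifts$dr[k]), idx(d[2], shifts$dc[k]),
                  drop = FALSE]
      } else {
        sh <- lab[idx(d[1], shifts$ds[k]), idx(d[2], shifts$dr[k]),
                  idx(d[3], shifts$dc[k]), drop = FALSE]
      }
      pos <- new > 0L & sh > 0L & sh < new
      new[pos] <- sh[pos]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

keep_largest_component <- function(mask) {
  lab <- label_components(mask)
  tab <- table(lab[lab > 0L])
  big <- as.integer(names(tab)[which.max(tab)])
  array(lab == big, dim = dim(mask))
}
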