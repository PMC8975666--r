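#' Lesion measurement record
#'
#' Holds the longest in-plane diameter (mm) and the volume (cm^3) of a
#' connected lesion.  The exact volume is stored; exports round it to
#' 0.1 cm^3 (see [volume_change()]).
#'
#' @param diameter_mm longest in-plane diameter in mm.
#' @param volume_cm3 volume in cm^3.
#' @param n_voxels voxel count of the component.
#' @param degenerate flag for empty or single-voxel masks.
#' @export
lesion_measurement <- function(diameter_mm, volume_cm3, n_voxels = NA_integer_,
                               degenerate = FALSE) {
  if (diameter_mm < 0 || volume_cm3 < 0)
    stop("diameter and volume must be non-negative")
  structure(list(diameter_mm = diameter_mm, volume_cm3 = volume_cm3,
                 n_voxels = n_voxels, degenerate = degenerate),
            class = "lesion_measurement")
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf("Lesion: long diameter %.1f mm, volume %.1f cm^3%s\n",
              x$diameter_mm, round(x$volume_cm3, 1),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Measure a segmented lesion
#'
#' Longest in-plane diameter: the maximum pairwise distance between
#' boundary-pixel centers within the slice that maximizes it, in mm.
#' Volume: voxel count times voxel volume, in cm^3 (exact value stored;
#' round to 0.1 for reporting).
#'
#' @param mask logical matrix (single slice) or 3D array (slices, rows,
#'   cols).  If several connected components are present the largest is
#'   measured unless \code{component} gives a label from
#'   the internal component labelling.
#' @param spacing voxel spacing in mm: (row, col) for a matrix,
#'   (slice, row, col) for a stack.
#' @param component optional component id.
#' @return a [lesion_measurement()]; an empty mask yields a zero measurement
#'   flagged degenerate.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(21, 64, 64),
#'                                 semiaxes = c(10, 10, 10)))
#' measure_lesion(ph$mask, spacing = ph$spec$spacing)
#' @export
measure_lesion <- function(mask, spacing, component = NULL) {
  is2d <- is.matrix(mask)
  if (is2d) {
    mask <- array(mask, dim = c(1L, dim(mask)))
    spacing <- c(1, spacing)
  }
  d <- dim(mask)
  if (!any(mask))
    return(lesion_measurement(0, 0, 0L, degenerate = TRUE))
  lab <- label_components(mask)
  if (is.null(component)) {
    tab <- table(lab[lab > 0L])
    component <- as.integer(names(tab)[which.max(tab)])
  }
  sel <- lab == component
  nv <- sum(sel)
  vol <- nv * prod(spacing) / 1000
  dia <- 0
  for (s in seq_len(d[1])) {
    sl <- sel[s, , ]
    if (!any(sl)) next
    dia <- max(dia, slice_diameter(sl, spacing[2:3]))
  }
  lesion_measurement(dia, vol, nv, degenerate = nv <= 1L)
}

# Longest diameter within one slice: max pairwise distance between boundary
# pixel centers, computed on the convex hull.
slice_diameter <- function(sl, spacing) {
  idx <- which(sl, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(0)
  nr <- nrow(sl); nc <- ncol(sl)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sl
  i <- idx[, 1] + 1L; j <- idx[, 2] + 1L
  interior <- pad[cbind(i - 1L, j)] & pad[cbind(i + 1L, j)] &
    pad[cbind(i, j - 1L)] & pad[cbind(i, j + 1L)]
  bdry <- idx[!interior, , drop = FALSE]
  pts <- cbind(bdry[, 1] * spacing[1], bdry[, 2] * spacing[2])
  if (nrow(pts) > 2L) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Volume change between timepoints
#'
#' Difference pre - post in cm^3, reported to 0.1 cm^3.  For the normal-lung
#' surrogate (lung volume grows as the tumor shrinks), call
#' \code{volume_change(post, pre)} so that the increase of normal lung reads
#' as the equivalent tumor reduction.
#'
#' @param pre,post volumes in cm^3 (>= 0).
#' @return signed change in cm^3, rounded to 0.1.
#' @examples
#' volume_change(53.6, 48.1)        # 5.5
#' volume_change(2327.4, 2139.0)    # 188.4: normal-lung increase
#' @export
volume_change <- function(pre, post) {
  if (pre < 0 || post < 0) stop("volumes must be non-negative")
  round(pre - post, 1)
}
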