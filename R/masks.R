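#' Tumor mask objects
#'
#' A tumor mask is a 2-D logical grid (rows x cols, origin top-left) with
#' exactly one 4-connected foreground component, as produced by outlining a
#' tumor in an image-analysis tool.
#'
#' @param m Logical (or 0/1 numeric) matrix; `TRUE`/nonzero = foreground.
#' @param pixel_scale Optional physical scale, mm per pixel.
#' @param validate Check the single-component invariant (default `TRUE`).
#' @return An object of class `tumor_mask` (a logical matrix with attributes).
#' @export
tumor_mask <- function(m, pixel_scale = NULL, validate = TRUE) {
  stopifnot(is.matrix(m))
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  if (validate) {
    if (!any(m)) abort("Mask has no foreground pixels.")
    n_comp <- max(EBImage::bwlabel(m * 1L))
    if (n_comp != 1) {
      abort(sprintf("Mask must have exactly one 4-connected component (found %d).",
                    n_comp))
    }
  }
  structure(m, pixel_scale = pixel_scale, class = c("tumor_mask", "matrix", "array"))
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %d x %d px, %d foreground px\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# strip class for matrix arithmetic
mask_matrix <- function(mask) matrix(as.logical(mask), nrow(mask), ncol(mask))

#' Generate a synthetic tumor mask
#'
#' Renders a parametric shape onto a square canvas by a center-of-pixel
#' inclusion test. `"perturbed_blob"` deforms a circle of radius `r` with a
#' random low-order Fourier perturbation of the boundary radius; with
#' `perturbation = 0` it reproduces the base circle exactly, and increasing
#' `perturbation` yields increasingly irregular (higher F-value) outlines.
#'
#' @param shape One of `"circle"`, `"ellipse"`, `"square"`,
#'   `"perturbed_blob"`.
#' @param size_px Canvas side length in pixels.
#' @param r Circle / blob base radius (px).
#' @param a,b Ellipse semi-axes (px): `a` along columns, `b` along rows.
#' @param side Square side length (px).
#' @param perturbation Relative amplitude of the blob boundary perturbation.
#' @param n_harmonics Number of Fourier harmonics in the blob perturbation.
#' @param seed Integer seed (used by `"perturbed_blob"` only).
#' @param pixel_scale Optional mm per pixel, carried on the mask.
#'
#' @return A [tumor_mask].
#' @export
#' @examples
#' mask <- generate_tumor_mask("circle", size_px = 128, r = 50)
#' sum(mask) / (pi * 50^2)  # close to 1
generate_tumor_mask <- function(shape = c("circle", "ellipse", "square",
                                          "perturbed_blob"),
                                size_px = 128, r = 40, a = 40, b = 20,
                                side = 60, perturbation = 0.15,
                                n_harmonics = 4, seed = NULL,
                                pixel_scale = NULL) {
  shape <- match.arg(shape)
  c0 <- (size_px + 1) / 2
  half <- size_px / 2
  extent <- switch(shape,
    circle = r, ellipse = max(a, b), square = side / 2,
    perturbed_blob = r * (1 + abs(perturbation)))
  if (extent + 2 > half) {
    abort("Shape does not fit inside the canvas with a 2 px margin.")
  }

  rows <- matrix(seq_len(size_px), size_px, size_px) - c0        # y
  cols <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE) - c0  # x

  m <- switch(shape,
    circle = rows^2 + cols^2 <= r^2,
    ellipse = (cols / a)^2 + (rows / b)^2 <= 1,
    square = abs(rows) <= side / 2 & abs(cols) <= side / 2,
    perturbed_blob = with_seed(seed, {
      ks <- seq_len(n_harmonics) + 1L   # harmonics 2..n+1; k=1 would translate
      ak <- rnorm(n_harmonics) / ks
      bk <- rnorm(n_harmonics) / ks
      theta <- atan2(rows, cols)
      wobble <- matrix(0, size_px, size_px)
      for (i in seq_along(ks)) {
        wobble <- wobble + ak[i] * cos(ks[i] * theta) + bk[i] * sin(ks[i] * theta)
      }
      r_theta <- pmax(r * (1 + perturbation * wobble), 0.2 * r)
      rows^2 + cols^2 <= r_theta^2
    }))
  tumor_mask(m, pixel_scale = pixel_scale)
}

#' Read/write binary masks as PNG or TIFF
#'
#' Files are written as 8-bit grayscale with 0 = background and 255 =
#' foreground; on reading, any nonzero pixel is foreground.
#'
#' @param mask A logical matrix (e.g. a [tumor_mask]).
#' @param path File path; the extension (`.png`, `.tif`, `.tiff`) selects the
#'   format.
#' @param validate Passed to [tumor_mask()] when reading.
#' @return `path` (write) or a [tumor_mask] (read).
#' @export
write_mask <- function(mask, path) {
  img <- mask_matrix(mask) * 1.0
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path)
  else abort("Unsupported mask format; use .png or .tif/.tiff.")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, validate = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else abort("Unsupported mask format; use .png or .tif/.tiff.")
  if (length(dim(img)) == 3) img <- img[, , 1]
  tumor_mask(img > 0, validate = validate)
}
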