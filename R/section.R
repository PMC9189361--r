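#' Liver section masks
#'
#' Pairs a liver mask with a lesion mask on the same pixel grid, together
#' with the invasion geometry: the axis along which depth is measured and the
#' capsule edge where the tumor-cell hydrogel drop was adhered (invasion
#' proceeds inward from that surface).
#'
#' @param liver_mask,lesion_mask Logical matrices of equal dimensions; the
#'   lesion must lie entirely within the liver.
#' @param invasion_axis `"rows"` (depth runs down the rows) or `"cols"`.
#' @param capsule_edge `"start"` (first row/column is the capsule surface) or
#'   `"end"`.
#' @return An object of class `section_mask`.
#' @export
section_mask <- function(liver_mask, lesion_mask,
                         invasion_axis = c("rows", "cols"),
                         capsule_edge = c("start", "end")) {
  invasion_axis <- match.arg(invasion_axis)
  capsule_edge <- match.arg(capsule_edge)
  liver_mask <- mask_matrix(liver_mask)
  lesion_mask <- mask_matrix(lesion_mask)
  if (!identical(dim(liver_mask), dim(lesion_mask))) {
    abort("Liver and lesion masks must have identical dimensions.")
  }
  if (!any(liver_mask)) abort("Liver mask has no foreground pixels.")
  if (any(lesion_mask & !liver_mask)) {
    abort("Lesion pixels must lie within the liver mask.")
  }
  structure(list(liver = liver_mask, lesion = lesion_mask,
                 invasion_axis = invasion_axis, capsule_edge = capsule_edge),
            class = "section_mask")
}

#' @export
print.section_mask <- function(x, ...) {
  cat(sprintf("<section_mask> %d x %d px; liver %d px, lesion %d px (%s, capsule at %s)\n",
              nrow(x$liver), ncol(x$liver), sum(x$liver), sum(x$lesion),
              x$invasion_axis, x$capsule_edge))
  invisible(x)
}

#' Generate a synthetic liver section with an invasion front
#'
#' Renders a rectangular liver slab spanning `total_depth_px` along the
#' invasion axis and a lesion extending from the capsule edge to exactly
#' `lesion_depth_px`, so the downstream relative invasion is
#' `lesion_depth_px / total_depth_px` by construction. The lesion's lateral
#' profile is jittered (seeded) to avoid a perfectly straight front; its
#' maximal depth is pinned exactly.
#'
#' @param total_depth_px Liver depth in pixels.
#' @param lesion_depth_px Deepest lesion extent from the capsule, in pixels
#'   (0 = no lesion).
#' @param width_px Section width perpendicular to the invasion axis.
#' @param seed Integer seed for the lateral jitter.
#' @return A [section_mask()] with `invasion_axis = "rows"` and the capsule
#'   at the first row.
#' @export
#' @examples
#' relative_invasion(generate_section(120, 30, 100))$relative_invasion  # 0.25
generate_section <- function(total_depth_px, lesion_depth_px, width_px,
                             seed = NULL) {
  stopifnot(total_depth_px >= 1, width_px >= 1)
  if (lesion_depth_px < 0 || lesion_depth_px > total_depth_px) {
    abort("`lesion_depth_px` must lie in [0, total_depth_px].")
  }
  liver <- matrix(TRUE, total_depth_px, width_px)
  lesion <- matrix(FALSE, total_depth_px, width_px)
  if (lesion_depth_px >= 1) {
    with_seed(seed, {
      lo <- max(1L, floor(width_px / 3))
      hi <- min(width_px, ceiling(2 * width_px / 3))
      depths <- pmax(1L, pmin(as.integer(lesion_depth_px),
        as.integer(round(lesion_depth_px * (0.7 + 0.3 * runif(hi - lo + 1L))))))
      depths[ceiling(length(depths) / 2)] <- as.integer(lesion_depth_px)
      for (k in seq_along(depths)) {
        lesion[seq_len(depths[k]), lo + k - 1L] <- TRUE
      }
    })
  }
  section_mask(liver, lesion)
}

#' Threshold a grayscale image into a mask
#'
#' Simple intensity thresholding for stained-section images. For the liver
#' compartment only the largest 4-connected component is kept
#' (`keep = "largest"`); for lesions all components are kept
#' (`keep = "all"`).
#'
#' @param image Numeric matrix of intensities.
#' @param threshold Intensity threshold.
#' @param polarity `"below"` (foreground where intensity <= threshold) or
#'   `"above"`.
#' @param keep `"all"` or `"largest"`.
#' @return A logical mask matrix.
#' @export
mask_from_intensity <- function(image, threshold,
                                polarity = c("below", "above"),
                                keep = c("all", "largest")) {
  polarity <- match.arg(polarity)
  keep <- match.arg(keep)
  stopifnot(is.matrix(image), is.numeric(image))
  m <- if (polarity == "below") image <= threshold else image >= threshold
  if (!any(m)) abort("Thresholding produced an empty mask.")
  if (keep == "largest") {
    lab <- EBImage::bwlabel(m * 1L)
    counts <- tabulate(lab[lab > 0])
    m <- matrix(lab == which.max(counts), nrow(m), ncol(m))
  }
  m
}

#' Relative invasion depth of a section
#'
#' Measures the total liver depth as the maximal per-line extent of the liver
#' mask along the invasion axis, and the invaded depth as the maximal
#' distance of any lesion pixel from the capsule edge along that axis. The
#' relative invasion is their ratio, in `[0, 1]` (0 when there is no lesion).
#'
#' @param section A [section_mask()].
#' @return A one-row tibble: `total_depth`, `invaded_depth`,
#'   `relative_invasion`.
#' @export
relative_invasion <- function(section) {
  stopifnot(inherits(section, "section_mask"))
  liver <- section$liver
  lesion <- section$lesion
  if (section$invasion_axis == "cols") {
    liver <- t(liver); lesion <- t(lesion)
  }
  if (section$capsule_edge == "end") {
    liver <- liver[rev(seq_len(nrow(liver))), , drop = FALSE]
    lesion <- lesion[rev(seq_len(nrow(lesion))), , drop = FALSE]
  }
  # per-column extent of the liver, then the maximum across columns
  extents <- apply(liver, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) 0L else max(w) - min(w) + 1L
  })
  total_depth <- max(extents)
  invaded_depth <- if (!any(lesion)) 0L else max(which(rowSums(lesion) > 0))
  tibble(total_depth = as.integer(total_depth),
         invaded_depth = as.integer(invaded_depth),
         relative_invasion = invaded_depth / total_depth)
}

#' Score a set of sections
#'
#' @param sections Named list of [section_mask()] objects.
#' @param groups Optional group labels (recycled against `sections`).
#' @return A tibble: `section_id`, `group`, `total_depth_px`,
#'   `invaded_depth_px`, `relative_invasion`.
#' @export
invasion_report <- function(sections, groups = NA_character_) {
  stopifnot(is.list(sections), length(sections) >= 1)
  ids <- names(sections) %||% sprintf("section_%d", seq_along(sections))
  groups <- rep_len(groups, length(sections))
  purrr::map2(sections, seq_along(sections), function(s, i) {
    ri <- relative_invasion(s)
    tibble(section_id = ids[i], group = groups[i],
           total_depth_px = ri$total_depth, invaded_depth_px = ri$invaded_depth,
           relative_invasion = ri$relative_invasion)
  }) |> bind_rows()
}
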