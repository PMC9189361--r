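# Shape-regularity morphometry: maximum Feret axis, minimum enclosing circle
# and the F-value (enclosing area minus tumor area, over enclosing area).

# Boundary pixel centers of a mask as an n x 2 matrix of (row, col).
boundary_points <- function(m) {
  m <- mask_matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
           pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(m & !inner, arr.ind = TRUE)
}

# Convex hull vertices (row, col) of a point matrix; handles n < 3.
hull_points <- function(pts) {
  if (nrow(pts) <= 2) return(pts)
  idx <- grDevices::chull(pts[, 2], pts[, 1])
  pts[idx, , drop = FALSE]
}

#' Maximum Feret diameter (tumor long axis)
#'
#' The largest Euclidean distance between any two foreground boundary pixel
#' centers, computed over the convex hull of the boundary (the diameter of a
#' point set is attained at hull vertices). Holes are filled first.
#'
#' @param mask A [tumor_mask] (or logical matrix with one foreground
#'   component).
#' @return The long axis in pixels (0 for a single-pixel mask).
#' @export
#' @examples
#' long_axis(generate_tumor_mask("circle", r = 50, size_px = 128))  # ~100
long_axis <- function(mask) {
  m <- filled_mask(mask)
  h <- hull_points(boundary_points(m))
  if (nrow(h) < 2) return(0)
  max(stats::dist(h))
}

filled_mask <- function(mask) {
  m <- mask_matrix(mask)
  if (!any(m)) abort("Mask has no foreground pixels.")
  matrix(as.logical(EBImage::fillHull(m * 1L)), nrow(m), ncol(m))
}

# --- minimum enclosing circle (Welzl) --------------------------------------

circle_from2 <- function(p, q) {
  list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
}

circle_from3 <- function(p, q, r) {
  # circumcircle; falls back to the widest 2-point circle when collinear
  d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
  if (abs(d) < 1e-9) {
    cands <- list(circle_from2(p, q), circle_from2(p, r), circle_from2(q, r))
    return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
  }
  ux <- (sum(p^2) * (q[2] - r[2]) + sum(q^2) * (r[2] - p[2]) +
         sum(r^2) * (p[2] - q[2])) / d
  uy <- (sum(p^2) * (r[1] - q[1]) + sum(q^2) * (p[1] - r[1]) +
         sum(r^2) * (q[1] - p[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
}

trivial_circle <- function(boundary) {
  n <- length(boundary)
  if (n == 0) list(center = c(NA_real_, NA_real_), radius = 0)
  else if (n == 1) list(center = boundary[[1]], radius = 0)
  else if (n == 2) circle_from2(boundary[[1]], boundary[[2]])
  else circle_from3(boundary[[1]], boundary[[2]], boundary[[3]])
}

in_circle <- function(p, circ) {
  !is.na(circ$center[1]) &&
    sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + 1e-10) + 1e-9
}

#' Minimum enclosing circle of a point set
#'
#' Welzl's algorithm over the convex hull of the input points. Deterministic:
#' the internal point order is fixed.
#'
#' @param pts An n x 2 numeric matrix of point coordinates.
#' @return List with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  pts <- hull_points(pts)
  n <- nrow(pts)
  if (n == 0) abort("No points supplied.")
  ord <- with_seed(19937, sample.int(n))  # fixed shuffle for Welzl
  pts <- pts[ord, , drop = FALSE]
  welzl <- function(i, boundary) {
    if (i > n || length(boundary) == 3) return(trivial_circle(boundary))
    p <- pts[i, ]
    circ <- welzl(i + 1, boundary)
    if (in_circle(p, circ)) return(circ)
    welzl(i + 1, c(boundary, list(p)))
  }
  old <- options(expressions = max(getOption("expressions"), 50000))
  on.exit(options(old))
  welzl(1, list())
}

#' Tumor shape metrics and F-value
#'
#' Measures a tumor mask the way outline-based image analysis does: the tumor
#' area is the foreground pixel count (holes filled); the perimeter is the
#' traced outer contour length with diagonal steps weighted sqrt(2); the long
#' axis is the maximum Feret diameter; the selected area is the area of the
#' minimum enclosing circle of the tumor boundary, inflated by half a pixel
#' diagonal so the circle covers whole pixels and the selected area can never
#' fall below the tumor area. The F-value is
#' `(area_selected - area_tumor) / area_selected`: 0 for a perfect disc and
#' approaching 1 as the outline departs from a circle, so larger F means a
#' less regular shape.
#'
#' @param mask A [tumor_mask].
#' @return A one-row tibble: `area_tumor`, `perimeter`, `long_axis`,
#'   `area_selected`, `f_value`.
#' @export
#' @examples
#' shape_metrics(generate_tumor_mask("ellipse", a = 40, b = 20))$f_value  # ~0.5
shape_metrics <- function(mask) {
  m <- filled_mask(mask)
  area_tumor <- sum(m)
  bnd <- boundary_points(m)
  mec <- min_enclosing_circle(bnd)
  radius <- mec$radius + sqrt(2) / 2   # cover pixel squares, not just centers
  area_selected <- pi * radius^2
  contour <- EBImage::ocontour(EBImage::bwlabel(m * 1L))[[1]]
  perimeter <- if (nrow(contour) < 2) 0 else {
    steps <- sqrt(rowSums((contour - contour[c(2:nrow(contour), 1), ])^2))
    sum(ifelse(steps > 1.01, sqrt(2), steps))
  }
  tibble(
    area_tumor = area_tumor,
    perimeter = perimeter,
    long_axis = if (nrow(bnd) < 2) 0 else max(stats::dist(hull_points(bnd))),
    area_selected = area_selected,
    f_value = (area_selected - area_tumor) / area_selected
  )
}

#' Caliper tumor volume
#'
#' The standard xenograft caliper formula: volume = width^2 x length / 2,
#' with width and length in mm and volume in mm^3.
#'
#' @param width_mm,length_mm Caliper measurements in mm; requires
#'   `0 < width_mm <= length_mm`.
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 20)  # 1000
tumor_volume <- function(width_mm, length_mm) {
  if (any(width_mm <= 0) || any(length_mm <= 0)) {
    abort("Width and length must be positive.")
  }
  if (any(width_mm > length_mm)) {
    abort("Width must not exceed length (length is the long axis).")
  }
  width_mm^2 * length_mm / 2
}

#' Per-tumor F-value table with group summary
#'
#' Scores a list of tumor masks and lays the result out like a per-group
#' shape-regularity table: one row per tumor with its metrics, missing tumors
#' (entries that are `NULL` or `NA`, e.g. animals that grew no tumor)
#' preserved as `NA` rows. The group summary (mean +/- SD of F, excluding
#' missing tumors) is available via [regularity_summary()].
#'
#' @param masks List of [tumor_mask] objects; `NULL`/`NA` entries mark
#'   missing tumors.
#' @param groups Character vector of group labels, one per mask.
#' @param tumor_ids Optional identifiers; defaults to per-group tumor numbers.
#' @return A tibble of class `regularity_report`: `tumor_id`, `group`,
#'   `area_px`, `perimeter_px`, `long_axis_px`, `area_selected_px`,
#'   `f_value`.
#' @export
regularity_report <- function(masks, groups, tumor_ids = NULL) {
  stopifnot(length(masks) == length(groups))
  if (length(masks) == 0) abort("At least one mask is required.")
  missing <- vapply(masks, function(m) is.null(m) ||
                      (length(m) == 1 && is.na(m)), logical(1))
  if (any(!nzchar(groups)) ||
      any(!groups %in% groups[!missing])) {
    abort("Every group must contain at least one measured tumor.")
  }
  if (is.null(tumor_ids)) {
    tumor_ids <- stats::ave(seq_along(groups), groups, FUN = seq_along)
    tumor_ids <- sprintf("%s_%d", groups, tumor_ids)
  }
  rows <- purrr::map2(masks, seq_along(masks), function(m, i) {
    if (missing[i]) {
      tibble(area_px = NA_real_, perimeter_px = NA_real_,
             long_axis_px = NA_real_, area_selected_px = NA_real_,
             f_value = NA_real_)
    } else {
      sm <- shape_metrics(m)
      tibble(area_px = sm$area_tumor, perimeter_px = sm$perimeter,
             long_axis_px = sm$long_axis, area_selected_px = sm$area_selected,
             f_value = sm$f_value)
    }
  })
  out <- bind_rows(rows) |>
    mutate(tumor_id = tumor_ids, group = groups, .before = 1)
  class(out) <- c("regularity_report", class(out))
  out
}

#' @rdname regularity_report
#' @param report A `regularity_report` tibble.
#' @export
regularity_summary <- function(report) {
  as_tibble(report) |>
    group_by(group) |>
    summarise(
      n = sum(!is.na(.data$f_value)),
      n_missing = sum(is.na(.data$f_value)),
      mean_f = mean(.data$f_value, na.rm = TRUE),
      sd_f = sd(.data$f_value, na.rm = TRUE),
      .groups = "drop"
    )
}
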