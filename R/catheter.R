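#' Build a star-catheter layout
#'
#' Describes the geometry of a multi-spline mapping catheter: `n_splines`
#' radial splines spread evenly over the circle, each carrying
#' `electrodes_per_spline` electrodes at increasing radial distance. The
#' default call `build_layout()` reproduces the 5-spline, 20-electrode star
#' catheter used for atrial mapping (20 unipolar / 15 bipolar channels).
#'
#' Electrodes are indexed 0-based internally as `(spline, position)` with
#' `spline` in `0:(n_splines-1)` (by increasing angle, counterclockwise) and
#' `position` in `0:(electrodes_per_spline-1)` (innermost first). The flat
#' channel index of electrode `(s, p)` in the canonical unipolar-by-spline
#' ordering is `s * electrodes_per_spline + p`.
#'
#' @param n_splines number of splines (>= 1).
#' @param electrodes_per_spline electrodes on each spline (>= 1).
#' @param electrode_radii radial distance of each within-spline position, mm,
#'   strictly increasing outward. Defaults to 3 mm spacing starting at 2 mm.
#' @return An object of class `catheter_layout` with fields `n_splines`,
#'   `electrodes_per_spline`, `spline_angles` (degrees), `electrode_radii` (mm).
#' @examples
#' lay <- build_layout()
#' n_electrodes(lay)    # 20
#' @export
build_layout <- function(n_splines = 5L, electrodes_per_spline = 4L,
                         electrode_radii = 2 + 3 * seq_len(electrodes_per_spline) - 3) {
  n_splines <- as.integer(n_splines)
  electrodes_per_spline <- as.integer(electrodes_per_spline)
  if (is.na(n_splines) || n_splines < 1L)
    stop("`n_splines` must be a positive integer", call. = FALSE)
  if (is.na(electrodes_per_spline) || electrodes_per_spline < 1L)
    stop("`electrodes_per_spline` must be a positive integer", call. = FALSE)
  if (length(electrode_radii) != electrodes_per_spline || any(diff(electrode_radii) <= 0))
    stop("`electrode_radii` must be strictly increasing, one value per position",
         call. = FALSE)
  structure(
    list(
      n_splines = n_splines,
      electrodes_per_spline = electrodes_per_spline,
      spline_angles = 360 * (seq_len(n_splines) - 1L) / n_splines,
      electrode_radii = as.numeric(electrode_radii)
    ),
    class = "catheter_layout"
  )
}

#' Number of electrodes in a layout
#' @param layout a `catheter_layout`.
#' @return integer count.
#' @export
n_electrodes <- function(layout) {
  stopifnot(inherits(layout, "catheter_layout"))
  layout$n_splines * layout$electrodes_per_spline
}

#' @export
print.catheter_layout <- function(x, ...) {
  cat(sprintf("<catheter_layout> %d splines x %d electrodes (%d total)\n",
              x$n_splines, x$electrodes_per_spline, n_electrodes(x)))
  cat(sprintf("  spline angles: %s deg\n", paste(round(x$spline_angles, 1), collapse = ", ")))
  cat(sprintf("  radii: %s mm\n", paste(x$electrode_radii, collapse = ", ")))
  invisible(x)
}

new_channel_ordering <- function(kind, index_map, layout) {
  stopifnot(is.matrix(index_map), ncol(index_map) == 2L)
  if (anyDuplicated(index_map[, 1L] * 1e6 + index_map[, 2L]))
    stop("index_map contains repeated channels", call. = FALSE)
  structure(
    list(kind = kind, index_map = index_map,
         n_splines = layout$n_splines,
         electrodes_per_spline = layout$electrodes_per_spline),
    class = "channel_ordering"
  )
}

#' @export
print.channel_ordering <- function(x, ...) {
  cat(sprintf("<channel_ordering> kind=%s, %d channels\n", x$kind, nrow(x$index_map)))
  invisible(x)
}

#' Canonical unipolar channel ordering (by spline, inner to outer)
#' @param layout a `catheter_layout`.
#' @return a `channel_ordering` with one row per electrode.
#' @export
unipolar_order <- function(layout) {
  stopifnot(inherits(layout, "catheter_layout"))
  s <- rep(seq_len(layout$n_splines) - 1L, each = layout$electrodes_per_spline)
  p <- rep(seq_len(layout$electrodes_per_spline) - 1L, times = layout$n_splines)
  new_channel_ordering("unipolar-by-spline", cbind(spline = s, position = p), layout)
}

#' Electrodes of one concentric ring
#'
#' A ring collects the electrodes sitting at the same within-spline position
#' on every spline, ordered counterclockwise by increasing spline angle.
#' Rotational activity manifests on a ring as a staircase of activation times
#' spanning the cycle.
#'
#' @param layout a `catheter_layout`.
#' @param ring_index 0-based within-spline position, `0` = innermost.
#' @return a `channel_ordering` of kind `"ring-order"` with `n_splines` rows.
#' @export
ring_order <- function(layout, ring_index) {
  stopifnot(inherits(layout, "catheter_layout"))
  ring_index <- as.integer(ring_index)
  if (is.na(ring_index) || ring_index < 0L || ring_index >= layout$electrodes_per_spline)
    stop("`ring_index` out of range [0, electrodes_per_spline)", call. = FALSE)
  s <- seq_len(layout$n_splines) - 1L
  new_channel_ordering("ring-order",
                       cbind(spline = s, position = rep(ring_index, layout$n_splines)),
                       layout)
}

#' Adjacent within-spline bipolar pairs
#'
#' Bipolar channels are formed by differencing electrically adjacent
#' electrodes on the same spline (positions 1-2, 2-3, ... in 1-based clinical
#' numbering), yielding `n_splines * (electrodes_per_spline - 1)` bipoles:
#' 15 for the default 20-electrode catheter.
#'
#' @param layout a `catheter_layout` with at least 2 electrodes per spline.
#' @return integer matrix with columns `a`, `b`: 0-based flat electrode
#'   indices (canonical unipolar-by-spline order) of each pair.
#' @export
bipolar_pairs <- function(layout) {
  stopifnot(inherits(layout, "catheter_layout"))
  eps <- layout$electrodes_per_spline
  if (eps < 2L)
    stop("bipolar derivation needs >= 2 electrodes per spline", call. = FALSE)
  s <- rep(seq_len(layout$n_splines) - 1L, each = eps - 1L)
  p <- rep(seq_len(eps - 1L) - 1L, times = layout$n_splines)
  cbind(a = s * eps + p, b = s * eps + p + 1L)
}

#' Cyclic spline relabeling of a channel ordering
#'
#' Rotates the spline enumeration of an ordering so that it begins at
#' `start_spline` (1-based): spline `start_spline` takes the role of spline 1,
#' `start_spline + 1` of spline 2, and so on cyclically. Applying the rotation
#' `n_splines` times (or `start_spline = 1`) is the identity. Used as the
#' 5-fold ring-permutation augmentation of window datasets.
#'
#' @param ordering a `channel_ordering`.
#' @param start_spline 1-based spline at which the rotated enumeration starts.
#' @return a `channel_ordering` of the same kind.
#' @export
spline_rotation <- function(ordering, start_spline) {
  stopifnot(inherits(ordering, "channel_ordering"))
  ns <- ordering$n_splines
  start_spline <- as.integer(start_spline)
  if (is.na(start_spline) || start_spline < 1L || start_spline > ns)
    stop("`start_spline` must be in 1..n_splines", call. = FALSE)
  im <- ordering$index_map
  im[, 1L] <- (im[, 1L] + (start_spline - 1L)) %% ns
  out <- ordering
  out$index_map <- im
  out
}

#' Row permutation realizing a spline rotation on channel-major data
#'
#' For a signal matrix whose rows follow `ordering`, returns the integer row
#' permutation `perm` such that `x[perm, ]` is the same acquisition re-indexed
#' with spline enumeration starting at `start_spline`. Works for unipolar,
#' ring, and bipolar orderings (any ordering whose rows are `(spline, position)`
#' labeled).
#'
#' @inheritParams spline_rotation
#' @return integer vector of row indices.
#' @export
spline_rotation_perm <- function(ordering, start_spline) {
  rot <- spline_rotation(ordering, start_spline)
  key <- function(im) im[, 1L] * 1e6 + im[, 2L]
  match(key(rot$index_map), key(ordering$index_map))
}

#' Cartesian electrode coordinates
#' @param layout a `catheter_layout`.
#' @return numeric matrix (n_electrodes x 2) of x, y positions in mm, rows in
#'   canonical unipolar-by-spline order.
#' @export
electrode_positions <- function(layout) {
  stopifnot(inherits(layout, "catheter_layout"))
  ord <- unipolar_order(layout)$index_map
  th <- layout$spline_angles[ord[, 1L] + 1L] * pi / 180
  r <- layout$electrode_radii[ord[, 2L] + 1L]
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Serialize / restore a layout as a plain-text config block
#' @param layout a `catheter_layout`.
#' @return `layout_to_config`: a named list suitable for YAML embedding;
#'   `layout_from_config`: a `catheter_layout`.
#' @export
layout_to_config <- function(layout) {
  list(n_splines = layout$n_splines,
       electrodes_per_spline = layout$electrodes_per_spline,
       electrode_radii = layout$electrode_radii)
}

#' @rdname layout_to_config
#' @param cfg a list as produced by [layout_to_config()].
#' @export
layout_from_config <- function(cfg) {
  build_layout(cfg$n_splines, cfg$electrodes_per_spline,
               electrode_radii = cfg$electrode_radii)
}
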