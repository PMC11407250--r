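# Optode grids, measurement channels and source-detector distance groups.

#' Place a source-detector grid on the phantom surface
#'
#' A `rows x cols` rectangular grid spanning `extent` (mm) is centred on the
#' scanned surface and each grid point is assigned source or detector role in
#' a checkerboard pattern, which for a 6 x 6 grid yields the canonical 18
#' sources and 18 detectors. Grid coordinates live in the parametric frame
#' (true arclength on the surface); physical positions follow the bend.
#'
#' @param mesh a [tet_mesh()] from [build_phantom()] or [tet_box_mesh()].
#' @param grid_shape integer length-2, rows x cols (rows along y, cols along x).
#' @param extent numeric length-2, grid span in mm (x-span, y-span).
#' @param pattern only `"alternating"` (checkerboard) is supported.
#' @return Object of class `probe_layout`: data frame `optodes` with columns
#'   `id`, `role`, `u`, `v`, `x`, `y`, `z`, plus `grid_shape`, `extent`.
#' @export
build_probe_layout <- function(mesh, grid_shape = c(6L, 6L),
                               extent = c(100, 70), pattern = "alternating") {
  pattern <- match.arg(pattern, "alternating")
  pr <- mesh$param
  umax <- max(pr[, 1]); vmax <- max(pr[, 2])
  if (extent[1] > umax || extent[2] > vmax)
    stop("grid extent exceeds the meshed surface")
  cols <- grid_shape[2]; rows <- grid_shape[1]
  us <- seq((umax - extent[1]) / 2, (umax + extent[1]) / 2, length.out = cols)
  vs <- seq((vmax - extent[2]) / 2, (vmax + extent[2]) / 2, length.out = rows)
  gg <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  u <- us[gg$col]; v <- vs[gg$row]
  role <- ifelse((gg$col + gg$row) %% 2L == 0L, "source", "detector")
  p <- cbind(u, v, 0)
  xyz <- if (is.null(mesh$bend_radius)) p else
    bend_coordinates(p, mesh$bend_radius, vc = vmax / 2)
  opt <- data.frame(id = seq_len(nrow(gg)), role = role,
                    u = u, v = v, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  structure(list(optodes = opt, grid_shape = grid_shape, extent = extent),
            class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("probe_layout: %d x %d grid over %.0f x %.0f mm; %d sources, %d detectors\n",
              x$grid_shape[1], x$grid_shape[2], x$extent[1], x$extent[2],
              sum(x$optodes$role == "source"), sum(x$optodes$role == "detector")))
  invisible(x)
}

#' Select measurement channels by source-detector distance
#'
#' Forms all source x detector pairs and keeps those whose Euclidean (chord)
#' distance between the physical optode positions lies in `[dmin, dmax]`.
#' On the curved anatomies of interest roughly 313 of 324 pairs survive the
#' 20-120 mm window; the exact count is geometry dependent.
#'
#' @param layout a [build_probe_layout()] result.
#' @param dmin,dmax distance window in mm.
#' @return data frame of class `channel_set`: `channel`, `source_id`,
#'   `detector_id`, `distance`.
#' @export
select_channels <- function(layout, dmin = 20, dmax = 120) {
  if (dmin >= dmax) stop("dmin must be smaller than dmax")
  opt <- layout$optodes
  src <- opt[opt$role == "source", ]
  det <- opt[opt$role == "detector", ]
  if (!nrow(src) || !nrow(det)) stop("layout needs at least one source and one detector")
  pairs <- expand.grid(si = seq_len(nrow(src)), di = seq_len(nrow(det)))
  dx <- src$x[pairs$si] - det$x[pairs$di]
  dy <- src$y[pairs$si] - det$y[pairs$di]
  dz <- src$z[pairs$si] - det$z[pairs$di]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- dist >= dmin & dist <= dmax
  out <- data.frame(channel = seq_len(sum(keep)),
                    source_id = src$id[pairs$si][keep],
                    detector_id = det$id[pairs$di][keep],
                    distance = dist[keep])
  class(out) <- c("channel_set", class(out))
  out
}

#' Group channels into source-detector distance bins
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed at its upper
#' edge, so the default edges tile 20-120 mm in 20 mm increments without
#' double counting.
#'
#' @param channels a [select_channels()] result.
#' @param edges increasing numeric vector of bin edges in mm.
#' @return The channel data frame with added `group` (label "lo-hi") and
#'   `group_id`; attribute `groups` holds a per-group summary (label, lower,
#'   upper, `NM` = member count).
#' @export
group_channels <- function(channels, edges = seq(20, 120, by = 20)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  d <- channels$distance
  if (any(d < edges[1] | d > edges[length(edges)]))
    stop("channel distance outside the binning range")
  gid <- findInterval(d, edges, rightmost.closed = TRUE)
  lab <- paste0(edges[-length(edges)], "-", edges[-1])
  channels$group_id <- gid
  channels$group <- lab[gid]
  counts <- tabulate(gid, nbins = length(lab))
  attr(channels, "groups") <- data.frame(
    group_id = seq_along(lab), label = lab,
    lower = edges[-length(edges)], upper = edges[-1], NM = counts)
  channels
}

#' Export-ready channel table
#'
#' @param channels grouped channels from [group_channels()].
#' @param layout the layout the channels came from.
#' @return data frame with `source_id`, `detector_id`, `distance_mm`, `group`.
#' @export
channel_table <- function(channels, layout) {
  data.frame(source_id = channels$source_id,
             detector_id = channels$detector_id,
             distance_mm = channels$distance,
             group = if (!is.null(channels$group)) channels$group else NA_character_)
}
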