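# Nuclear segmentation from the DAPI channel:
# normalize -> background subtraction (min filter) -> percentile saturation ->
# fixed 0.4 threshold -> debris area filter -> watershed splitting of
# over-large objects. All thresholds are pixel/intensity-denominated and live
# in seg_config() so they can be audited in one place.

#' Segmentation configuration
#'
#' @param min_filter_size side (px) of the square minimum-filter window used
#'   for background estimation.
#' @param sat_low_pct,sat_high_pct saturation percentiles.
#' @param nuc_threshold normalized-intensity threshold; pixels strictly above
#'   it are foreground.
#' @param min_area components below this area (px) are removed as debris.
#' @param split_area components strictly above this area (px) are routed to
#'   watershed splitting.
#' @param max_single_area optional upper area bound: components above it that
#'   the watershed could not subdivide are dropped. `NULL` (default) disables
#'   the bound.
#' @param connectivity 4 or 8 (default) for connected components.
#' @param marker_merge_dist watershed seeds (distance-transform maxima) closer
#'   than this many px are merged before flooding.
#' @param watershed_tolerance dynamics threshold of the watershed (surface
#'   units; see [split_large_nuclei()]).
#' @return a validated `seg_config` list.
#' @export
seg_config <- function(min_filter_size = 50, sat_low_pct = 5, sat_high_pct = 95,
                       nuc_threshold = 0.4, min_area = 10, split_area = 200,
                       max_single_area = NULL, connectivity = 8,
                       marker_merge_dist = 3, watershed_tolerance = 1) {
  cfg <- list(min_filter_size = min_filter_size, sat_low_pct = sat_low_pct,
              sat_high_pct = sat_high_pct, nuc_threshold = nuc_threshold,
              min_area = min_area, split_area = split_area,
              max_single_area = max_single_area, connectivity = connectivity,
              marker_merge_dist = marker_merge_dist,
              watershed_tolerance = watershed_tolerance)
  if (!(sat_low_pct >= 0 && sat_low_pct < sat_high_pct && sat_high_pct <= 100))
    stop("need 0 <= sat_low_pct < sat_high_pct <= 100", call. = FALSE)
  if (!(nuc_threshold > 0 && nuc_threshold < 1))
    stop("nuc_threshold must lie in (0,1)", call. = FALSE)
  if (!(min_area > 0 && min_area < split_area))
    stop("need 0 < min_area < split_area", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (min_filter_size < 1) stop("min_filter_size must be >= 1", call. = FALSE)
  structure(cfg, class = "seg_config")
}

#' Normalize an 8-bit raster to [0,1]
#'
#' @param raster matrix with values in 0..255.
#' @return `raster / 255`.
#' @export
normalize_channel <- function(raster) {
  if (any(raster < 0 | raster > 255, na.rm = TRUE))
    stop("raster values must lie in [0, 255]", call. = FALSE)
  raster / 255
}

#' Estimate and subtract the local background
#'
#' The background is the running minimum over a square window of side `size`;
#' the raster minus this estimate (clipped below at 0) is returned. Flat
#' regions map to ~0 while compact bright objects smaller than the window
#' survive, which is what makes the downstream fixed threshold meaningful.
#'
#' @param raster normalized float matrix.
#' @param size window side in pixels; must be >= 1 and below the smallest
#'   image dimension.
#' @return background-subtracted matrix.
#' @export
subtract_background <- function(raster, size = 50) {
  if (size < 1 || size >= min(dim(raster)))
    stop("size must satisfy 1 <= size < min(image dims)", call. = FALSE)
  pmax(raster - min_filter(raster, size), 0)
}

#' Saturate a raster to two percentiles and rescale
#'
#' Values are clipped to `[P_low, P_high]` (percentiles over all pixels,
#' linear-interpolation convention) and linearly rescaled so that
#' `P_low -> 0` and `P_high -> 1`. Degenerate rule: if the two percentiles
#' coincide the output is all zeros.
#'
#' @param raster float matrix.
#' @param low_pct,high_pct percentiles in [0,100].
#' @return matrix in [0,1].
#' @export
saturate_percentiles <- function(raster, low_pct = 5, high_pct = 95) {
  q <- stats::quantile(raster, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) return(matrix(0, nrow(raster), ncol(raster)))
  (pmin(pmax(raster, q[1]), q[2]) - q[1]) / (q[2] - q[1])
}

#' Threshold a raster into a binary mask
#'
#' Strict inequality: pixels exactly at `t` are background.
#'
#' @param raster float matrix.
#' @param t threshold.
#' @return logical matrix.
#' @export
threshold_mask <- function(raster, t = 0.4) raster > t

#' Remove small components from a binary mask
#'
#' Components with area strictly below `min_area` are removed (debris filter);
#' everything else is retained. Optionally drops components above
#' `max_area` as well.
#'
#' @param mask logical matrix.
#' @param min_area minimum retained area in px.
#' @param max_area optional maximum retained area (default `NULL`: no bound).
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
filter_by_area <- function(mask, min_area = 10, max_area = NULL, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- label_areas(lab)
  keep <- areas >= min_area
  if (!is.null(max_area)) keep <- keep & areas <= max_area
  matrix(lab %in% which(keep), nrow(mask), ncol(mask))
}

# Marker-controlled watershed of one component by union-find flooding.
# Pixels are visited in decreasing order of the flooding surface; a pixel
# with no labeled neighbour founds a new region at a local maximum, a pixel
# adjacent to one region joins it, and where regions meet, any region whose
# dynamics (its peak height minus the meeting level) are at most `tolerance`
# is merged into the highest neighbouring region. The dynamics rule removes
# the spurious maxima that discrete distance transforms carry along necks and
# ridges; afterwards regions whose peaks lie within `merge_dist` px are also
# merged (single linkage). Deterministic: ties are broken by pixel index.
watershed_component <- function(comp_mask, surface, tolerance = 1, merge_dist = 3) {
  H <- nrow(comp_mask); W <- ncol(comp_mask)
  px <- which(comp_mask > 0)
  px <- px[order(-surface[px], px)]
  lab <- integer(H * W)
  parent <- integer(0); peak <- numeric(0); peak_pos <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nb <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  up_moves <- c(1L, 5L, 7L); down_moves <- c(2L, 6L, 8L)
  for (p in px) {
    r <- ((p - 1L) %% H) + 1L
    ok <- rep(TRUE, 8L)
    if (r == 1L) ok[up_moves] <- FALSE
    if (r == H) ok[down_moves] <- FALSE
    nbr <- p + nb[ok]
    nbr <- nbr[nbr >= 1L & nbr <= H * W]
    roots <- unique(vapply(nbr[lab[nbr] > 0L], function(q) find(lab[q]), integer(1)))
    if (!length(roots)) {
      k <- length(parent) + 1L
      parent[k] <- k; peak[k] <- surface[p]; peak_pos[k] <- p
      lab[p] <- k
    } else {
      best <- roots[order(-peak[roots], roots)][1]
      lab[p] <- best
      for (r2 in setdiff(roots, best)) {
        if (peak[r2] - surface[p] <= tolerance) parent[r2] <- best
      }
    }
  }
  if (!length(parent)) return(matrix(0L, H, W))
  roots <- vapply(seq_along(parent), find, integer(1))
  final <- sort(unique(roots))
  # spec'd spatial rule: peaks closer than merge_dist merge as well
  if (length(final) > 1L) {
    pos <- cbind(((peak_pos[final] - 1L) %% H) + 1L, ((peak_pos[final] - 1L) %/% H) + 1L)
    hc <- stats::hclust(stats::dist(pos), method = "single")
    grp <- stats::cutree(hc, h = merge_dist)
  } else grp <- 1L
  map <- integer(length(parent))
  map[final] <- grp
  out <- matrix(0L, H, W)
  sel <- lab > 0L
  out[sel] <- map[roots[lab[sel]]]
  relabel_consecutive(out)
}

#' Split over-large nuclear objects with a marker-controlled watershed
#'
#' Components with area at most `split_area` are labeled as-is. Larger
#' components are subdivided: seeds are the local maxima of the component's
#' Euclidean distance transform (plateaus joined, maxima closer than
#' `marker_merge_dist` px merged), and the flooding surface is the distance
#' transform weighted multiplicatively by the DAPI signal. Splitting never
#' adds or removes foreground pixels, and a component with a single seed is
#' kept whole.
#'
#' @param mask area-filtered logical matrix.
#' @param dapi_raster the saturated DAPI raster (same shape).
#' @param split_area routing threshold in px (strictly-above goes to splitting).
#' @param connectivity 4 or 8.
#' @param marker_merge_dist seed merge radius in px.
#' @param tolerance watershed dynamics threshold (surface units): a candidate
#'   seed whose peak rises less than this above the level where it meets a
#'   higher region is merged into it (suppresses discretization maxima).
#' @return integer label matrix with consecutive labels 1..n.
#' @export
split_large_nuclei <- function(mask, dapi_raster, split_area = 200,
                               connectivity = 8, marker_merge_dist = 3,
                               tolerance = 1) {
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(lab)
  areas <- label_areas(lab)
  big <- which(areas > split_area)
  if (!length(big)) return(lab)
  out <- lab
  next_label <- 0L
  result <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_len(n)) {
    sel <- lab == k
    if (!(k %in% big)) {
      next_label <- next_label + 1L
      result[sel] <- next_label
      next
    }
    # crop to the component's bounding box (1-px pad) and flood locally
    rr <- range(row(sel)[sel]); cc <- range(col(sel)[sel])
    r0 <- max(1L, rr[1] - 1L); r1 <- min(nrow(sel), rr[2] + 1L)
    c0 <- max(1L, cc[1] - 1L); c1 <- min(ncol(sel), cc[2] + 1L)
    sub <- sel[r0:r1, c0:c1, drop = FALSE]
    d <- EBImage::imageData(EBImage::distmap(sub))
    surface <- d * dapi_raster[r0:r1, c0:c1, drop = FALSE]
    flooded <- watershed_component(sub, surface, tolerance, marker_merge_dist)
    for (j in seq_len(max(flooded))) {
      next_label <- next_label + 1L
      piece <- flooded == j & sub
      idx <- which(piece, arr.ind = TRUE)
      result[cbind(idx[, 1] + r0 - 1L, idx[, 2] + c0 - 1L)] <- next_label
    }
  }
  relabel_consecutive(result)
}

#' Segment nuclei from the DAPI channel of a scene
#'
#' Full pipeline: normalize, subtract background, saturate to percentiles,
#' threshold (strict), remove debris by area, split over-large objects with
#' the marker-controlled watershed. Deterministic for fixed input and config.
#'
#' @param scene an `image_scene` with a channel named "DAPI".
#' @param config a [seg_config()].
#' @return integer nucleus label matrix (0 = background, labels 1..n).
#' @export
segment_nuclei <- function(scene, config = seg_config()) {
  stopifnot(inherits(scene, "image_scene"))
  if (!"DAPI" %in% names(scene$channels))
    stop("scene has no DAPI channel", call. = FALSE)
  x <- normalize_channel(scene$channels[["DAPI"]])
  x <- subtract_background(x, config$min_filter_size)
  x <- saturate_percentiles(x, config$sat_low_pct, config$sat_high_pct)
  mask <- threshold_mask(x, config$nuc_threshold)
  mask <- filter_by_area(mask, config$min_area, config$max_single_area,
                         config$connectivity)
  split_large_nuclei(mask, x, config$split_area, config$connectivity,
                     config$marker_merge_dist, config$watershed_tolerance)
}

#' Write a nucleus label map to disk
#'
#' Writes the label map as a 16-bit grayscale TIFF plus a per-nucleus CSV
#' (label, centroid_row, centroid_col, area_px).
#'
#' @param label_map integer label matrix (labels must fit in 16 bits).
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  stopifnot(max(label_map) <= 65535)
  tiff::writeTIFF(label_map / 65535, file.path(path, "labels.tif"), bits.per.sample = 16L)
  n <- max(label_map)
  pos <- label_map > 0L
  df <- data.frame(
    label = seq_len(n),
    centroid_row = as.numeric(tapply(row(label_map)[pos], label_map[pos], mean)),
    centroid_col = as.numeric(tapply(col(label_map)[pos], label_map[pos], mean)),
    area_px = as.integer(label_areas(label_map)))
  utils::write.csv(df, file.path(path, "nuclei_labels.csv"), row.names = FALSE)
  invisible(path)
}
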