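# Per-cell immunofluorescence quantification: cytoplasm territories indexed
# to nuclei, per-cell mean fluorescence (nuclear / cytoplasmic / combined),
# the >5-px overlap positivity rule, the stellate-cell elongation filter for
# fibrous markers, and per-slide aggregation.

#' Assign cytoplasmic territories to nuclei
#'
#' Every background pixel within `expansion_radius` (Euclidean distance to the
#' nearest nuclear pixel) is attached to its nearest nucleus; pixels beyond
#' the radius stay unassigned. Territories are grown with a seeded propagation
#' (EBImage::propagate on a flat landscape), which realizes the nearest-
#' nucleus partition up to +-1 px along equidistant boundaries.
#'
#' @param label_map integer nucleus label matrix with >= 1 label.
#' @param expansion_radius territory radius in px (> 0).
#' @return a `cell_regions` list: `nuclear` and `cytoplasm` label matrices
#'   (disjoint), plus `expansion_radius`.
#' @export
assign_cytoplasm <- function(label_map, expansion_radius = 10) {
  if (expansion_radius <= 0) stop("expansion_radius must be > 0", call. = FALSE)
  if (max(label_map) < 1L) stop("label map contains no nuclei", call. = FALSE)
  nuc <- label_map > 0L
  dist_to_nuc <- EBImage::imageData(EBImage::distmap(1 - nuc))
  mask <- dist_to_nuc <= expansion_radius
  grown <- EBImage::imageData(EBImage::propagate(
    matrix(0, nrow(label_map), ncol(label_map)), seeds = label_map, mask = mask))
  mode(grown) <- "integer"
  cyto <- grown
  cyto[nuc] <- 0L
  structure(list(nuclear = label_map, cytoplasm = cyto,
                 expansion_radius = expansion_radius),
            class = "cell_regions")
}

#' Prepare a marker channel for positivity calling
#'
#' Same filtering as the DAPI channel but without percentile saturation:
#' normalize to [0,1], subtract the minimum-filter background, threshold
#' strictly above `t`.
#'
#' @param raster 8-bit marker channel matrix.
#' @param min_filter_size background window side (px).
#' @param t threshold (default 0.4).
#' @return logical marker mask.
#' @export
prepare_marker_mask <- function(raster, min_filter_size = 50, t = 0.4) {
  x <- normalize_channel(raster)
  x <- subtract_background(x, min_filter_size)
  threshold_mask(x, t)
}

#' Elongation filter for fibrous (stellate-cell) markers
#'
#' Retains connected components that are larger than `min_area` px AND have a
#' perimeter-to-area ratio above `min_ratio` (both strict), so that only
#' fibre-like signal counts towards positivity. The perimeter estimator is
#' pinned (default: 4-connected boundary-step count; see [label_perimeters()]).
#'
#' @param mask prepared marker mask.
#' @param min_area area clause in px (strictly larger passes).
#' @param min_ratio perimeter/area clause (strictly higher passes).
#' @param perimeter "steps" (default) or "crofton".
#' @param connectivity 4 or 8.
#' @return filtered logical mask.
#' @export
filter_elongated <- function(mask, min_area = 20, min_ratio = 0.5,
                             perimeter = c("steps", "crofton"), connectivity = 8) {
  perimeter <- match.arg(perimeter)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- label_areas(lab)
  per <- label_perimeters(lab, perimeter)
  keep <- areas > min_area & per / areas > min_ratio
  matrix(lab %in% which(keep), nrow(mask), ncol(mask))
}

#' Overlap-based positivity call for one cell region
#'
#' @param region_mask logical mask of the cell's region.
#' @param marker_mask prepared (and possibly elongation-filtered) marker mask.
#' @param min_overlap a cell is positive iff the overlap is strictly larger
#'   than this many px (default 5).
#' @return list(positive=, overlap_px=).
#' @export
call_positive <- function(region_mask, marker_mask, min_overlap = 5) {
  ov <- sum(region_mask & marker_mask)
  list(positive = ov > min_overlap, overlap_px = as.integer(ov))
}

# per-label pixel means of a raster (NA for empty labels)
label_means <- function(raster, lab, n) {
  pos <- lab > 0L
  if (!any(pos)) return(rep(NA_real_, n))
  s <- rowsum(raster[pos], lab[pos])
  cnt <- tabulate(lab[pos], nbins = n)
  out <- rep(NA_real_, n)
  out[as.integer(rownames(s))] <- s[, 1] / cnt[as.integer(rownames(s))]
  out
}

#' Measure per-cell marker fluorescence
#'
#' Nuclear and cytoplasmic MFI are means of the raw normalized channel over
#' the respective region; the combined MFI is the mean of the two region
#' means ("region-means" rule; a pooled-pixel mean is available via
#' `combine = "pooled"`). Cells with empty cytoplasm get `NA` cytoplasmic MFI
#' and their combined MFI falls back to the nuclear mean.
#'
#' @param scene an `image_scene`.
#' @param regions a `cell_regions` object.
#' @param marker_name channel to measure.
#' @param combine "region_means" (default) or "pooled".
#' @return data.frame: label, mfi_nuclear, mfi_cytoplasmic, mfi_combined.
#' @export
measure_cells <- function(scene, regions, marker_name,
                          combine = c("region_means", "pooled")) {
  combine <- match.arg(combine)
  stopifnot(inherits(scene, "image_scene"), inherits(regions, "cell_regions"))
  if (!marker_name %in% names(scene$channels))
    stop(sprintf("unknown marker channel '%s'", marker_name), call. = FALSE)
  x <- normalize_channel(scene$channels[[marker_name]])
  n <- max(regions$nuclear)
  mfi_n <- label_means(x, regions$nuclear, n)
  mfi_c <- label_means(x, regions$cytoplasm, n)
  if (combine == "region_means") {
    comb <- rowMeans(cbind(mfi_n, mfi_c), na.rm = TRUE)
  } else {
    pos_n <- regions$nuclear > 0L; pos_c <- regions$cytoplasm > 0L
    s <- rowsum(c(x[pos_n], x[pos_c]), c(regions$nuclear[pos_n], regions$cytoplasm[pos_c]))
    cnt <- tabulate(regions$nuclear[pos_n], nbins = n) +
      tabulate(regions$cytoplasm[pos_c], nbins = n)
    comb <- rep(NA_real_, n)
    comb[as.integer(rownames(s))] <- s[, 1] / cnt[as.integer(rownames(s))]
  }
  data.frame(label = seq_len(n), mfi_nuclear = mfi_n,
             mfi_cytoplasmic = mfi_c, mfi_combined = comb)
}

#' Quantify all marker channels of a scene
#'
#' For each marker: prepare the mask (minimum-filter background subtraction,
#' 0.4 threshold, no saturation), optionally apply the elongation filter
#' (fibrous markers such as ACTA-2), measure per-cell MFI, and call positivity
#' from the overlap of the cell region with the marker mask.
#'
#' @param scene an `image_scene`.
#' @param regions a `cell_regions` object.
#' @param records classified nucleus records (provides the `class` column).
#' @param markers character vector of marker channel names (default: all
#'   non-DAPI channels).
#' @param elongation_markers markers that receive the elongation filter.
#' @param min_overlap positivity overlap threshold (strict, px).
#' @param min_filter_size background window for the marker masks.
#' @param positivity_region "cell" (nuclear + cytoplasm, default) or "nuclear".
#' @param elongation list of elongation-filter settings
#'   (min_area, min_ratio, perimeter).
#' @param combine MFI combination rule, see [measure_cells()].
#' @return data.frame of cell measurements, one row per cell x marker:
#'   label, class, marker, MFIs, overlap_px, positive.
#' @export
quantify_markers <- function(scene, regions, records,
                             markers = NULL,
                             elongation_markers = character(0),
                             min_overlap = 5, min_filter_size = 50,
                             positivity_region = c("cell", "nuclear"),
                             elongation = list(min_area = 20, min_ratio = 0.5,
                                               perimeter = "steps"),
                             combine = "region_means") {
  positivity_region <- match.arg(positivity_region)
  if (is.null(markers)) markers <- setdiff(names(scene$channels), "DAPI")
  n <- max(regions$nuclear)
  cls <- rep("unclassified", n)
  cls[records$label] <- records$class
  out <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    mask <- prepare_marker_mask(scene$channels[[mk]], min_filter_size)
    if (mk %in% elongation_markers) {
      mask <- filter_elongated(mask, elongation$min_area, elongation$min_ratio,
                               elongation$perimeter)
    }
    mfi <- measure_cells(scene, regions, mk, combine)
    lab_for_overlap <- regions$nuclear
    if (positivity_region == "cell") {
      lab_for_overlap <- regions$nuclear + regions$cytoplasm * (regions$nuclear == 0L)
    }
    ov <- tabulate(lab_for_overlap[mask & lab_for_overlap > 0L], nbins = n)
    out[[i]] <- data.frame(label = seq_len(n), class = cls, marker = mk,
                           mfi_nuclear = mfi$mfi_nuclear,
                           mfi_cytoplasmic = mfi$mfi_cytoplasmic,
                           mfi_combined = mfi$mfi_combined,
                           overlap_px = as.integer(ov),
                           positive = ov > min_overlap)
  }
  do.call(rbind, out)
}

#' Aggregate cell measurements into a per-slide summary
#'
#' Human-cell metrics (the paper's headline numbers) are computed over human
#' nuclei only — both chicken classes are excluded. For each marker: mean
#' combined MFI over all human cells, mean over positive cells, positive
#' count and class count. Double-positive percentages are computed per pair
#' with the first marker's positive cells as denominator; empty denominators
#' yield `NA`, not 0.
#'
#' @param measurements output of [quantify_markers()].
#' @param double_positive_pairs list of 2-element character vectors, e.g.
#'   `list(c("ACTA2","MMP2"))`.
#' @param metric_class class whose cells enter the metrics (default "human").
#' @return a `slide_summary` list: `markers` data.frame and
#'   `double_positive` data.frame.
#' @export
summarize_slide <- function(measurements, double_positive_pairs = list(),
                            metric_class = "human") {
  hm <- measurements[measurements$class %in% metric_class, , drop = FALSE]
  mk_names <- unique(measurements$marker)
  rows <- lapply(mk_names, function(mk) {
    m <- hm[hm$marker == mk, , drop = FALSE]
    data.frame(marker = mk,
               class = paste(metric_class, collapse = "+"),
               n_cells = nrow(m),
               n_positive = sum(m$positive),
               mean_mfi = if (nrow(m)) mean(m$mfi_combined) else NA_real_,
               mean_mfi_positive = if (any(m$positive))
                 mean(m$mfi_combined[m$positive]) else NA_real_)
  })
  dp <- lapply(double_positive_pairs, function(pr) {
    a <- hm[hm$marker == pr[1], c("label", "positive")]
    b <- hm[hm$marker == pr[2], c("label", "positive")]
    ab <- merge(a, b, by = "label", suffixes = c("_a", "_b"))
    denom <- sum(ab$positive_a)
    data.frame(marker_a = pr[1], marker_b = pr[2],
               n_first_positive = denom,
               n_double_positive = sum(ab$positive_a & ab$positive_b),
               pct_double_positive = if (denom > 0)
                 100 * sum(ab$positive_a & ab$positive_b) / denom else NA_real_)
  })
  structure(list(
    markers = do.call(rbind, rows),
    double_positive = if (length(dp)) do.call(rbind, dp) else
      data.frame(marker_a = character(0), marker_b = character(0),
                 n_first_positive = integer(0), n_double_positive = integer(0),
                 pct_double_positive = numeric(0))),
    class = "slide_summary")
}

#' @export
print.slide_summary <- function(x, ...) {
  cat("slide_summary\n")
  print(x$markers, row.names = FALSE)
  if (nrow(x$double_positive)) print(x$double_positive, row.names = FALSE)
  invisible(x)
}
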