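# DAB/haematoxylin (Ki-67) scoring from optical density: OD-sum detection
# image, per-cell mean OD, positivity at a fixed threshold, and 1+/2+/3+
# intensity bins at 0.2/0.4/0.6. This is a deliberately small scoring rule
# over this package's own cell regions; it does not re-create a full
# positive-cell-detection pipeline (background radius, sigma, cell expansion).

#' Optical-density-sum image from an RGB raster
#'
#' `OD = sum over channels of -log10(max(I,1)/255)`; pure white maps to 0 and
#' zero intensities are floored at 1 before the log so the OD stays finite.
#'
#' @param rgb numeric array `height x width x 3` with values in 0..255.
#' @return OD matrix (>= 0).
#' @export
od_sum <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (any(rgb < 0 | rgb > 255)) stop("RGB values must lie in [0,255]", call. = FALSE)
  od <- -log10(pmax(rgb, 1) / 255)
  matrix(od[, , 1] + od[, , 2] + od[, , 3], dim(rgb)[1], dim(rgb)[2])
}

#' Score cells from an optical-density image
#'
#' Per-cell mean OD over the cell's region; a cell is positive iff its mean OD
#' is at least `positive_threshold`. Positive cells are binned by left-closed
#' intervals on the cut points: `[bins[1], bins[2]) -> 1+`,
#' `[bins[2], bins[3]) -> 2+`, `[bins[3], Inf) -> 3+`. Positive cells below
#' the first cut are reported as 1+ (lowest bin) with a note.
#'
#' @param od OD matrix from [od_sum()].
#' @param regions integer label matrix of cell regions (e.g. a nucleus label
#'   map, or nuclear + cytoplasm labels).
#' @param positive_threshold mean-OD positivity threshold (default 0.1).
#' @param bins increasing cut points for the 1+/2+/3+ bins.
#' @return a `ki67_score` list: `cells` data.frame (label, mean_od, positive,
#'   bin) and `counts` (named vector: negative, 1+, 2+, 3+).
#' @export
score_ihc_cells <- function(od, regions, positive_threshold = 0.1,
                            bins = c(0.2, 0.4, 0.6)) {
  if (!all(dim(od) == dim(regions)))
    stop("OD raster and region map have different shapes", call. = FALSE)
  stopifnot(length(bins) == 3, !is.unsorted(bins, strictly = TRUE))
  n <- max(regions)
  mean_od <- label_means(od, regions, n)
  eps <- 1e-9  # keep means that sit numerically on a cut in the closed bin
  positive <- !is.na(mean_od) & mean_od >= positive_threshold - eps
  bin <- rep("negative", n)
  bin[positive] <- c("1+", "2+", "3+")[
    pmax(1L, findInterval(mean_od[positive] + eps, bins))]
  if (any(positive & mean_od + eps < bins[1]))
    message("positive cells below the first intensity cut were binned as 1+")
  counts <- c(negative = sum(!positive),
              `1+` = sum(bin == "1+"), `2+` = sum(bin == "2+"),
              `3+` = sum(bin == "3+"))
  structure(list(cells = data.frame(label = seq_len(n), mean_od = mean_od,
                                    positive = positive, bin = bin),
                 counts = counts),
            class = "ki67_score")
}

#' @export
print.ki67_score <- function(x, ...) {
  cat("ki67_score bin counts:\n")
  print(x$counts)
  invisible(x)
}

#' Write per-slide IHC bin counts to CSV
#'
#' @param score a `ki67_score`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ihc_counts <- function(score, path) {
  df <- data.frame(bin = names(score$counts), n_cells = as.integer(score$counts))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
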