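# Low-level raster helpers shared by the segmentation and quantification stages.
# All rasters are plain R matrices indexed [row, col]; label maps are integer
# matrices with 0 = background.

#' Shift a matrix by whole pixels
#'
#' Vacated cells are filled with `fill`. Used to build separable running
#' min/max filters and boundary counts without loops over pixels.
#'
#' @param m matrix.
#' @param dr,dc shift in rows / columns (positive = down / right).
#' @param fill value for cells shifted in from outside the image.
#' @return matrix of the same dimensions.
#' @keywords internal
shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  keep_r <- src_r >= 1L & src_r <= nr
  keep_c <- src_c >= 1L & src_c <= nc
  if (any(keep_r) && any(keep_c)) {
    out[keep_r, keep_c] <- m[src_r[keep_r], src_c[keep_c]]
  }
  out
}

# Running extreme along one dimension via repeated shifted pmin/pmax.
# Window offsets follow the centred convention: for width w the window spans
# [-floor(w/2), ceiling(w/2) - 1] around each pixel, clipped at the image edge
# (i.e. the extreme is taken over the window intersected with the image).
run_extreme_1d <- function(m, size, dim, op) {
  pad <- if (identical(op, pmin)) Inf else -Inf
  lo <- -(size %/% 2L)
  hi <- size - 1L + lo
  acc <- m
  # window offset o reads m[p + o], i.e. a shift by -o
  for (k in setdiff(-seq.int(lo, hi), 0L)) {
    s <- if (dim == 1L) shift_mat(m, k, 0L, pad) else shift_mat(m, 0L, k, pad)
    acc <- op(acc, s)
  }
  acc
}

#' Square-window minimum filter
#'
#' Each pixel is replaced by the minimum over a `size` x `size` window centred
#' on it (window clipped at the image border). Separable implementation.
#'
#' @param m numeric matrix.
#' @param size window side in pixels (>= 1).
#' @return filtered matrix.
#' @export
min_filter <- function(m, size) {
  stopifnot(is.matrix(m), size >= 1)
  if (size == 1) return(m)
  run_extreme_1d(run_extreme_1d(m, size, 1L, pmin), size, 2L, pmin)
}

#' Square-window maximum filter
#'
#' @inheritParams min_filter
#' @return filtered matrix.
#' @export
max_filter <- function(m, size) {
  stopifnot(is.matrix(m), size >= 1)
  if (size == 1) return(m)
  run_extreme_1d(run_extreme_1d(m, size, 1L, pmax), size, 2L, pmax)
}

#' Quantize a [0,1] raster to 8-bit
#'
#' Values are clipped to [0,1] and rounded half-up onto 0..255, matching the
#' unsigned-8-bit provenance of the microscope images.
#'
#' @param x numeric matrix in (approximately) [0,1].
#' @return integer matrix with values in 0..255.
#' @export
quantize_u8 <- function(x) {
  q <- floor(pmin(pmax(x, 0), 1) * 255 + 0.5)
  mode(q) <- "integer"
  q
}

#' Label connected components of a binary mask
#'
#' 4- or 8-connected labeling with labels 1..n assigned in column-major order
#' of each component's first pixel (deterministic). 8-connectivity is obtained
#' by merging 4-connected labels that touch diagonally.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  mode(lab) <- "integer"
  n4 <- max(lab)
  if (n4 == 0L) return(lab)
  if (connectivity == 8) {
    parent <- seq_len(n4)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (d in list(c(1L, 1L), c(1L, -1L))) {
      s <- shift_mat(lab, d[1], d[2], 0L)
      sel <- lab > 0L & s > 0L & lab != s
      if (any(sel)) {
        pr <- unique(cbind(lab[sel], s[sel]))
        for (k in seq_len(nrow(pr))) {
          a <- find(pr[k, 1]); b <- find(pr[k, 2])
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
    root <- vapply(seq_len(n4), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  relabel_consecutive(lab)
}

# Relabel positive labels to consecutive 1..n, ordered by first (column-major)
# occurrence; background stays 0.
relabel_consecutive <- function(lab) {
  pos <- lab > 0L
  if (!any(pos)) return(lab)
  u <- unique(lab[pos])           # unique() preserves first-occurrence order
  lab[pos] <- match(lab[pos], u)
  mode(lab) <- "integer"
  lab
}

#' Component areas of a label map
#'
#' @param lab integer label matrix.
#' @return named integer vector of pixel counts, names = label ids.
#' @keywords internal
label_areas <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  a <- tabulate(lab[lab > 0L], nbins = n)
  names(a) <- seq_len(n)
  a
}

# Directed boundary-transition counts per label: number of pixels of each label
# whose neighbour in direction (dr,dc) carries a different label (or lies
# outside the image). Summed over both orientations of a direction this counts
# every crossing of that direction's scan lines.
transitions_by_label <- function(lab, dr, dc) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  s1 <- shift_mat(lab, dr, dc, -1L)
  s2 <- shift_mat(lab, -dr, -dc, -1L)
  sel1 <- lab > 0L & lab != s1
  sel2 <- lab > 0L & lab != s2
  tabulate(c(lab[sel1], lab[sel2]), nbins = n)
}

#' Per-component perimeter estimates
#'
#' Two pinned estimators for the elongation filter:
#' * `"steps"` (default): the 4-connected boundary-step count — the number of
#'   unit pixel edges separating the component from anything else (including
#'   the image border). A `w x h` rectangle scores exactly `2(w+h)`.
#' * `"crofton"`: Crofton-style estimate from line intercepts in 4 directions,
#'   `pi/8 * (n_h + n_v + (n_d1 + n_d2)/sqrt(2))`; closer to the Euclidean
#'   perimeter of smooth shapes (a digital disk of radius r scores ~ 2*pi*r).
#'
#' @param lab integer label matrix.
#' @param method "steps" or "crofton".
#' @return numeric vector of perimeters, one per label 1..max(lab).
#' @export
label_perimeters <- function(lab, method = c("steps", "crofton")) {
  method <- match.arg(method)
  nh <- transitions_by_label(lab, 0L, 1L)
  nv <- transitions_by_label(lab, 1L, 0L)
  if (method == "steps") return(as.numeric(nh + nv))
  nd1 <- transitions_by_label(lab, 1L, 1L)
  nd2 <- transitions_by_label(lab, 1L, -1L)
  pi / 8 * (nh + nv + (nd1 + nd2) / sqrt(2))
}
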