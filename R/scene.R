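# Seeded synthetic CAM-xenograft scenes with ground truth.
#
# A scene emulates a 10x fluorescence field of xenograft tissue: large round
# human nuclei in the interior, a dense rim of elongated chicken (CAM) nuclei
# hugging the image border, sparse elongated chicken nuclei infiltrating the
# tissue, and marker channels painted over a known subset of cells. Everything
# is rendered at pixel resolution, quantized to 8 bits, and accompanied by a
# ground-truth table so segmentation, classification and quantification can be
# scored without real images.

#' Declare a marker channel for the scene generator
#'
#' @param name channel name (e.g. "ACTA2").
#' @param target_class nucleus class that can be positive
#'   ("human", "chicken_peripheral" or "chicken_infiltrating").
#' @param positive_fraction fraction of target-class cells painted positive.
#' @param morphology `"cytoplasmic_ring"` paints the whole cell body (nucleus
#'   plus perinuclear territory); `"elongated_fibre"` paints a thin fibre
#'   (aspect ratio > 5) through the cell, as fibrous cytoskeletal stains do.
#' @param intensity marker intensity in [0,1]; must exceed the 0.4 detection
#'   threshold to be recoverable.
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(name, target_class = "human", positive_fraction = 0.5,
                        morphology = c("cytoplasmic_ring", "elongated_fibre"),
                        intensity = 0.8) {
  morphology <- match.arg(morphology)
  stopifnot(is.character(name), nchar(name) > 0,
            target_class %in% c("human", "chicken_peripheral", "chicken_infiltrating"),
            positive_fraction >= 0, positive_fraction <= 1,
            intensity >= 0, intensity <= 1)
  structure(list(name = name, target_class = target_class,
                 positive_fraction = positive_fraction,
                 morphology = morphology, intensity = intensity),
            class = "marker_spec")
}

#' Parameters of a synthetic scene
#'
#' Defaults describe a tissue-dense 512 x 512 field: interior human nuclei,
#' a dense peripheral CAM rim, and a few infiltrating chicken nuclei. The
#' nuclear (DAPI-positive) coverage of the defaults exceeds 5% of the frame,
#' which the percentile-saturation step of the segmentation pipeline requires
#' (see the methods vignette).
#'
#' @param image_height,image_width frame size in pixels.
#' @param n_human,n_chicken_rim,n_chicken_infiltrating nucleus counts.
#' @param human_area_range,chicken_area_range nuclear area intervals (px^2).
#' @param human_ecc_range,chicken_ecc_range eccentricity intervals in [0,1).
#' @param rim_width width in pixels of the border annulus holding the CAM rim.
#' @param touching_pair_fraction fraction of human nuclei placed as touching
#'   pairs whose union exceeds 200 px (exercises watershed splitting).
#' @param marker_specs list of [marker_spec()] objects.
#' @param noise_sd additive Gaussian noise sd (intensity units, pre-quantization).
#' @param background_level DAPI-channel background in [0,1].
#' @param dapi_intensity nuclear DAPI intensity in [0,1].
#' @param min_clearance extra centre-to-centre clearance (px) between interior
#'   nuclei beyond the sum of their semi-major axes. `NULL` (default) picks 28
#'   when marker channels are present — so each cell's marker footprint stays
#'   inside its own cytoplasmic territory — and 3 otherwise.
#' @param seed integer RNG seed; identical params give bit-identical scenes.
#' @return a validated `scene_params` list.
#' @export
scene_params <- function(image_height = 512, image_width = 512,
                         n_human = 45, n_chicken_rim = 300,
                         n_chicken_infiltrating = 8,
                         human_area_range = c(80, 180),
                         human_ecc_range = c(0.2, 0.5),
                         chicken_area_range = c(25, 50),
                         chicken_ecc_range = c(0.8, 0.95),
                         rim_width = 40,
                         touching_pair_fraction = 0,
                         marker_specs = list(),
                         noise_sd = 0.05,
                         background_level = 0.1,
                         dapi_intensity = 0.9,
                         min_clearance = NULL,
                         seed = 1) {
  p <- list(image_height = as.integer(image_height), image_width = as.integer(image_width),
            n_human = as.integer(n_human), n_chicken_rim = as.integer(n_chicken_rim),
            n_chicken_infiltrating = as.integer(n_chicken_infiltrating),
            human_area_range = as.numeric(human_area_range),
            human_ecc_range = as.numeric(human_ecc_range),
            chicken_area_range = as.numeric(chicken_area_range),
            chicken_ecc_range = as.numeric(chicken_ecc_range),
            rim_width = as.numeric(rim_width),
            touching_pair_fraction = as.numeric(touching_pair_fraction),
            marker_specs = marker_specs,
            noise_sd = as.numeric(noise_sd),
            background_level = as.numeric(background_level),
            dapi_intensity = as.numeric(dapi_intensity),
            min_clearance = min_clearance,
            seed = as.integer(seed))
  validate_scene_params(p)
  if (is.null(p$min_clearance)) {
    p$min_clearance <- if (length(marker_specs) > 0) 28 else 3
  }
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  chk_range <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2 || !(r[1] < r[2]) || r[1] < lo || r[2] > hi)
      stop(sprintf("%s must be a non-degenerate interval with low < high", nm), call. = FALSE)
  }
  if (p$image_height < 16 || p$image_width < 16) stop("image dimensions too small", call. = FALSE)
  counts <- c(p$n_human, p$n_chicken_rim, p$n_chicken_infiltrating)
  if (any(counts < 0)) stop("all nucleus counts must be >= 0", call. = FALSE)
  chk_range(p$human_area_range, "human_area_range", lo = 1)
  chk_range(p$chicken_area_range, "chicken_area_range", lo = 1)
  chk_range(p$human_ecc_range, "human_ecc_range", lo = 0, hi = 1 - 1e-9)
  chk_range(p$chicken_ecc_range, "chicken_ecc_range", lo = 0, hi = 1 - 1e-9)
  if (p$rim_width >= min(p$image_height, p$image_width) / 2)
    stop("rim_width must be below half the smallest image dimension", call. = FALSE)
  if (p$touching_pair_fraction < 0 || p$touching_pair_fraction > 1)
    stop("touching_pair_fraction must lie in [0,1]", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$background_level < 0 || p$background_level > 1)
    stop("background_level must lie in [0,1]", call. = FALSE)
  for (ms in p$marker_specs)
    if (!inherits(ms, "marker_spec")) stop("marker_specs must be marker_spec objects", call. = FALSE)
  invisible(p)
}

# semi-axes of the ellipse with given area and eccentricity
ellipse_axes <- function(area, ecc) {
  boa <- sqrt(1 - ecc^2)
  a <- sqrt(area / (pi * boa))
  c(a = a, b = a * boa)
}

# pixel centres inside an ellipse, clipped to the frame
ellipse_pixels <- function(cr, cc, a, b, theta, H, W) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(W, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  rr <- r0:r1; cc2 <- c0:c1
  R <- matrix(rr, length(rr), length(cc2)) - cr
  C <- matrix(cc2, length(rr), length(cc2), byrow = TRUE) - cc
  X <- C * cos(theta) + R * sin(theta)
  Y <- -C * sin(theta) + R * cos(theta)
  inside <- (X / a)^2 + (Y / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc2[idx[, 2]])
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic CAM-xenograft scene with ground truth
#'
#' Renders nuclei as filled ellipses (orientation uniform in `[0, pi)`), the
#' CAM rim as a dense jittered annular lattice of tangentially oriented
#' elongated nuclei, and marker channels over exactly the ground-truth
#' positive cells. Additive Gaussian noise is applied, clipped to [0,1], and
#' the result quantized round-half-up to 8 bits.
#'
#' @param params a [scene_params()] object.
#' @return list with `scene` (an `image_scene`: named list of 8-bit channel
#'   matrices, DAPI first) and `truth` (a `scene_truth`: nucleus table,
#'   per-marker positive id sets, marker specs).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_local_seed(params$seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  H <- p$image_height; W <- p$image_width
  nuclei <- list()
  add_nucleus <- function(class, row, col, a, b, theta, area, ecc, pair_id = NA_integer_) {
    nuclei[[length(nuclei) + 1L]] <<- data.frame(
      id = NA_integer_, class = class, row = row, col = col,
      a = a, b = b, theta = theta, area_target = area, ecc_target = ecc,
      pair_id = pair_id)
  }

  ## --- interior nuclei (humans + pairs + infiltrating chicken), RSA placement
  clearance <- p$min_clearance
  placed_r <- numeric(0); placed_c <- numeric(0); placed_rad <- numeric(0)
  try_place <- function(margin, rad, max_try = 8000) {
    lo_r <- margin; hi_r <- H - margin; lo_c <- margin; hi_c <- W - margin
    if (lo_r >= hi_r || lo_c >= hi_c) return(NULL)
    for (i in seq_len(max_try)) {
      r <- stats::runif(1, lo_r, hi_r); c <- stats::runif(1, lo_c, hi_c)
      if (!length(placed_r)) return(c(r, c))
      d <- sqrt((placed_r - r)^2 + (placed_c - c)^2)
      if (all(d >= placed_rad + rad + clearance)) return(c(r, c))
    }
    NULL
  }
  register <- function(r, c, rad) {
    placed_r <<- c(placed_r, r); placed_c <<- c(placed_c, c); placed_rad <<- c(placed_rad, rad)
  }

  n_pairs <- floor(p$touching_pair_fraction * p$n_human / 2)
  n_single <- p$n_human - 2L * n_pairs

  sample_nucleus <- function(area_range, ecc_range) {
    area <- stats::runif(1, area_range[1], area_range[2])
    ecc <- stats::runif(1, ecc_range[1], ecc_range[2])
    ax <- ellipse_axes(area, ecc)
    list(area = area, ecc = ecc, a = ax["a"], b = ax["b"],
         theta = stats::runif(1, 0, pi))
  }

  # keep interior cells' marker footprints (paint reach ~16 px) clear of the rim
  margin_extra <- if (length(p$marker_specs) > 0) 16 else 0

  # large footprints (pairs) first: random sequential placement packs better
  for (i in seq_len(n_pairs)) {
    # touching pair: union must exceed the 200-px splitting threshold
    amin <- p$human_area_range[1]; amax <- p$human_area_range[2]
    if (2 * amax < 260)
      stop("human_area_range too small for touching pairs with union > 200 px", call. = FALSE)
    # near-equal members and a shallow overlap keep the union's distance
    # transform clearly bimodal (two peaks well above the neck saddle)
    repeat {
      a1 <- stats::runif(1, amin, amax)
      a2 <- min(max(a1 * stats::runif(1, 0.9, 1.1), amin), amax)
      if (a1 + a2 >= 280) break
    }
    e1 <- stats::runif(1, p$human_ecc_range[1], p$human_ecc_range[2])
    e2 <- stats::runif(1, p$human_ecc_range[1], p$human_ecc_range[2])
    ax1 <- ellipse_axes(a1, e1); ax2 <- ellipse_axes(a2, e2)
    r1 <- sqrt(a1 / pi); r2 <- sqrt(a2 / pi)
    off <- 0.9 * (r1 + r2)
    ang <- stats::runif(1, 0, 2 * pi)
    rad_pair <- off + max(ax1["a"], ax2["a"])
    margin <- p$rim_width + 6 + margin_extra + rad_pair
    pos <- try_place(margin, rad_pair)
    if (is.null(pos))
      stop(sprintf("could not place %d human nuclei without forbidden overlap", p$n_human), call. = FALSE)
    register(pos[1], pos[2], rad_pair)
    dr <- off * sin(ang); dc <- off * cos(ang)
    add_nucleus("human", pos[1], pos[2], ax1["a"], ax1["b"], stats::runif(1, 0, pi), a1, e1, i)
    add_nucleus("human", pos[1] + dr, pos[2] + dc, ax2["a"], ax2["b"], stats::runif(1, 0, pi), a2, e2, i)
  }

  for (i in seq_len(n_single)) {
    nu <- sample_nucleus(p$human_area_range, p$human_ecc_range)
    margin <- p$rim_width + 6 + margin_extra + nu$a
    pos <- try_place(margin, nu$a)
    if (is.null(pos))
      stop(sprintf("could not place %d human nuclei without forbidden overlap", p$n_human), call. = FALSE)
    register(pos[1], pos[2], nu$a)
    add_nucleus("human", pos[1], pos[2], nu$a, nu$b, nu$theta, nu$area, nu$ecc)
  }

  for (i in seq_len(p$n_chicken_infiltrating)) {
    nu <- sample_nucleus(p$chicken_area_range, p$chicken_ecc_range)
    margin <- p$rim_width + 6 + margin_extra + nu$a
    pos <- try_place(margin, nu$a)
    if (is.null(pos))
      stop(sprintf("could not place %d infiltrating chicken nuclei without forbidden overlap",
                   p$n_chicken_infiltrating), call. = FALSE)
    register(pos[1], pos[2], nu$a)
    add_nucleus("chicken_infiltrating", pos[1], pos[2], nu$a, nu$b, nu$theta, nu$area, nu$ecc)
  }

  ## --- CAM rim: jittered annular lattice, tangential orientation
  if (p$n_chicken_rim > 0) {
    ax_max <- ellipse_axes(p$chicken_area_range[2], p$chicken_ecc_range[2])
    dt <- 2 * ax_max["a"] + 4   # along-border spacing
    dd <- 2 * ax_max["b"] + 4   # between-ring spacing
    depth_lo <- ax_max["b"] + 3
    depth_hi <- p$rim_width - ax_max["b"] - 1
    depths <- seq(depth_lo, depth_hi, by = dd)
    slots <- list()
    for (d in depths) {
      # four sides of the inset rectangle at this depth
      cs <- seq(d + dt / 2, W - d - dt / 2, by = dt)
      rs <- seq(d + dt, H - d - dt, by = dt)  # corners covered by top/bottom rows
      if (length(cs)) {
        slots <- c(slots,
                   lapply(cs, function(x) c(d, x, 0)),          # top, tangent = columns
                   lapply(cs, function(x) c(H - d, x, 0)))       # bottom
      }
      if (length(rs)) {
        slots <- c(slots,
                   lapply(rs, function(x) c(x, d, pi / 2)),      # left, tangent = rows
                   lapply(rs, function(x) c(x, W - d, pi / 2)))  # right
      }
    }
    if (length(slots) < p$n_chicken_rim)
      stop(sprintf("could not place %d rim chicken nuclei in a rim of width %g",
                   p$n_chicken_rim, p$rim_width), call. = FALSE)
    pick <- sort(sample.int(length(slots), p$n_chicken_rim))
    for (k in pick) {
      sl <- slots[[k]]
      nu <- sample_nucleus(p$chicken_area_range, p$chicken_ecc_range)
      # tangential orientation: theta measured from the column axis
      theta <- sl[3] + stats::rnorm(1, 0, 0.1)
      # keep fully inside using the ellipse's directional extents
      ext_r <- sqrt((nu$a * sin(theta))^2 + (nu$b * cos(theta))^2)
      ext_c <- sqrt((nu$a * cos(theta))^2 + (nu$b * sin(theta))^2)
      r <- min(max(sl[1] + stats::runif(1, -1, 1), ext_r + 1), H - ext_r - 1)
      c <- min(max(sl[2] + stats::runif(1, -1, 1), ext_c + 1), W - ext_c - 1)
      add_nucleus("chicken_peripheral", r, c, nu$a, nu$b, theta, nu$area, nu$ecc)
    }
  }

  nuc <- if (length(nuclei)) do.call(rbind, nuclei) else
    data.frame(id = integer(0), class = character(0), row = numeric(0), col = numeric(0),
               a = numeric(0), b = numeric(0), theta = numeric(0),
               area_target = numeric(0), ecc_target = numeric(0),
               pair_id = integer(0))
  if (nrow(nuc)) nuc$id <- seq_len(nrow(nuc))

  ## --- render DAPI
  dapi <- matrix(p$background_level, H, W)
  px_list <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    px <- ellipse_pixels(nuc$row[i], nuc$col[i], nuc$a[i], nuc$b[i], nuc$theta[i], H, W)
    px_list[[i]] <- px
    if (nrow(px)) dapi[px] <- pmax(dapi[px], p$dapi_intensity)
  }
  nuc$area_px <- vapply(px_list, nrow, integer(1))

  ## --- marker channels over ground-truth positive cells
  channels <- list(DAPI = dapi)
  positives <- list()
  for (ms in p$marker_specs) {
    ch <- matrix(0, H, W)
    eligible <- nuc$id[nuc$class == ms$target_class]
    k <- round(ms$positive_fraction * length(eligible))
    pos_ids <- if (k > 0) sort(sample(eligible, k)) else integer(0)
    for (id in pos_ids) {
      i <- match(id, nuc$id)
      if (ms$morphology == "cytoplasmic_ring") {
        # cell body: nucleus plus perinuclear territory out to 12 px from the
        # nuclear boundary (covers the default 10-px cytoplasm expansion)
        ext <- 12
        px <- paint_cell_body(px_list[[i]], ext, H, W)
      } else {
        px <- paint_fibre(nuc$row[i], nuc$col[i], H, W,
                          half_len = 15, half_wid = 1,
                          vertical = stats::runif(1) < 0.5)
      }
      if (nrow(px)) ch[px] <- pmax(ch[px], ms$intensity)
    }
    positives[[ms$name]] <- pos_ids
    channels[[ms$name]] <- ch
  }

  ## --- noise, clipping, 8-bit quantization
  channels <- lapply(channels, function(m) {
    if (p$noise_sd > 0) m <- m + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
    quantize_u8(m)
  })

  scene <- structure(list(channels = channels, height = H, width = W, bit_depth = 8L),
                     class = "image_scene")
  truth <- structure(list(nuclei = nuc, positives = positives, marker_specs = p$marker_specs),
                     class = "scene_truth")
  list(scene = scene, truth = truth)
}

# pixels within `ext` of the nucleus pixel set (exact Euclidean dilation)
paint_cell_body <- function(nuc_px, ext, H, W) {
  if (!nrow(nuc_px)) return(nuc_px)
  r0 <- max(1L, min(nuc_px[, 1]) - ext - 1L); r1 <- min(H, max(nuc_px[, 1]) + ext + 1L)
  c0 <- max(1L, min(nuc_px[, 2]) - ext - 1L); c1 <- min(W, max(nuc_px[, 2]) + ext + 1L)
  box <- matrix(1, r1 - r0 + 1L, c1 - c0 + 1L)
  box[cbind(nuc_px[, 1] - r0 + 1L, nuc_px[, 2] - c0 + 1L)] <- 0
  d <- EBImage::imageData(EBImage::distmap(box))  # distance to the nucleus set
  idx <- which(d <= ext, arr.ind = TRUE)
  cbind(row = idx[, 1] + r0 - 1L, col = idx[, 2] + c0 - 1L)
}

# thin axis-aligned fibre through the cell centre (aspect ratio > 5)
paint_fibre <- function(cr, cc, H, W, half_len = 15, half_wid = 1, vertical = FALSE) {
  if (vertical) {
    rr <- max(1L, round(cr - half_len)):min(H, round(cr + half_len))
    cc2 <- max(1L, round(cc - half_wid)):min(W, round(cc + half_wid))
  } else {
    rr <- max(1L, round(cr - half_wid)):min(H, round(cr + half_wid))
    cc2 <- max(1L, round(cc - half_len)):min(W, round(cc + half_len))
  }
  as.matrix(expand.grid(row = rr, col = cc2))
}

#' @export
print.image_scene <- function(x, ...) {
  cat(sprintf("image_scene: %dx%d px, %d-bit, channels: %s\n",
              x$height, x$width, x$bit_depth, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth: %d nuclei (%s)\n", nrow(x$nuclei),
              paste(sprintf("%s=%d", names(table(x$nuclei$class)), table(x$nuclei$class)),
                    collapse = ", ")))
  for (nm in names(x$positives))
    cat(sprintf("  %s: %d positive cells\n", nm, length(x$positives[[nm]])))
  invisible(x)
}

#' Write a scene and its ground truth to disk
#'
#' Writes a multipage 8-bit grayscale TIFF (one page per channel, DAPI first)
#' plus plain-text sidecars: `channels.csv` (page order to channel name),
#' `nuclei.csv`, `positives.csv` and `marker_specs.csv`. Pixel values
#' round-trip exactly through [read_scene()].
#'
#' @param scene an `image_scene`.
#' @param truth a `scene_truth` (or `NULL` to write the image only).
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
scene_to_files <- function(scene, truth, path) {
  stopifnot(inherits(scene, "image_scene"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2) != 0)
    stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  pages <- lapply(scene$channels, function(m) m / 255)
  tiff::writeTIFF(pages, file.path(path, "scene.tif"), bits.per.sample = 8L)
  utils::write.csv(data.frame(page = seq_along(scene$channels), name = names(scene$channels)),
                   file.path(path, "channels.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth$nuclei, file.path(path, "nuclei.csv"), row.names = FALSE)
    pos <- do.call(rbind, c(list(data.frame(marker = character(0), id = integer(0))),
                            lapply(names(truth$positives), function(nm)
                              if (length(truth$positives[[nm]]))
                                data.frame(marker = nm, id = truth$positives[[nm]])
                              else NULL)))
    utils::write.csv(pos, file.path(path, "positives.csv"), row.names = FALSE)
    ms <- do.call(rbind, lapply(truth$marker_specs, function(s)
      data.frame(name = s$name, target_class = s$target_class,
                 positive_fraction = s$positive_fraction,
                 morphology = s$morphology, intensity = s$intensity)))
    if (is.null(ms)) ms <- data.frame(name = character(0), target_class = character(0),
                                      positive_fraction = numeric(0),
                                      morphology = character(0), intensity = numeric(0))
    utils::write.csv(ms, file.path(path, "marker_specs.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a scene (and ground truth, if present) from disk
#'
#' @param path directory written by [scene_to_files()], or a TIFF file path
#'   (channel names then default to DAPI, marker1, ...).
#' @return list with `scene` and `truth` (`NULL` when no sidecars exist).
#' @export
read_scene <- function(path) {
  tif <- if (dir.exists(path)) file.path(path, "scene.tif") else path
  if (!file.exists(tif)) stop(sprintf("no scene TIFF at '%s'", tif), call. = FALSE)
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) { mode(m) <- "integer"; m })
  nms <- paste0("channel", seq_along(pages)); nms[1] <- "DAPI"
  truth <- NULL
  if (dir.exists(path)) {
    chf <- file.path(path, "channels.csv")
    if (file.exists(chf)) {
      ch <- utils::read.csv(chf)
      nms[ch$page] <- ch$name
    }
    nf <- file.path(path, "nuclei.csv")
    if (file.exists(nf)) {
      nuclei <- utils::read.csv(nf)
      pos <- utils::read.csv(file.path(path, "positives.csv"))
      ms <- utils::read.csv(file.path(path, "marker_specs.csv"))
      specs <- lapply(seq_len(nrow(ms)), function(i)
        marker_spec(ms$name[i], ms$target_class[i], ms$positive_fraction[i],
                    ms$morphology[i], ms$intensity[i]))
      positives <- stats::setNames(
        lapply(ms$name, function(nm) pos$id[pos$marker == nm]), ms$name)
      truth <- structure(list(nuclei = nuclei, positives = positives, marker_specs = specs),
                         class = "scene_truth")
    }
  }
  names(pages) <- nms
  scene <- structure(list(channels = pages, height = nrow(pages[[1]]),
                          width = ncol(pages[[1]]), bit_depth = 8L),
                     class = "image_scene")
  list(scene = scene, truth = truth)
}

#' Sample feature vectors from the separable three-class preset
#'
#' Draws (area, eccentricity, k-3 density) features from well-separated
#' class-conditional Gaussians: human nuclei are large and round with
#' intermediate neighbour distances; peripheral (CAM rim) chicken nuclei are
#' small, elongated and densely packed (low k-3); infiltrating chicken nuclei
#' share the chicken morphology but sit sparsely in the tissue (high k-3).
#' Used to train the packaged default classifier and in classifier tests.
#'
#' @param n_per_class examples per class.
#' @param seed RNG seed.
#' @return data.frame with columns area, eccentricity, k3_density, class.
#' @export
sample_separable_features <- function(n_per_class = 200, seed = 1) {
  with_local_seed(seed, {
    one <- function(n, cls, am, asd, em, esd, km, ksd) data.frame(
      area = pmax(5, stats::rnorm(n, am, asd)),
      eccentricity = pmin(0.98, pmax(0.01, stats::rnorm(n, em, esd))),
      k3_density = pmax(0.5, stats::rnorm(n, km, ksd)),
      class = cls)
    rbind(one(n_per_class, "human", 120, 15, 0.30, 0.05, 25, 4),
          one(n_per_class, "chicken_peripheral", 35, 8, 0.85, 0.05, 8, 2),
          one(n_per_class, "chicken_infiltrating", 35, 8, 0.85, 0.05, 40, 6))
  })
}
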