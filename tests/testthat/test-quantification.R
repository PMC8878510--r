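# Cytoplasm assignment, marker masks, MFI measurement, positivity and the
# elongation filter.

make_scene <- function(channels) {
  structure(list(channels = channels, height = nrow(channels[[1]]),
                 width = ncol(channels[[1]]), bit_depth = 8L),
            class = "image_scene")
}

test_that("a single nucleus gets exactly its within-radius annulus", {
  lab <- matrix(0L, 50, 50)
  lab[disk_mask(50, 50, 25, 25, 5)] <- 1L
  reg <- assign_cytoplasm(lab, 10)
  expect_true(all(reg$cytoplasm[reg$nuclear > 0] == 0))  # disjoint
  d_bg <- EBImage::imageData(EBImage::distmap(1 - (lab > 0)))
  inside <- d_bg <= 10 & lab == 0L
  expect_identical(reg$cytoplasm > 0, inside)
  expect_error(assign_cytoplasm(lab, 0), "expansion_radius")
})

test_that("two-nucleus territories follow the perpendicular bisector", {
  lab <- matrix(0L, 60, 60)
  lab[disk_mask(60, 60, 30, 20, 4)] <- 1L
  lab[disk_mask(60, 60, 30, 40, 4)] <- 2L
  reg <- assign_cytoplasm(lab, 15)
  cy <- reg$cytoplasm
  # brute-force nearest-nucleus-pixel oracle, +-1 px at the boundary
  np <- which(lab > 0, arr.ind = TRUE)
  nl <- lab[np]
  idx <- which(cy > 0, arr.ind = TRUE)
  d1 <- d2 <- rep(Inf, nrow(idx))
  for (k in seq_len(nrow(np))) {
    dd <- (idx[, 1] - np[k, 1])^2 + (idx[, 2] - np[k, 2])^2
    if (nl[k] == 1L) d1 <- pmin(d1, dd) else d2 <- pmin(d2, dd)
  }
  clear <- abs(sqrt(d1) - sqrt(d2)) > 1   # away from the tie zone
  oracle <- ifelse(d1 < d2, 1L, 2L)
  expect_true(all(cy[idx][clear] == oracle[clear]))
})

test_that("marker masks are prepared without saturation and strictly thresholded", {
  # constant channel at 102/255 = 0.4: background subtraction flattens it
  expect_false(any(prepare_marker_mask(matrix(102L, 60, 60), 50)))
  # isolated bright blob on zero background is retained as-is
  ch <- matrix(0L, 60, 60)
  ch[disk_mask(60, 60, 30, 30, 4)] <- 128L
  got <- prepare_marker_mask(ch, 50)
  expect_identical(got, ch > 0L)
  # a pixel at exactly 0.4 after preparation stays out; 0.404 gets in
  ch2 <- matrix(0L, 60, 60); ch2[10, 10] <- 102L; ch2[20, 20] <- 103L
  got2 <- prepare_marker_mask(ch2, 50)
  expect_false(got2[10, 10])
  expect_true(got2[20, 20])
})

test_that("per-cell MFI follows the mean-of-region-means rule", {
  lab <- matrix(0L, 40, 40)
  lab[disk_mask(40, 40, 20, 20, 5)] <- 1L
  reg <- assign_cytoplasm(lab, 6)
  # nuclear pixels at 0.2, cytoplasmic at 0.6
  ch <- matrix(0L, 40, 40)
  ch[reg$nuclear > 0] <- 51L
  ch[reg$cytoplasm > 0] <- 153L
  sc <- make_scene(list(DAPI = matrix(0L, 40, 40), MK = ch))
  m <- measure_cells(sc, reg, "MK")
  expect_equal(m$mfi_nuclear, 0.2)
  expect_equal(m$mfi_cytoplasmic, 0.6)
  expect_equal(m$mfi_combined, 0.4)
  # pooled alternative weights by pixel counts
  mp <- measure_cells(sc, reg, "MK", combine = "pooled")
  n_n <- sum(reg$nuclear > 0); n_c <- sum(reg$cytoplasm > 0)
  expect_equal(mp$mfi_combined, (0.2 * n_n + 0.6 * n_c) / (n_n + n_c))
  # uniform marker: all three MFIs equal the value
  sc2 <- make_scene(list(DAPI = matrix(0L, 40, 40), MK = matrix(102L, 40, 40)))
  m2 <- measure_cells(sc2, reg, "MK")
  expect_equal(m2$mfi_nuclear, 0.4); expect_equal(m2$mfi_combined, 0.4)
  # zero channel, and unknown markers error
  m3 <- measure_cells(make_scene(list(DAPI = ch, MK = matrix(0L, 40, 40))), reg, "MK")
  expect_equal(m3$mfi_combined, 0)
  expect_error(measure_cells(sc, reg, "NOPE"), "unknown")
})

test_that("positivity needs strictly more than min_overlap pixels", {
  region <- rect_mask(20, 20, 5, 5, 5, 5)
  mk5 <- rect_mask(20, 20, 5, 5, 1, 5)
  expect_false(call_positive(region, mk5, 5)$positive)
  expect_equal(call_positive(region, mk5, 5)$overlap_px, 5L)
  mk6 <- rect_mask(20, 20, 5, 5, 2, 3)
  expect_true(call_positive(region, mk6, 5)$positive)
  expect_equal(call_positive(region, matrix(FALSE, 20, 20), 5)$overlap_px, 0L)
})

test_that("growing the marker mask never turns a positive cell negative", {
  region <- disk_mask(30, 30, 15, 15, 6)
  mask <- rect_mask(30, 30, 13, 13, 2, 4)
  base <- call_positive(region, mask, 5)
  grown <- call_positive(region, mask | rect_mask(30, 30, 12, 12, 4, 6), 5)
  expect_true(grown$overlap_px >= base$overlap_px)
  expect_true(!base$positive || grown$positive)
})

test_that("the elongation filter keeps fibres and rejects blobs", {
  # 2x30 fibre: area 60, boundary steps 64, ratio ~1.07 -> kept
  fib <- rect_mask(60, 60, 10, 10, 2, 30)
  expect_identical(filter_elongated(fib), fib)
  # disk radius 10: ratio well below 0.5 -> removed
  dsk <- disk_mask(60, 60, 40, 30, 10)
  expect_false(any(filter_elongated(dsk)))
  # 15-px elongated object: fails the area clause regardless of ratio
  thin <- rect_mask(60, 60, 50, 10, 1, 15)
  expect_false(any(filter_elongated(thin)))
  # exactly 20 px is not "larger than 20"
  r20 <- rect_mask(60, 60, 30, 40, 2, 10)
  expect_false(any(filter_elongated(r20)))
})

test_that("slide summaries aggregate MFI, counts and double positives", {
  meas <- data.frame(
    label = rep(1:4, 2), class = "human",
    marker = rep(c("ACTA2", "MMP2"), each = 4),
    mfi_nuclear = 0, mfi_cytoplasmic = 0,
    mfi_combined = c(0.1, 0.2, 0.6, 0.3, rep(0.5, 4)),
    overlap_px = 10L,
    positive = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  s <- summarize_slide(meas, list(c("ACTA2", "MMP2")))
  a <- s$markers[s$markers$marker == "ACTA2", ]
  expect_equal(a$mean_mfi, mean(c(0.1, 0.2, 0.6, 0.3)))
  expect_equal(a$n_positive, 4)
  expect_equal(s$double_positive$pct_double_positive, 25)
  # empty denominator reports NA, not 0
  meas2 <- meas; meas2$positive[meas2$marker == "ACTA2"] <- FALSE
  s2 <- summarize_slide(meas2, list(c("ACTA2", "MMP2")))
  expect_true(is.na(s2$double_positive$pct_double_positive))
  # three-cell MFI example
  m3 <- data.frame(label = 1:3, class = "human", marker = "X",
                   mfi_nuclear = 0, mfi_cytoplasmic = 0,
                   mfi_combined = c(0.1, 0.2, 0.6), overlap_px = 0L, positive = FALSE)
  expect_equal(summarize_slide(m3)$markers$mean_mfi, 0.3)
})

test_that("human metrics are unchanged by adding chicken-classified cells", {
  meas <- data.frame(label = 1:5, class = "human", marker = "CD44",
                     mfi_nuclear = 0.1, mfi_cytoplasmic = 0.2,
                     mfi_combined = seq(0.1, 0.5, by = 0.1),
                     overlap_px = 10L, positive = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  chick <- data.frame(label = 6:9, class = rep(c("chicken_peripheral",
                                                 "chicken_infiltrating"), 2),
                      marker = "CD44", mfi_nuclear = 0.9, mfi_cytoplasmic = 0.9,
                      mfi_combined = 0.9, overlap_px = 100L, positive = TRUE)
  s1 <- summarize_slide(meas)
  s2 <- summarize_slide(rbind(meas, chick))
  expect_equal(s1$markers, s2$markers)
})

test_that("noise-free scenes recover positives and intensities exactly", {
  out <- recovery_scene(seed = 9)
  lab <- segment_nuclei(out$scene)
  recs <- classify_nuclei(compute_features(lab), scene_trained_model())
  reg <- assign_cytoplasm(lab, 10)
  meas <- quantify_markers(out$scene, reg, recs, elongation_markers = "ACTA2")
  tl <- truth_labels(out$truth, lab)
  for (nm in names(out$truth$positives)) {
    m <- meas[meas$marker == nm, ]
    called <- sort(m$label[m$positive & m$class == "human"])
    expect_identical(called, sort(tl[out$truth$positives[[nm]]]))
  }
  # cell-body marker intensity recovered within quantization
  cd <- meas[meas$marker == "CD44", ]
  pos_lab <- tl[out$truth$positives$CD44]
  err <- abs(cd$mfi_combined[cd$label %in% pos_lab] - round(0.7 * 255) / 255)
  expect_lte(max(err), 1 / 255)
})
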