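# Morphometric features and the linear nucleus classifier.

test_that("features: area is the pixel count and disks are near-circular", {
  lab <- matrix(0L, 30, 30)
  lab[disk_mask(30, 30, 15, 15, 6)] <- 1L
  f <- compute_features(lab)
  expect_equal(f$area, sum(lab > 0))
  expect_lt(f$eccentricity, 0.1)
  expect_true(is.na(f$k3_density))  # fewer than 4 nuclei
})

test_that("a 10x12 rectangle has area 120 exactly and high eccentricity axis", {
  lab <- matrix(0L, 30, 30)
  lab[rect_mask(30, 30, 5, 5, 10, 12)] <- 1L
  f <- compute_features(lab)
  expect_equal(f$area, 120)
  # moment eccentricity of a 10x12 box is modest but nonzero
  expect_gt(f$eccentricity, 0)
})

test_that("k-3 density on a square grid matches the closed form", {
  d <- 20
  lab <- matrix(0L, 60, 60)
  centres <- rbind(c(20, 20), c(20, 40), c(40, 20), c(40, 40))
  for (i in 1:4) lab[disk_mask(60, 60, centres[i, 1], centres[i, 2], 3)] <- i
  f <- compute_features(lab)
  # each corner's 3 nearest: d, d, d*sqrt(2)
  expect_equal(f$k3_density, rep(d * (2 + sqrt(2)) / 3, 4), tolerance = 1e-10)
  # brute-force oracle over all pairwise distances
  D <- as.matrix(dist(centres))
  oracle <- apply(D, 1, function(r) mean(sort(r[r > 0])[1:3]))
  expect_equal(f$k3_density, unname(oracle), tolerance = 1e-10)
})

test_that("features are translation invariant and scale as expected", {
  base <- matrix(0L, 80, 80)
  ctr <- rbind(c(20, 20), c(20, 44), c(44, 20), c(50, 50))
  for (i in 1:4) base[disk_mask(80, 80, ctr[i, 1], ctr[i, 2], 5)] <- i
  shifted <- matrix(0L, 80, 80)
  for (i in 1:4) shifted[disk_mask(80, 80, ctr[i, 1] + 13, ctr[i, 2] + 9, 5)] <- i
  f1 <- compute_features(base); f2 <- compute_features(shifted)
  expect_equal(f1$area, f2$area)
  expect_equal(f1$eccentricity, f2$eccentricity, tolerance = 1e-8)
  expect_equal(f1$k3_density, f2$k3_density, tolerance = 1e-8)
  # uniform x2 scaling: k3 doubles, area ~quadruples (rasterization tolerance)
  scaled <- matrix(0L, 160, 160)
  for (i in 1:4) scaled[disk_mask(160, 160, 2 * ctr[i, 1], 2 * ctr[i, 2], 10)] <- i
  f3 <- compute_features(scaled)
  expect_equal(f3$k3_density, 2 * f1$k3_density, tolerance = 1e-8)
  expect_equal(f3$area / f1$area, rep(4, 4), tolerance = 0.1)
})

test_that("training on separable classes reaches perfect training accuracy", {
  feats <- sample_separable_features(60, seed = 5)
  model <- train_classifier(feats)
  pred <- classify_nuclei(transform(feats, label = seq_len(nrow(feats)),
                                    class = "unclassified"), model)
  expect_equal(mean(pred$class == feats$class), 1)
})

test_that("training rejects degenerate inputs with clear errors", {
  feats <- sample_separable_features(20, seed = 1)
  expect_error(train_classifier(feats[feats$class == "human", ]), "2 classes")
  bad <- feats; bad$area[3] <- NA
  expect_error(train_classifier(bad), "record 3")
  few <- feats[c(1:5, 21:25), ]
  expect_error(train_classifier(few), "at least 10")
})

test_that("duplicating the training set leaves predictions unchanged", {
  feats <- sample_separable_features(50, seed = 6)
  m1 <- train_classifier(feats)
  m2 <- train_classifier(rbind(feats, feats))
  te <- sample_separable_features(100, seed = 7)
  te$label <- seq_len(nrow(te)); te$class <- "unclassified"
  expect_identical(classify_nuclei(te, m1)$class, classify_nuclei(te, m2)$class)
})

test_that("renaming classes permutes labels but not the partition", {
  feats <- sample_separable_features(50, seed = 8)
  ren <- c(human = "A", chicken_peripheral = "B", chicken_infiltrating = "C")
  feats2 <- feats; feats2$class <- unname(ren[feats$class])
  m1 <- train_classifier(feats); m2 <- train_classifier(feats2)
  te <- sample_separable_features(100, seed = 9)
  te$label <- seq_len(nrow(te)); te$class <- "unclassified"
  p1 <- classify_nuclei(te, m1)$class
  p2 <- classify_nuclei(te, m2)$class
  expect_identical(unname(ren[p1]), p2)
})

test_that("a record at a class centroid scores highest for that class", {
  # hand-built 2-class model with printed weights: argmax checked by hand
  model <- structure(list(
    version = 1L, classes = c("big", "small"),
    features = c("area", "eccentricity", "k3_density"),
    center = c(0, 0, 0), scale = c(1, 1, 1),
    weights = rbind(c(1, 0, 0), c(-1, 0, 0)),
    intercepts = c(0, 0), fingerprint = "manual"),
    class = "nucleus_classifier")
  rec <- data.frame(label = 1:2, area = c(2, -3), eccentricity = 0, k3_density = 1,
                    class = "unclassified")
  got <- classify_nuclei(rec, model)
  # scores: big = area, small = -area
  expect_identical(got$class, c("big", "small"))
})

test_that("classification is deterministic and preserves empty input", {
  model <- default_classifier()
  te <- sample_separable_features(30, seed = 10)
  te$label <- seq_len(nrow(te)); te$class <- "unclassified"
  expect_identical(classify_nuclei(te, model)$class, classify_nuclei(te, model)$class)
  empty <- te[0, ]
  expect_equal(nrow(classify_nuclei(empty, model)), 0)
})

test_that("missing k-3 density falls back to remaining features with a warning", {
  model <- default_classifier()
  rec <- data.frame(label = 1:2, area = c(120, 35), eccentricity = c(0.3, 0.85),
                    k3_density = NA_real_, class = "unclassified")
  expect_warning(got <- classify_nuclei(rec, model), "k-3")
  # area/eccentricity still separate human from chicken; with the density
  # feature imputed the chicken sub-class is whichever scores higher
  expect_identical(got$class[1], "human")
  expect_match(got$class[2], "^chicken")
})

test_that("model serialization round-trips to identical predictions", {
  model <- train_classifier(sample_separable_features(40, seed = 11))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  te <- sample_separable_features(120, seed = 12)
  te$label <- seq_len(nrow(te)); te$class <- "unclassified"
  expect_identical(classify_nuclei(te, model)$class, classify_nuclei(te, back)$class)
  expect_equal(back$weights, model$weights)
  expect_equal(back$fingerprint, model$fingerprint)
})

test_that("CAM exclusion partitions without deleting records", {
  recs <- data.frame(label = 1:17,
                     class = c(rep("human", 10), rep("chicken_peripheral", 5),
                               rep("chicken_infiltrating", 2)))
  parts <- exclude_cam(recs)
  expect_equal(nrow(parts$human_analysis), 12)
  expect_equal(nrow(parts$excluded), 5)
  expect_false(any(parts$human_analysis$class == "chicken_peripheral"))
  expect_equal(sort(c(parts$human_analysis$label, parts$excluded$label)), 1:17)
  # degenerate compositions
  allh <- data.frame(label = 1:3, class = "human")
  expect_equal(nrow(exclude_cam(allh)$excluded), 0)
  allc <- data.frame(label = 1:3, class = "chicken_peripheral")
  expect_equal(nrow(exclude_cam(allc)$human_analysis), 0)
})

test_that("scene-level classification recovers the true tissue classes", {
  out <- generate_scene(scene_params(noise_sd = 0, seed = 14))
  lab <- segment_nuclei(out$scene)
  recs <- classify_nuclei(compute_features(lab), default_classifier())
  tr <- out$truth$nuclei
  nn <- apply(cbind(recs$centroid_row, recs$centroid_col), 1, function(z)
    which.min((tr$row - z[1])^2 + (tr$col - z[2])^2))
  expect_gte(mean(recs$class == tr$class[nn]), 0.95)
})
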