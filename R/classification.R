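# Morphometric nucleus classification: area, eccentricity and k-3 neighbour
# density feed a linear (LDA-form) classifier separating human nuclei from
# peripheral (CAM) and infiltrating chicken nuclei. The fitted rule is a set
# of affine scores over z-scored features, serialized to versioned JSON.

CLASS_LEVELS <- c("human", "chicken_peripheral", "chicken_infiltrating")
CLASSIFIER_FEATURES <- c("area", "eccentricity", "k3_density")

#' Compute per-nucleus features from a label map
#'
#' For every label: pixel-count area, moment eccentricity (eccentricity of the
#' ellipse with identical second central moments; 0 = circle), centroid, and
#' k-3 density — the mean Euclidean centroid distance to the 3 nearest other
#' nuclei. With fewer than 4 nuclei the k-3 density is `NA` (flagged, not
#' fabricated). Tied neighbour distances are resolved in ascending
#' (distance, label) order.
#'
#' @param label_map integer label matrix.
#' @return data.frame: label, centroid_row, centroid_col, area, eccentricity,
#'   k3_density, class (= "unclassified").
#' @export
compute_features <- function(label_map) {
  n <- max(label_map)
  if (n < 1L) stop("label map contains no nuclei", call. = FALSE)
  pos <- label_map > 0L
  l <- label_map[pos]
  rr <- row(label_map)[pos]
  cc <- col(label_map)[pos]
  area <- tabulate(l, nbins = n)
  cr <- as.numeric(rowsum(rr, l)) / area
  ccol <- as.numeric(rowsum(cc, l)) / area
  # central second moments per label
  dr <- rr - cr[l]; dc <- cc - ccol[l]
  mu20 <- as.numeric(rowsum(dr * dr, l)) / area
  mu02 <- as.numeric(rowsum(dc * dc, l)) / area
  mu11 <- as.numeric(rowsum(dr * dc, l)) / area
  tr <- mu20 + mu02
  det_part <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det_part) / 2
  l2 <- (tr - det_part) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0)), 0)
  k3 <- k3_density(cr, ccol)
  data.frame(label = seq_len(n), centroid_row = cr, centroid_col = ccol,
             area = as.numeric(area), eccentricity = ecc, k3_density = k3,
             class = "unclassified")
}

#' Mean distance to the 3 nearest neighbours
#'
#' @param r,c centroid coordinates.
#' @return numeric vector (NA when fewer than 4 points exist).
#' @keywords internal
k3_density <- function(r, c) {
  n <- length(r)
  if (n < 4L) return(rep(NA_real_, n))
  D <- as.matrix(stats::dist(cbind(r, c)))
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    idx <- order(d, seq_along(d))[1:3]   # ascending (distance, label) order
    mean(d[idx])
  }, numeric(1))
}

#' Train the linear nucleus classifier
#'
#' Features are z-scored and a linear discriminant (pooled-covariance LDA) is
#' fitted; the decision rule is the argmax of one affine score per class, and
#' those weights are what gets stored, so a serialized model reproduces the
#' fit's predictions exactly. Training is deterministic; `seed` is accepted
#' for interface stability with stochastic estimators.
#'
#' @param features data.frame with columns area, eccentricity, k3_density and
#'   class; needs >= 2 classes and >= 10 examples per class.
#' @param seed unused by the deterministic LDA fit; kept in the signature.
#' @return a `nucleus_classifier` object.
#' @export
train_classifier <- function(features, seed = 1) {
  stopifnot(all(c(CLASSIFIER_FEATURES, "class") %in% names(features)))
  X <- as.matrix(features[, CLASSIFIER_FEATURES])
  if (any(!is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)[1]
    stop(sprintf("non-finite features in training record %d", bad), call. = FALSE)
  }
  cls <- as.character(features$class)
  tab <- table(cls)
  if (length(tab) < 2) stop("training data must contain at least 2 classes", call. = FALSE)
  if (any(tab < 10)) stop("each class needs at least 10 training examples", call. = FALSE)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  if (any(scale_ <= 0)) stop("constant feature in training data", call. = FALSE)
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  fit <- MASS::lda(Z, grouping = factor(cls))
  # affine scores: inv(Sigma) = scaling %*% t(scaling) for the sphering matrix
  Sinv <- fit$scaling %*% t(fit$scaling)
  mu <- fit$means
  W <- mu %*% Sinv                                   # one weight row per class
  b <- -0.5 * rowSums((mu %*% Sinv) * mu) + log(fit$prior)
  model <- structure(list(
    version = 1L,
    classes = rownames(mu),
    features = CLASSIFIER_FEATURES,
    center = as.numeric(center), scale = as.numeric(scale_),
    weights = unname(W), intercepts = unname(as.numeric(b)),
    fingerprint = feature_fingerprint(features)),
    class = "nucleus_classifier")
  model
}

# md5 of the training table (canonical CSV rendering)
feature_fingerprint <- function(features) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  df <- features[, c(CLASSIFIER_FEATURES, "class")]
  utils::write.csv(format(df, digits = 12), tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

# affine class scores for a feature matrix
classifier_scores <- function(model, X) {
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  S <- Z %*% t(model$weights)
  sweep(S, 2, model$intercepts, "+")
}

#' Classify nucleus records
#'
#' Assigns each record the class with the highest affine score. Records with a
#' missing k-3 density (scenes with < 4 nuclei) are scored from the remaining
#' features — the missing feature is set to the training mean — with a warning.
#'
#' @param records data.frame from [compute_features()].
#' @param model a `nucleus_classifier`.
#' @return `records` with the `class` column filled in.
#' @export
classify_nuclei <- function(records, model) {
  stopifnot(inherits(model, "nucleus_classifier"))
  if (nrow(records) == 0) return(records)
  stopifnot(all(model$features %in% names(records)))
  X <- as.matrix(records[, model$features])
  if (anyNA(X[, "k3_density"])) {
    warning("k-3 density missing for some records; classifying from remaining features")
    X[is.na(X[, "k3_density"]), "k3_density"] <- model$center[3]
  }
  S <- classifier_scores(model, X)
  records$class <- model$classes[max.col(S, ties.method = "first")]
  records
}

#' Partition records for human-cell analysis
#'
#' CAM tissue at the section edge is excluded from all human-cell metrics.
#' The partition is a view — nothing is deleted: `human_analysis` holds every
#' record that is not peripheral chicken (infiltrating chicken stay in the
#' record set, flagged by their class, and are excluded again at metric
#' aggregation), `excluded` holds the peripheral-chicken records.
#'
#' @param records classified records.
#' @return list(human_analysis=, excluded=).
#' @export
exclude_cam <- function(records) {
  sel <- records$class == "chicken_peripheral"
  list(human_analysis = records[!sel, , drop = FALSE],
       excluded = records[sel, , drop = FALSE])
}

#' Serialize a classifier to JSON
#'
#' @param model a `nucleus_classifier`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "nucleus_classifier"))
  out <- unclass(model)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized classifier
#'
#' @param path JSON file from [write_model()].
#' @return a `nucleus_classifier` with predictions identical to the original.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- matrix(unlist(x$weights), nrow = length(x$classes), byrow = FALSE)
  if (is.list(x$weights)) x$weights <- do.call(rbind, x$weights)
  structure(x, class = "nucleus_classifier")
}

#' @export
print.nucleus_classifier <- function(x, ...) {
  cat(sprintf("nucleus_classifier (v%d): %s over (%s)\n", x$version,
              paste(x$classes, collapse = "/"), paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Train a classifier on labeled synthetic scenes
#'
#' Mirrors the study workflow of pretraining on curated images from the same
#' dataset: each training scene is generated, segmented, its features
#' computed, and every nucleus labeled with the class of the nearest
#' ground-truth nucleus; the pooled feature table is then fed to
#' [train_classifier()]. Use scenes drawn from the same conditions as the
#' scenes to be analysed.
#'
#' @param params_list one [scene_params()] or a list of them (vary the seeds).
#' @param seed forwarded to [train_classifier()].
#' @return a `nucleus_classifier`.
#' @export
train_classifier_on_scenes <- function(params_list, seed = 1) {
  if (inherits(params_list, "scene_params")) params_list <- list(params_list)
  feats <- do.call(rbind, lapply(params_list, function(p) {
    out <- generate_scene(p)
    lab <- segment_nuclei(out$scene)
    f <- compute_features(lab)
    tr <- out$truth$nuclei
    nn <- apply(cbind(f$centroid_row, f$centroid_col), 1, function(z)
      which.min((tr$row - z[1])^2 + (tr$col - z[2])^2))
    f$class <- tr$class[nn]
    f
  }))
  train_classifier(feats, seed)
}

.camquant_cache <- new.env(parent = emptyenv())

#' The packaged default classifier
#'
#' A reproducible default model: LDA trained at first use on
#' the synthetic separable preset ([sample_separable_features()], 200 per
#' class, seed 20). Cached per session.
#'
#' @return a `nucleus_classifier`.
#' @export
default_classifier <- function() {
  if (is.null(.camquant_cache$default_model)) {
    .camquant_cache$default_model <-
      train_classifier(sample_separable_features(200, seed = 20))
  }
  .camquant_cache$default_model
}
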