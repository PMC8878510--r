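# Shared fixture builders; everything is generated in code.

disk_mask <- function(H, W, cr, cc, r) {
  m <- matrix(FALSE, H, W)
  idx <- which((row(m) - cr)^2 + (col(m) - cc)^2 <= r^2)
  m[idx] <- TRUE
  m
}

rect_mask <- function(H, W, r0, c0, h, w) {
  m <- matrix(FALSE, H, W)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

# scene used by marker-recovery tests: noise-free, markers on human cells
recovery_params <- function(seed = 9, noise_sd = 0) {
  specs <- list(marker_spec("ACTA2", "human", 0.4, "elongated_fibre", 0.8),
                marker_spec("CD44", "human", 0.5, "cytoplasmic_ring", 0.7))
  scene_params(marker_specs = specs, noise_sd = noise_sd, seed = seed)
}

recovery_scene <- function(seed = 9, noise_sd = 0) {
  generate_scene(recovery_params(seed, noise_sd))
}

# classifier trained on scenes drawn from the same conditions (study-style
# pretraining on curated images from the dataset); memoised across tests
.helper_cache <- new.env(parent = emptyenv())
scene_trained_model <- function() {
  if (is.null(.helper_cache$model)) {
    .helper_cache$model <- train_classifier_on_scenes(
      lapply(c(100, 101), function(s) recovery_params(seed = s, noise_sd = 0.05)))
  }
  .helper_cache$model
}

# map ground-truth nucleus ids to segmentation labels via centroids
truth_labels <- function(truth, lab) {
  tr <- truth$nuclei
  lab[cbind(round(tr$row), round(tr$col))]
}

# small triplicate Cq table: target shifted by `shift` cycles in CAP vs UT
cq_fixture <- function(shift = -1, jitter = 0, seed = 1, n_samples = 3) {
  set.seed(seed)
  mk <- function(s, cond, g, base) data.frame(
    sample_id = s, condition = cond, gene = g, replicate = 1:3,
    cq = base + if (jitter > 0) stats::rnorm(3, 0, jitter) else 0)
  do.call(rbind, lapply(seq_len(n_samples), function(i) rbind(
    mk(paste0("UT", i), "UT", "TGT", 25),
    mk(paste0("UT", i), "UT", "HK1", 20),
    mk(paste0("UT", i), "UT", "HK2", 22),
    mk(paste0("CAP", i), "CAP", "TGT", 25 + shift),
    mk(paste0("CAP", i), "CAP", "HK1", 20),
    mk(paste0("CAP", i), "CAP", "HK2", 22))))
}
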