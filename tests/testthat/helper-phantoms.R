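# phantoms are expensive; build each named configuration once per test run
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(name, cfg) {
  if (!exists(name, envir = .phantom_cache))
    assign(name, make_phantom(cfg), envir = .phantom_cache)
  get(name, envir = .phantom_cache)
}

phantom_small <- function() {
  cached_phantom("small", phantom_config(
    width = 300L, height = 300L, n_fibers = 40L, n_interstitial = 10L,
    seed = 7L))
}

phantom_small_gaps <- function() {
  cached_phantom("small_gaps", phantom_config(
    width = 300L, height = 300L, n_fibers = 40L, n_interstitial = 10L,
    gap_fraction = 0.3, seed = 7L))
}

# ground-truth training labels for a segmented phantom, n per class
phantom_training <- function(rois, phantom, n_per_class = 25L, seed = 1L) {
  tc <- truth_roi_classes(rois, phantom)
  set.seed(seed)
  idx <- c(sample(which(tc$label == "myofiber"), n_per_class),
           sample(which(tc$label == "non_myofiber"), n_per_class))
  tc[idx, ]
}

# dimmest ground-truth-positive fiber per channel (seed-fiber selection)
phantom_seed_fibers <- function(rois, phantom) {
  nf <- phantom$truth$n_fibers
  gtid <- vapply(rois, function(r) {
    v <- phantom$truth$labels[r$coords]
    v <- v[v > 0 & v <= nf]
    if (!length(v)) NA_integer_ else
      as.integer(names(which.max(table(v))))
  }, 0L)
  ids <- vapply(rois, function(r) r$id, 0L)
  out <- list()
  for (ch in c("I", "IIa", "IIb")) {
    mfi <- measure_mfi(rois, phantom$channels$markers[[ch]])
    posf <- phantom$truth$fibers$id[phantom$truth$fibers[[paste0("pos_", ch)]]]
    cand <- which(gtid %in% posf)
    out[[ch]] <- ids[cand[which.min(mfi[cand])]]
  }
  out
}
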