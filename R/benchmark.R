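#' The default desk-scale synthetic benchmark
#'
#' A registered, fully synthetic end-to-end exercise of the pipeline at a
#' size a single CPU handles in minutes: a 24-subject cohort (140 windows
#' per subject) at moderate burst strength (3 dB, i.e. an FM window holds
#' about twice the in-band energy of a background window — hard enough
#' that a compact student does not saturate, leaving the teacher a
#' capacity margin), split
#' subject-independently, with the FM training minority expanded by virtual
#' rotation and the N-FM majority undersampled by the clustering selector
#' until both classes hold `target_per_class` segments (2 x 1000 balanced
#' training segments by default). Spectrogram normalization statistics are
#' fitted on the balanced training set only.
#'
#' @param seed master seed driving cohort generation, splitting,
#'   augmentation and undersampling.
#' @param n_subjects,segments_per_subject cohort geometry.
#' @param fm_prevalence fraction of windows carrying a dual-confirmed FM
#'   event.
#' @param fm_snr_db FM burst strength in dB (see [fm_cohort_config()]).
#' @param target_per_class balanced per-class training count.
#' @return list with `x_train`, `x_val`, `x_test` (spectrogram arrays with
#'   `labels` attributes), `stats` (the training-split `fm_norm_stats`) and
#'   `counts` (bookkeeping).
#' @export
fm_benchmark_data <- function(seed = 1L, n_subjects = 24L,
                              segments_per_subject = 140L,
                              fm_prevalence = 0.12, fm_snr_db = 3,
                              target_per_class = 1000L) {
  cfg <- fm_cohort_config(
    n_subjects = n_subjects,
    session_duration_s = (segments_per_subject + 0.5) * 5,
    fm_prevalence = fm_prevalence,
    fm_snr_db = fm_snr_db)
  seeds <- derive_seeds(seed, 4L)
  cohort <- generate_cohort(cfg, seeds[1])
  segs <- do.call(bind_segments, lapply(cohort, segment_and_label))
  rm(cohort)
  folds <- split_subject_independent(segs, split_spec(seed = seeds[2]))
  rm(segs)
  fm <- folds$train[folds$train$label == "FM"]
  nfm <- folds$train[folds$train$label == "N-FM"]
  if (length(fm) < 2L) stop("degenerate benchmark draw: too few FM segments")
  factor_ <- ceiling(target_per_class / length(fm))
  fm_aug <- augment_minority(fm, factor_, seed = seeds[3])
  # originals come first, so trimming to the target keeps every original
  fm_aug <- fm_aug[seq_len(min(target_per_class, length(fm_aug)))]
  n_nfm <- min(target_per_class, length(nfm))
  nfm_sel <- undersample_majority(nfm, n_nfm, seed = seeds[4])
  train_segs <- bind_segments(fm_aug, nfm_sel)
  x_train <- spectrogram_batch(train_segs)
  stats <- fit_global_stats(x_train)
  x_train <- (x_train - stats$global_mean) / stats$global_sd
  attr(x_train, "labels") <- train_segs$label
  x_val <- spectrogram_batch(folds$validation, stats)
  x_test <- spectrogram_batch(folds$test, stats)
  list(x_train = x_train, x_val = x_val, x_test = x_test, stats = stats,
       counts = list(train_fm = sum(train_segs$label == "FM"),
                     train_nfm = sum(train_segs$label == "N-FM"),
                     val = length(folds$validation),
                     test = length(folds$test)))
}

#' Registered training configuration for the desk-scale benchmark
#'
#' The fixed settings used whenever the benchmark is trained: Adam at
#' 1e-3, batch 64, dropout 0.2, up to 8 epochs with patience 2 (the
#' synthetic task plateaus within a handful of epochs and early stopping
#' ends runs at the validation-loss plateau), and the distillation
#' operating point T = 3, alpha = 0.5 with 3 repeat seeds.
#'
#' @return named list of training arguments.
#' @export
fm_benchmark_config <- function() {
  list(lr = 1e-3, batch_size = 64L, dropout = 0.2,
       max_epochs = 8L, patience = 2L,
       temperature = 3, alpha = 0.5, seeds = 1:3)
}
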