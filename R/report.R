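#' Augmentation / undersampling ratio sweep
#'
#' For every `(aug_factor, under_target)` configuration: expands the FM
#' minority by virtual rotation, undersamples the N-FM majority to the
#' balanced target, fits global spectrogram statistics on the balanced
#' training set, trains every model over the given seeds, and records the
#' validation F1 mean and SD. Re-running with the same `out_csv` manifest
#' skips configurations that already have rows (resumable).
#'
#' @param minority `fm_segments` of FM training segments.
#' @param majority `fm_segments` of N-FM training segments.
#' @param val_segments `fm_segments` of the untouched validation split.
#' @param factors list of `c(aug_factor, under_target)` pairs; an
#'   `under_target` equal to the majority count means no undersampling.
#' @param model_specs named list of `fm_model_spec`s (or family names).
#' @param seeds training seeds per configuration.
#' @param out_csv optional manifest CSV for persistence and resumption.
#' @param undersample_seed seed for the clustering-based undersampler.
#' @param ... passed to [fm_train()] (epochs, patience, lr, ...).
#' @return data.frame of class `fm_sweep`: one row per configuration and
#'   model with `aug_factor`, `under_target`, `model`, `F1_mean`, `F1_sd`,
#'   `n_seeds`.
#' @export
ratio_sweep <- function(minority, majority, val_segments, factors,
                        model_specs, seeds = 1:3, out_csv = NULL,
                        undersample_seed = 1L, ...) {
  done <- NULL
  if (!is.null(out_csv) && file.exists(out_csv))
    done <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
  if (is.null(names(model_specs)))
    names(model_specs) <- vapply(model_specs, function(s)
      if (is.character(s)) s else s$family, character(1))
  rows <- if (is.null(done)) list() else list(done)
  for (f in factors) {
    aug_factor <- f[[1]]
    under_target <- f[[2]]
    if (aug_factor < 1 || under_target > length(majority)) {
      message(sprintf("skipping infeasible configuration aug=%g target=%g",
                      aug_factor, under_target))
      next
    }
    todo <- names(model_specs)
    if (!is.null(done))
      todo <- setdiff(todo, done$model[done$aug_factor == aug_factor &
                                       done$under_target == under_target])
    if (!length(todo)) next
    fm_aug <- augment_minority(minority, aug_factor)
    nfm <- undersample_majority(majority, under_target,
                                seed = undersample_seed)
    train_segs <- bind_segments(fm_aug, nfm)
    x_train <- spectrogram_batch(train_segs)
    stats <- fit_global_stats(x_train)
    x_train <- (x_train - stats$global_mean) / stats$global_sd
    attr(x_train, "labels") <- train_segs$label
    x_val <- spectrogram_batch(val_segments, stats)
    for (mn in todo) {
      res <- fm_train_repeated(model_specs[[mn]], x_train,
                               train_segs$label, x_val,
                               val_segments$label, seeds = seeds, ...)
      row <- data.frame(aug_factor = aug_factor,
                        under_target = under_target, model = mn,
                        F1_mean = res$mean[["F1"]], F1_sd = res$sd[["F1"]],
                        n_seeds = length(seeds))
      rows[[length(rows) + 1L]] <- row
      if (!is.null(out_csv))
        utils::write.csv(do.call(rbind, rows), out_csv, row.names = FALSE)
    }
  }
  if (!length(rows)) return(invisible(NULL))
  out <- do.call(rbind, rows)
  class(out) <- c("fm_sweep", class(out))
  out
}

#' Pivoted report of a distillation grid
#'
#' Summarizes grid results by configuration and picks the best per student
#' by mean validation F1, breaking ties toward the smaller temperature and
#' then the smaller alpha.
#'
#' @param results data.frame of grid rows: optional `teacher` / `student`
#'   columns plus `temperature`, `alpha`, `F1_mean` (the `results` table of
#'   [grid_search()] qualifies).
#' @return list with `table` (results sorted by student and F1) and `best`
#'   (one row per student).
#' @export
kd_grid_report <- function(results) {
  df <- as.data.frame(results)
  if (!"student" %in% names(df)) df$student <- "student"
  if (!"teacher" %in% names(df)) df$teacher <- "teacher"
  ord <- order(df$student, -df$F1_mean, df$temperature, df$alpha)
  tab <- df[ord, ]
  best <- do.call(rbind, lapply(split(tab, tab$student), function(g) g[1, ]))
  rownames(best) <- NULL
  list(table = tab, best = best)
}

#' Performance / size / compute trade-off report
#'
#' Ranks models by F1 and flags the Pareto-efficient set over
#' (F1 maximized, parameter count minimized, MAC count minimized): a model
#' is dominated when another is at least as good on all three axes and
#' strictly better on at least one.
#'
#' @param results data.frame with columns `model`, `F1`, `params`, `macs`.
#' @return the same data.frame sorted by decreasing F1 with a logical
#'   `pareto` column.
#' @export
tradeoff_report <- function(results) {
  df <- as.data.frame(results)
  stopifnot(all(c("model", "F1", "params", "macs") %in% names(df)))
  n <- nrow(df)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      geq <- df$F1[j] >= df$F1[i] & df$params[j] <= df$params[i] &
        df$macs[j] <= df$macs[i]
      strict <- df$F1[j] > df$F1[i] | df$params[j] < df$params[i] |
        df$macs[j] < df$macs[i]
      geq && strict
    }, logical(1)))
  }, logical(1))
  df$pareto <- !dominated
  df[order(-df$F1), ]
}
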