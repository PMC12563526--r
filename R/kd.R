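#' Temperature-scaled softmax
#'
#' @param logits numeric vector of unnormalized scores.
#' @param T temperature, > 0; larger values smooth the distribution.
#' @return probability vector summing to 1.
#' @export
softmax_T <- function(logits, T = 1) {
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  z <- logits / T
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

row_log_softmax <- function(z) {
  m <- apply(z, 1, max)
  zc <- z - m
  zc - log(rowSums(exp(zc)))
}

#' Knowledge-distillation loss
#'
#' The distillation objective combines hard-label cross-entropy on the
#' student's ordinary (T = 1) output with the temperature-scaled
#' Kullback-Leibler divergence from the teacher's softened distribution to
#' the student's:
#' `(1 - alpha) * H(y, s(zs)) + alpha * T^2 * KL(s(zt, T) || s(zs, T))`.
#' The `T^2` factor keeps the soft-target gradient magnitude comparable
#' across temperatures.
#'
#' @param student_logits,teacher_logits numeric vectors of class logits.
#' @param label true class index (1-based) or a factor level among the
#'   class labels.
#' @param T distillation temperature, > 0.
#' @param alpha soft-target weight in `[0, 1]`; `alpha = 0` reduces to
#'   plain cross-entropy.
#' @return non-negative scalar loss.
#' @export
kd_loss <- function(student_logits, teacher_logits, label, T = 3,
                    alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  y <- if (is.numeric(label)) as.integer(label)
       else match(as.character(label), class_levels(length(student_logits)))
  ls <- log(softmax_T(student_logits, 1))
  ce <- -ls[y]
  kl <- 0
  if (alpha > 0 && !is.null(teacher_logits)) {
    pt <- softmax_T(teacher_logits, T)
    lst <- log(softmax_T(student_logits, T))
    kl <- sum(pt * (log(pt) - lst))
  }
  (1 - alpha) * ce + alpha * T^2 * kl
}

#' @rdname kd_loss
#' @return `kd_loss_grad` returns the analytic gradient of the loss with
#'   respect to the student logits.
#' @export
kd_loss_grad <- function(student_logits, teacher_logits, label, T = 3,
                         alpha = 0.5) {
  y <- if (is.numeric(label)) as.integer(label)
       else match(as.character(label), class_levels(length(student_logits)))
  ps <- softmax_T(student_logits, 1)
  onehot <- numeric(length(student_logits))
  onehot[y] <- 1
  g <- (1 - alpha) * (ps - onehot)
  if (alpha > 0 && !is.null(teacher_logits)) {
    pt <- softmax_T(teacher_logits, T)
    psT <- softmax_T(student_logits, T)
    g <- g + alpha * T * (psT - pt)
  }
  g
}

# batched loss + gradient; zs [N,K], zt [N,K] or NULL, y integer vector
kd_loss_batch <- function(zs, zt, y, T, alpha) {
  n <- nrow(zs)
  ls <- row_log_softmax(zs)
  ce <- -ls[cbind(seq_len(n), y)]
  ps <- exp(ls)
  onehot <- matrix(0, n, ncol(zs))
  onehot[cbind(seq_len(n), y)] <- 1
  grad <- (1 - alpha) * (ps - onehot)
  loss <- (1 - alpha) * mean(ce)
  if (alpha > 0 && !is.null(zt)) {
    lpt <- row_log_softmax(zt / T)
    lps <- row_log_softmax(zs / T)
    pt <- exp(lpt)
    kl <- rowSums(pt * (lpt - lps))
    loss <- loss + alpha * T^2 * mean(kl)
    grad <- grad + alpha * T * (exp(lps) - pt)
  }
  list(loss = loss, grad = grad / n)
}

model_logits <- function(object, x, batch_size = 256L) {
  layers <- if (inherits(object, "fm_fit")) object$model$layers
            else object$layers
  forward_batched(layers, x, batch_size)
}

#' Train a classifier, optionally with knowledge distillation
#'
#' Adam optimization of the distillation objective ([kd_loss()]) when a
#' frozen teacher is supplied, or plain cross-entropy otherwise. Training
#' stops when the validation loss has not improved for `patience` epochs
#' (or at `max_epochs`) and the best-validation-loss weights are restored.
#'
#' @param model an `fm_model`, `fm_model_spec`, or family name; specs are
#'   built under `seed`.
#' @param x,y training spectrogram array (`n x bins x frames x channels`)
#'   and labels (factor with levels FM / N-FM, or such a factor attached to
#'   `x` as the `labels` attribute by [spectrogram_batch()]).
#' @param x_val,y_val validation split, same conventions.
#' @param teacher optional frozen teacher: an `fm_model` / `fm_fit`, or a
#'   precomputed list with logit matrices `train` and `val`.
#' @param temperature,alpha distillation parameters (ignored without a
#'   teacher).
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @param max_epochs,patience early-stopping configuration; `patience = 0`
#'   stops one epoch after the first non-improvement.
#' @param seed seed controlling initialization, batch order and dropout.
#' @param verbose print per-epoch progress.
#' @return an object of class `fm_fit`: the trained model, per-epoch
#'   `history` (train/validation loss, validation F1), `best_epoch`,
#'   validation metrics at the restored weights, and the configuration.
#' @export
fm_train <- function(model, x, y = attr(x, "labels"),
                     x_val, y_val = attr(x_val, "labels"),
                     teacher = NULL, temperature = 3, alpha = 0.5,
                     lr = 1e-3, batch_size = 32L, max_epochs = 300L,
                     patience = 30L, seed = 1L, verbose = FALSE) {
  if (!inherits(model, "fm_model")) model <- build_model(model, seed = seed)
  lv <- class_levels(model$spec$n_classes)
  yi <- match(as.character(y), lv)
  yvi <- match(as.character(y_val), lv)
  stopifnot(!anyNA(yi), !anyNA(yvi), dim(x)[1] == length(yi))

  zt <- zt_val <- NULL
  if (!is.null(teacher)) {
    if (is.list(teacher) && !inherits(teacher, c("fm_model", "fm_fit"))) {
      zt <- teacher$train; zt_val <- teacher$val
    } else {
      zt <- model_logits(teacher, x)
      zt_val <- model_logits(teacher, x_val)
    }
  }

  layers <- model$layers
  theta <- nn_get_params(layers)
  st <- adam_init(length(theta))
  n <- dim(x)[1]
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  bad <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_f1 = numeric(0))

  val_eval <- function(layers) {
    zl <- forward_batched(layers, x_val)
    l <- kd_loss_batch(zl, zt_val, yvi,
                       if (is.null(zt_val)) 1 else temperature,
                       if (is.null(zt_val)) 0 else alpha)$loss
    pred <- max.col(zl, ties.method = "first")
    m <- fm_metrics(confusion_counts(factor(lv[pred], levels = lv),
                                     factor(lv[yvi], levels = lv)))
    list(loss = l, f1 = m$F1)
  }

  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(n)
      tot <- 0
      for (s0 in seq(1L, n, by = batch_size)) {
        idx <- perm[s0:min(n, s0 + batch_size - 1L)]
        xb <- x[idx, , , , drop = FALSE]
        fw <- nn_forward(layers, xb, train = TRUE)
        lb <- kd_loss_batch(fw$out, if (is.null(zt)) NULL
                            else zt[idx, , drop = FALSE],
                            yi[idx],
                            if (is.null(zt)) 1 else temperature,
                            if (is.null(zt)) 0 else alpha)
        if (!is.finite(lb$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        bw <- nn_backward(layers, fw$caches, lb$grad)
        g <- nn_grad_vector(bw$grads, layers)
        up <- adam_step(theta, g, st, lr)
        theta <- up$theta
        st <- up$state
        layers <- nn_set_params(layers, theta)
        tot <- tot + lb$loss * length(idx)
      }
      ve <- val_eval(layers)
      hist[nrow(hist) + 1L, ] <- list(epoch, tot / n, ve$loss, ve$f1)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val F1 %.2f%%",
                        epoch, tot / n, ve$loss, ve$f1))
      if (ve$loss < best$loss) {
        best <- list(loss = ve$loss, theta = theta, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > patience) break
      }
    }
  })

  layers <- nn_set_params(layers, best$theta)
  model$layers <- layers
  zl <- forward_batched(layers, x_val)
  pred <- factor(lv[max.col(zl, ties.method = "first")], levels = lv)
  vm <- fm_metrics(confusion_counts(pred, factor(lv[yvi], levels = lv)))
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 val_metrics = vm,
                 config = list(temperature = temperature, alpha = alpha,
                               lr = lr, batch_size = batch_size,
                               max_epochs = max_epochs, patience = patience,
                               distilled = !is.null(teacher)),
                 seed = seed),
            class = "fm_fit")
}

#' @export
print.fm_fit <- function(x, ...) {
  cat(sprintf("<fm_fit> %s%s: best epoch %d/%d, val F1 %.2f%%\n",
              x$model$spec$family,
              if (x$config$distilled)
                sprintf(" (KD, T=%g, alpha=%g)", x$config$temperature,
                        x$config$alpha) else "",
              x$best_epoch, nrow(x$history), x$val_metrics$F1))
  invisible(x)
}

#' @export
summary.fm_fit <- function(object, ...) {
  cat(sprintf("Family        : %s\n", object$model$spec$family))
  cat(sprintf("Parameters    : %.2f M\n", object$model$n_params / 1e6))
  cat(sprintf("Distilled     : %s\n",
              if (object$config$distilled)
                sprintf("yes (T=%g, alpha=%g)", object$config$temperature,
                        object$config$alpha) else "no"))
  cat(sprintf("Epochs run    : %d (best %d, patience %d)\n",
              nrow(object$history), object$best_epoch,
              object$config$patience))
  m <- object$val_metrics
  cat(sprintf("Validation    : SEN %.2f%%  PRE %.2f%%  F1 %.2f%%\n",
              m$SEN, m$PRE, m$F1))
  invisible(object)
}

#' @export
predict.fm_fit <- function(object, newdata, ...)
  predict(object$model, newdata, ...)

#' @export
plot.fm_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Repeat training over seeds and aggregate metrics
#'
#' Trains the same configuration under each seed and reports per-seed
#' validation (or test) sensitivity, precision and F1 with their mean and
#' standard deviation.
#'
#' @inheritParams fm_train
#' @param spec an `fm_model_spec` or family name rebuilt for every seed.
#' @param seeds integer vector of seeds.
#' @param x_eval,y_eval optional extra evaluation split (e.g. test); when
#'   given, reported metrics come from it instead of the validation split.
#' @param eval_split name recorded for the reported split.
#' @param ... passed to [fm_train()].
#' @return object of class `fm_train_result`: data.frame `per_seed`, named
#'   numeric `mean` and `sd`, `best_epochs`, `fits` (list of `fm_fit`),
#'   `split`.
#' @export
fm_train_repeated <- function(spec, x, y = attr(x, "labels"),
                              x_val, y_val = attr(x_val, "labels"),
                              seeds = 1:5, x_eval = NULL,
                              y_eval = if (!is.null(x_eval))
                                attr(x_eval, "labels") else NULL,
                              eval_split = if (is.null(x_eval)) "validation"
                                           else "test", ...) {
  rows <- list()
  fits <- list()
  for (i in seq_along(seeds)) {
    fit <- fm_train(spec, x, y, x_val, y_val, seed = seeds[i], ...)
    m <- if (is.null(x_eval)) fit$val_metrics
         else fm_metrics(confusion_counts(predict(fit, x_eval), y_eval))
    rows[[i]] <- data.frame(seed = seeds[i], SEN = m$SEN, PRE = m$PRE,
                            F1 = m$F1, best_epoch = fit$best_epoch)
    fits[[i]] <- fit
  }
  per_seed <- do.call(rbind, rows)
  agg <- function(f) vapply(per_seed[, c("SEN", "PRE", "F1")], f, numeric(1))
  structure(list(per_seed = per_seed,
                 mean = agg(function(v) mean(v, na.rm = TRUE)),
                 sd = agg(function(v) stats::sd(v, na.rm = TRUE)),
                 best_epochs = per_seed$best_epoch,
                 fits = fits, split = eval_split),
            class = "fm_train_result")
}

#' @export
print.fm_train_result <- function(x, ...) {
  cat(sprintf("<fm_train_result> %d seeds on %s split\n",
              nrow(x$per_seed), x$split))
  for (m in c("SEN", "PRE", "F1"))
    cat(sprintf("  %s: %.2f +/- %.2f %%\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Enumerates the full Cartesian grid, trains every configuration with
#' [fm_train_repeated()] and selects the configuration with the highest
#' mean validation F1 (ties broken by smaller temperature, then smaller
#' alpha).
#'
#' @param spec model spec or family name; the dropout column of the grid
#'   overrides the model spec's rate.
#' @param x,y,x_val,y_val training and validation data as in [fm_train()].
#' @param grid named list of parameter vectors among `temperature`,
#'   `alpha`, `lr`, `batch_size`, `dropout`. Missing entries use the
#'   defaults of [fm_train()].
#' @param teacher optional teacher (enables the KD term).
#' @param seeds seeds per configuration.
#' @param out_csv optional path: the per-configuration results are
#'   persisted as CSV (one row per configuration) for later reporting.
#' @param ... passed to [fm_train()] (e.g. `max_epochs`, `patience`).
#' @return list of class `fm_grid`: `results` (one row per configuration
#'   with mean/sd F1), `best_config`, `best_result`.
#' @export
grid_search <- function(spec, x, y = attr(x, "labels"),
                        x_val, y_val = attr(x_val, "labels"),
                        grid = list(), teacher = NULL, seeds = 1:5,
                        out_csv = NULL, ...) {
  if (is.character(spec)) spec <- fm_model_spec(spec)
  defaults <- list(temperature = 3, alpha = 0.5, lr = 1e-3,
                   batch_size = 32L, dropout = spec$dropout)
  for (nm in names(grid))
    if (!nm %in% names(defaults)) stop("unknown grid dimension: ", nm)
  full <- utils::modifyList(defaults, as.list(grid))
  combos <- expand.grid(full, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  results <- list()
  for (i in seq_len(nrow(combos))) {
    cf <- combos[i, ]
    sp <- spec
    sp$dropout <- cf$dropout
    res <- fm_train_repeated(sp, x, y, x_val, y_val, seeds = seeds,
                             teacher = teacher,
                             temperature = cf$temperature, alpha = cf$alpha,
                             lr = cf$lr, batch_size = cf$batch_size, ...)
    rows[[i]] <- cbind(cf, F1_mean = res$mean[["F1"]],
                       F1_sd = res$sd[["F1"]], n_seeds = length(seeds))
    results[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$F1_mean, tab$temperature, tab$alpha)
  best <- ord[1]
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  structure(list(results = tab, best_config = as.list(combos[best, ]),
                 best_result = results[[best]]),
            class = "fm_grid")
}

#' @export
print.fm_grid <- function(x, ...) {
  cat(sprintf("<fm_grid> %d configurations; best F1 %.2f%% at T=%g, alpha=%g, lr=%g, batch=%d, dropout=%g\n",
              nrow(x$results), max(x$results$F1_mean),
              x$best_config$temperature, x$best_config$alpha,
              x$best_config$lr, x$best_config$batch_size,
              x$best_config$dropout))
  invisible(x)
}

#' @importFrom graphics matplot abline legend
NULL
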