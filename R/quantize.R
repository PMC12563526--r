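# INT8 post-training quantization, emulated in software (fake
# quantization): weights are stored as 8-bit integers with per-output-
# channel symmetric scales (zero point 0), biases as 8-bit integers with a
# per-tensor scale, and every activation tensor is quantized/dequantized at
# each layer boundary with a per-tensor asymmetric scale and zero point
# calibrated from training data. Rounding is round-half-to-even with a
# symmetric clamp to [-127, 127].

q_clamp <- function(q, lo = -127, hi = 127) pmin(pmax(q, lo), hi)

quantize_weight_cols <- function(w, floor_scale = 1e-12) {
  scales <- pmax(apply(abs(w), 2, max) / 127, floor_scale)
  q <- q_clamp(round(sweep(w, 2, scales, "/")))
  list(q = q, scales = scales, deq = sweep(q, 2, scales, "*"))
}

quantize_tensor <- function(v, floor_scale = 1e-12) {
  s <- max(max(abs(v)) / 127, floor_scale)
  q <- q_clamp(round(v / s))
  list(q = q, scale = s, deq = q * s)
}

# asymmetric per-tensor fake quantization of activations; the range always
# includes zero so padding/ReLU zeros are exactly representable
fake_quant_act <- function(x, rng) {
  lo <- min(rng[1], 0); hi <- max(rng[2], 0)
  scale <- (hi - lo) / 255
  if (scale <= 0) return(x * 0)
  zp <- round(-128 - lo / scale)
  q <- q_clamp(round(x / scale) + zp, -128, 127)
  (q - zp) * scale
}

quantize_layers <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "dwconv", "dense")) {
      qw <- quantize_weight_cols(l$w)
      qb <- quantize_tensor(l$b)
      l$qw <- qw$q; l$w_scales <- qw$scales; l$w <- qw$deq
      l$qb <- qb$q; l$b_scale <- qb$scale; l$b <- qb$deq
    } else if (l$type == "res") {
      l$body <- quantize_layers(l$body)
    } else if (l$type == "cat") {
      l$branches <- lapply(l$branches, quantize_layers)
    }
    layers[[i]] <- l
  }
  layers
}

# forward pass recording per-path activation ranges into `env`
forward_collect <- function(layers, x, env, prefix = "") {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    path <- paste0(prefix, i)
    if (l$type == "res") {
      x <- x + forward_collect(l$body, x, env, paste0(path, "b."))
    } else if (l$type == "cat") {
      outs <- lapply(seq_along(l$branches), function(bi)
        forward_collect(l$branches[[bi]], x, env,
                        paste0(path, "b", bi, ".")))
      dm <- dim(outs[[1]])
      tot <- sum(vapply(outs, function(o) dim(o)[4], numeric(1)))
      xx <- array(0, c(dm[1:3], tot)); at <- 0L
      for (o in outs) {
        cc <- dim(o)[4]
        xx[, , , at + seq_len(cc)] <- o
        at <- at + cc
      }
      x <- xx
    } else {
      x <- layer_forward(l, x, train = FALSE)$out
    }
    old <- env$ranges[[path]] %||% c(Inf, -Inf)
    env$ranges[[path]] <- c(min(old[1], min(x)), max(old[2], max(x)))
  }
  x
}

# forward pass with fake quantization at every layer boundary
nn_forward_q <- function(layers, x, fq, prefix = "") {
  if (prefix == "") x <- fake_quant_act(x, fq$input)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    path <- paste0(prefix, i)
    if (l$type == "res") {
      x <- x + nn_forward_q(l$body, x, fq, paste0(path, "b."))
    } else if (l$type == "cat") {
      outs <- lapply(seq_along(l$branches), function(bi)
        nn_forward_q(l$branches[[bi]], x, fq, paste0(path, "b", bi, ".")))
      dm <- dim(outs[[1]])
      tot <- sum(vapply(outs, function(o) dim(o)[4], numeric(1)))
      xx <- array(0, c(dm[1:3], tot)); at <- 0L
      for (o in outs) {
        cc <- dim(o)[4]
        xx[, , , at + seq_len(cc)] <- o
        at <- at + cc
      }
      x <- xx
    } else {
      x <- layer_forward(l, x, train = FALSE)$out
    }
    x <- fake_quant_act(x, fq$ranges[[path]])
  }
  x
}

#' Calibrate and quantize a trained model to INT8
#'
#' Weight scales are `max(|w|) / 127` per output channel (symmetric, zero
#' point 0); biases use a per-tensor scale; activation ranges are the
#' min/max observed over calibration batches per tensor. Inference is
#' emulated by quantize / integer-affine / dequantize at every layer
#' boundary, so the quantized forward pass is bit-reproducible given the
#' calibration set.
#'
#' @param fit a trained `fm_fit` (or an `fm_model`).
#' @param calibration_x spectrogram array drawn from the training split.
#' @param n_batches,batch_size number and size of calibration batches used
#'   to observe activation ranges.
#' @return object of class `fm_quantized_model`.
#' @export
calibrate_and_quantize <- function(fit, calibration_x, n_batches = 8L,
                                   batch_size = 32L) {
  model <- if (inherits(fit, "fm_fit")) fit$model else fit
  stopifnot(inherits(model, "fm_model"))
  n <- dim(calibration_x)[1]
  if (is.null(n) || n < 1L) stop("empty calibration set", call. = FALSE)
  env <- new.env()
  env$ranges <- list()
  input_rng <- c(Inf, -Inf)
  used <- 0L
  for (bi in seq_len(n_batches)) {
    if (used >= n) break
    idx <- (used + 1L):min(n, used + batch_size)
    used <- used + length(idx)
    xb <- calibration_x[idx, , , , drop = FALSE]
    input_rng <- c(min(input_rng[1], min(xb)), max(input_rng[2], max(xb)))
    forward_collect(model$layers, xb, env)
  }
  qlayers <- quantize_layers(model$layers)
  structure(list(layers = qlayers, spec = model$spec,
                 n_params = model$n_params, macs = model$macs,
                 act_ranges = env$ranges, input_range = input_rng,
                 calibration_n = used),
            class = "fm_quantized_model")
}

#' @export
print.fm_quantized_model <- function(x, ...) {
  cat(sprintf("<fm_quantized_model> %s: %.2f M parameters, int8 payload %.2f MB (float32 %.2f MB)\n",
              x$spec$family, x$n_params / 1e6,
              model_size_bytes(x, "int8") / 2^20,
              model_size_bytes(x, "float32") / 2^20))
  invisible(x)
}

#' @export
predict.fm_quantized_model <- function(object, newdata,
                                       type = c("class", "prob", "logits"),
                                       batch_size = 256L, ...) {
  type <- match.arg(type)
  fq <- list(ranges = object$act_ranges, input = object$input_range)
  logits <- forward_batched(object$layers, newdata, batch_size, fq = fq)
  finish_prediction(logits, type, object$spec$n_classes)
}

# walk layers accumulating (n_weights, n_scale_channels, n_tensors)
payload_counts <- function(layers) {
  acc <- c(weights = 0, channels = 0, tensors = 0)
  for (l in layers) {
    if (l$type %in% c("conv", "dwconv", "dense")) {
      acc <- acc + c(length(l$w) + length(l$b), ncol(l$w), 2)
    } else if (l$type == "res") {
      acc <- acc + payload_counts(l$body)
    } else if (l$type == "cat") {
      for (br in l$branches) acc <- acc + payload_counts(br)
    }
  }
  acc
}

#' Parameter payload size in bytes
#'
#' `float32`: 4 bytes per parameter. `int8`: 1 byte per parameter plus
#' 4 bytes for every quantization scale (one per output channel for weight
#' tensors, one per bias tensor). Sizes in MB use the binary convention
#' (1 MB = 2^20 bytes).
#'
#' @param model an `fm_model` or `fm_quantized_model`.
#' @param precision `"float32"` or `"int8"`.
#' @return payload size in bytes, with the size in MB (2 decimals) as
#'   attribute `mb`.
#' @export
model_size_bytes <- function(model, precision = c("float32", "int8")) {
  precision <- match.arg(precision)
  pc <- payload_counts(model$layers)
  bytes <- if (precision == "float32") 4 * pc[["weights"]]
           else pc[["weights"]] + 4 * (pc[["channels"]] + pc[["tensors"]] / 2)
  structure(bytes, mb = round(bytes / 2^20, 2))
}

#' Paired float/INT8 performance report
#'
#' Evaluates the float and quantized models on the identical test set and
#' reports sensitivity, precision and F1 side by side with the
#' percentage-point deltas (`float - quantized`, sign preserved).
#'
#' @param fit trained float model (`fm_fit` or `fm_model`).
#' @param qmodel the corresponding `fm_quantized_model`.
#' @param x,y evaluation spectrograms and labels.
#' @return data.frame with columns `metric`, `float`, `quantized`,
#'   `delta_pp`.
#' @export
quantized_performance_report <- function(fit, qmodel, x,
                                         y = attr(x, "labels")) {
  mf <- fm_metrics(confusion_counts(predict(fit, x), y))
  mq <- fm_metrics(confusion_counts(predict(qmodel, x), y))
  data.frame(metric = c("SEN", "PRE", "F1"),
             float = c(mf$SEN, mf$PRE, mf$F1),
             quantized = c(mq$SEN, mq$PRE, mq$F1),
             delta_pp = c(mf$SEN - mq$SEN, mf$PRE - mq$PRE, mf$F1 - mq$F1))
}

#' Device power profile
#'
#' Duty-cycled operation of the wearable: a long low-power acquisition
#' phase at the idle draw followed by a short inference burst at the peak
#' draw, on a single-cell lithium-polymer supply.
#'
#' @param idle_power_mw idle (acquisition) power in mW.
#' @param peak_power_mw peak (inference) power in mW.
#' @param acquisition_s acquisition phase duration in seconds.
#' @param inference_s inference phase duration in seconds; must be shorter
#'   than the acquisition phase.
#' @param voltage_v battery voltage in volts.
#' @return object of class `fm_power_profile`.
#' @export
fm_power_profile <- function(idle_power_mw = 135, peak_power_mw = 179.8,
                             acquisition_s = 5.0, inference_s = 0.63,
                             voltage_v = 3.7) {
  for (nm in c("idle_power_mw", "peak_power_mw", "acquisition_s",
               "voltage_v"))
    stopifnot_scalar_pos(get(nm), nm)
  if (inference_s < 0) stop("inference_s must be non-negative", call. = FALSE)
  if (inference_s >= acquisition_s)
    stop("inference_s must be shorter than acquisition_s", call. = FALSE)
  structure(list(idle_power_mw = idle_power_mw,
                 peak_power_mw = peak_power_mw,
                 acquisition_s = acquisition_s, inference_s = inference_s,
                 voltage_v = voltage_v), class = "fm_power_profile")
}

#' Battery-life estimate under duty-cycled inference
#'
#' The duty-cycle average power is
#' `(idle * acquisition_s + peak * inference_s) / (acquisition_s +
#' inference_s)`; dividing by the battery voltage gives the average current
#' draw, and the runtime is `derate * capacity / current`. Linear in
#' capacity and derate, strictly decreasing in both power levels.
#'
#' @param capacity_mah battery capacity in mAh.
#' @param profile an [fm_power_profile()].
#' @param derate usable-capacity fraction in (0, 1].
#' @return estimated operating time in hours.
#' @export
estimate_battery_life <- function(capacity_mah, profile = fm_power_profile(),
                                  derate = 1.0) {
  stopifnot_scalar_pos(capacity_mah, "capacity_mah")
  if (!(derate > 0 && derate <= 1))
    stop("derate must lie in (0, 1]", call. = FALSE)
  cyc <- profile$acquisition_s + profile$inference_s
  avg_mw <- (profile$idle_power_mw * profile$acquisition_s +
             profile$peak_power_mw * profile$inference_s) / cyc
  avg_ma <- avg_mw / profile$voltage_v
  derate * capacity_mah / avg_ma
}
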