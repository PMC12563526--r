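#' Model specification
#'
#' Describes one of the four registered convolutional families operating on
#' `3 x 129 x 6` log-spectrogram inputs (channels x frequency bins x STFT
#' frames):
#'
#' * `student_inverted_residual` (preset 1, approx. 0.32 M parameters):
#'   stem convolution plus inverted-residual blocks (pointwise expansion,
#'   depthwise 3x3, linear pointwise projection, identity skip when shapes
#'   match).
#' * `student_shuffle` (preset 2, approx. 0.31 M): grouped pointwise
#'   convolutions with channel-shuffle units and depthwise convolutions.
#' * `student_fire` (preset 3, approx. 0.27 M): fire modules (1x1 squeeze
#'   followed by mixed 1x1 / 3x3 expansion).
#' * `teacher_large` (approx. 1.1 M): a deeper plain-residual network
#'   trained from scratch, serving as the distillation teacher.
#'
#' Downsampling compresses the frequency axis with stride 2 while keeping
#' the short time axis until the last stage. `width_multiplier` scales all
#' channel widths (rounded to multiples of 4).
#'
#' @param family one of the four families above.
#' @param width_multiplier channel-width scaling factor.
#' @param dropout dropout rate before the classifier.
#' @param n_classes number of output classes.
#' @param input_shape input array shape as `c(n_bins, n_frames, channels)`.
#' @param param_budget optional target parameter count; [build_model()]
#'   errors if the instantiated count deviates by more than 2%.
#' @return object of class `fm_model_spec`.
#' @export
fm_model_spec <- function(family = c("student_inverted_residual",
                                     "student_shuffle", "student_fire",
                                     "teacher_large"),
                          width_multiplier = 1, dropout = 0.2,
                          n_classes = 2L, input_shape = c(129L, 6L, 3L),
                          param_budget = NULL) {
  family <- match.arg(family)
  if (is.null(param_budget) && width_multiplier == 1)
    param_budget <- switch(family,
      student_inverted_residual = 0.32e6,
      student_shuffle = 0.31e6,
      student_fire = 0.27e6,
      teacher_large = NULL)
  structure(list(family = family, width_multiplier = width_multiplier,
                 dropout = dropout, n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 param_budget = param_budget),
            class = "fm_model_spec")
}

scale_ch <- function(ch, wm) max(4L, as.integer(4L * round(ch * wm / 4)))

# inverted-residual block: expand -> depthwise -> project, skip when legal
ir_block <- function(cin, cout, expand = 4L, stride = c(1L, 1L)) {
  mid <- cin * expand
  body <- list(layer_conv(1, 1, cin, mid), layer_relu(),
               layer_dwconv(3, mid, stride), layer_relu(),
               layer_conv(1, 1, mid, cout))
  if (cin == cout && all(stride == 1L)) list(layer_res(body))
  else body
}

shuffle_unit <- function(cin, cout, mid, stride = c(1L, 1L), groups = 2L) {
  body <- list(layer_conv(1, 1, cin, mid, groups = groups), layer_relu(),
               layer_shuffle(groups),
               layer_dwconv(3, mid, stride),
               layer_conv(1, 1, mid, cout, groups = groups))
  if (cin == cout && all(stride == 1L)) list(layer_res(body), layer_relu())
  else c(body, list(layer_relu()))
}

fire_module <- function(cin, squeeze, e1, e3) {
  list(layer_conv(1, 1, cin, squeeze), layer_relu(),
       layer_cat(list(list(layer_conv(1, 1, squeeze, e1)),
                      list(layer_conv(3, 3, squeeze, e3)))),
       layer_relu())
}

res_stage <- function(c)
  list(layer_res(list(layer_conv(3, 3, c, c), layer_relu(),
                      layer_conv(3, 3, c, c))),
       layer_relu())

build_layers <- function(spec) {
  wm <- spec$width_multiplier
  s <- function(ch) scale_ch(ch, wm)
  cin <- 3L # all registered families take the 3-channel merged spectrogram
  nc <- spec$n_classes
  switch(spec$family,
    student_inverted_residual = c(
      list(layer_conv(3, 3, cin, s(16), stride = c(2L, 1L)), layer_relu()),
      ir_block(s(16), s(24), stride = c(2L, 1L)),
      ir_block(s(24), s(24)),
      ir_block(s(24), s(40), stride = c(2L, 1L)),
      ir_block(s(40), s(40)),
      ir_block(s(40), s(80), stride = c(2L, 2L)),
      ir_block(s(80), s(80)),
      ir_block(s(80), s(112)),
      ir_block(s(112), s(112)),
      list(layer_conv(1, 1, s(112), s(352)), layer_relu(),
           layer_gap(), layer_dropout(spec$dropout),
           layer_dense(s(352), nc))),
    student_shuffle = c(
      list(layer_conv(3, 3, cin, s(32), stride = c(2L, 1L)), layer_relu()),
      shuffle_unit(s(32), s(80), s(40), stride = c(2L, 1L)),
      shuffle_unit(s(80), s(80), s(40)),
      shuffle_unit(s(80), s(160), s(80), stride = c(2L, 1L)),
      shuffle_unit(s(160), s(160), s(80)),
      shuffle_unit(s(160), s(160), s(80)),
      shuffle_unit(s(160), s(320), s(160), stride = c(2L, 2L)),
      shuffle_unit(s(320), s(320), s(160)),
      shuffle_unit(s(320), s(320), s(160)),
      list(layer_conv(1, 1, s(320), s(360)), layer_relu(),
           layer_gap(), layer_dropout(spec$dropout),
           layer_dense(s(360), nc))),
    student_fire = c(
      list(layer_conv(3, 3, cin, s(32), stride = c(2L, 1L)), layer_relu()),
      fire_module(s(32), s(16), s(64), s(64)),
      fire_module(s(64) + s(64), s(16), s(64), s(64)),
      list(layer_avgpool(3, c(2L, 1L))),
      fire_module(s(64) + s(64), s(32), s(128), s(128)),
      fire_module(s(128) + s(128), s(32), s(128), s(128)),
      list(layer_avgpool(3, c(2L, 1L))),
      fire_module(s(128) + s(128), s(40), s(144), s(144)),
      list(layer_avgpool(3, c(2L, 2L))),
      fire_module(s(144) + s(144), s(48), s(144), s(144)),
      list(layer_dropout(spec$dropout),
           layer_conv(1, 1, s(144) + s(144), nc),
           layer_gap())),
    teacher_large = c(
      list(layer_conv(3, 3, cin, s(16), stride = c(2L, 1L)), layer_relu()),
      res_stage(s(16)), res_stage(s(16)),
      list(layer_conv(3, 3, s(16), s(40), stride = c(2L, 2L)), layer_relu()),
      res_stage(s(40)),
      list(layer_conv(3, 3, s(40), s(80), stride = c(2L, 1L)), layer_relu()),
      res_stage(s(80)),
      list(layer_conv(3, 3, s(80), s(160), stride = c(2L, 2L)), layer_relu()),
      res_stage(s(160)), res_stage(s(160)),
      list(layer_gap(), layer_dropout(spec$dropout),
           layer_dense(s(160), nc)))
  )
}

#' Build a classifier from a model specification
#'
#' Instantiates the architecture with He-normal initial weights drawn under
#' `seed` (the same spec and seed give identical initial parameters), and
#' validates the downsampling schedule against the input shape.
#'
#' @param spec an [fm_model_spec()] (or a family name).
#' @param seed integer seed for the deterministic initialization.
#' @return object of class `fm_model`: list with `layers`, `spec`,
#'   `n_params`, `macs`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- fm_model_spec(spec)
  stopifnot(inherits(spec, "fm_model_spec"))
  layers <- build_layers(spec)
  shp <- tryCatch(shape_prop(layers, spec$input_shape),
                  error = function(e)
                    stop("input shape incompatible with the architecture: ",
                         conditionMessage(e), call. = FALSE))
  if (length(shp$shape) != 1L || shp$shape != spec$n_classes)
    stop("architecture does not reduce to the class logits", call. = FALSE)
  layers <- with_seed(seed, init_layers(layers))
  n_par <- length(nn_get_params(layers))
  if (!is.null(spec$param_budget) &&
      abs(n_par - spec$param_budget) / spec$param_budget > 0.02)
    stop(sprintf("instantiated parameter count %d deviates >2%% from budget %g",
                 n_par, spec$param_budget), call. = FALSE)
  structure(list(layers = layers, spec = spec, n_params = n_par,
                 macs = shp$macs, seed = seed),
            class = "fm_model")
}

#' @export
print.fm_model <- function(x, ...) {
  cat(sprintf("<fm_model> %s: %.2f M parameters, %.2f M MACs, input %s\n",
              x$spec$family, x$n_params / 1e6, x$macs / 1e6,
              paste(x$spec$input_shape, collapse = "x")))
  invisible(x)
}

#' Parameter and multiply-accumulate accounting
#'
#' `count_params()` returns the number of trainable parameters;
#' `count_flops()` the total multiply-accumulate (MAC) count for one
#' forward pass, using the standard per-layer accounting
#' (convolution: `kh * kw * Cin/groups * Cout * Hout * Wout`; dense:
#' `in * out`; parameter-free layers contribute none).
#'
#' @param model an `fm_model` (or `fm_quantized_model`).
#' @return numeric count.
#' @export
count_flops <- function(model) {
  stopifnot(inherits(model, c("fm_model", "fm_quantized_model")))
  shape_prop(model$layers, model$spec$input_shape)$macs
}

#' @rdname count_flops
#' @export
count_params <- function(model) length(nn_get_params(model$layers))

#' Predict from a built or trained classifier
#'
#' @param object an `fm_model`.
#' @param newdata array `n x n_bins x n_frames x channels` (as produced by
#'   [spectrogram_batch()]).
#' @param type `"class"` (argmax labels), `"prob"` (softmax matrix) or
#'   `"logits"`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return factor of labels, or a numeric matrix.
#' @export
predict.fm_model <- function(object, newdata, type = c("class", "prob",
                                                       "logits"),
                             batch_size = 256L, ...) {
  type <- match.arg(type)
  logits <- forward_batched(object$layers, newdata, batch_size)
  finish_prediction(logits, type, object$spec$n_classes)
}

forward_batched <- function(layers, x, batch_size = 256L, fq = NULL) {
  n <- dim(x)[1]
  out <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(n, s + batch_size - 1L)
    xb <- x[idx, , , , drop = FALSE]
    ob <- if (is.null(fq)) nn_forward(layers, xb, train = FALSE)$out
          else nn_forward_q(layers, xb, fq)
    if (is.null(out)) out <- matrix(0, n, ncol(ob))
    out[idx, ] <- ob
  }
  out
}

finish_prediction <- function(logits, type, n_classes) {
  if (type == "logits") return(logits)
  p <- t(apply(logits, 1, function(z) softmax_T(z, 1)))
  if (type == "prob") {
    colnames(p) <- class_levels(n_classes)
    return(p)
  }
  factor(class_levels(n_classes)[max.col(logits, ties.method = "first")],
         levels = class_levels(n_classes))
}

class_levels <- function(n_classes)
  if (n_classes == 2L) c("FM", "N-FM") else paste0("class", seq_len(n_classes))
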