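# The convolutional classifier: architecture spec, weight initialisation,
# training and inference wrappers around the compiled core.

#' Architecture specification of the pileup classifier
#'
#' Pins the published topology: three 3x3 convolutional blocks (32, 16, 32
#' filters, ReLU), each followed by 3x3 max-pooling with stride 3 and floor
#' size reduction; a 1x1 convolution with 32 filters and ReLU; batch
#' normalisation (momentum 0.8) followed by flattening; a dense layer with
#' 10 neurons, ReLU and dropout 0.2 on its out-edges during training; and a
#' two-neuron softmax classification layer.
#'
#' @param conv_filters integer vector of filter counts for the three
#'   convolutional blocks
#' @param pointwise_filters filters in the 1x1 convolution
#' @param bn_momentum batch-norm moving-statistics momentum
#' @param dense_units neurons in the penultimate dense layer
#' @param dropout_p dropout probability on the dense layer's out-edges
#' @return object of class `model_spec`
#' @export
model_spec <- function(conv_filters = c(32L, 16L, 32L),
                       pointwise_filters = 32L, bn_momentum = 0.8,
                       dense_units = 10L, dropout_p = 0.2) {
  if (length(conv_filters) != 3 || any(conv_filters < 1))
    stop_usage("conv_filters must be three positive integers")
  if (bn_momentum < 0 || bn_momentum >= 1)
    stop_usage("bn_momentum must lie in [0, 1)")
  if (dropout_p < 0 || dropout_p >= 1)
    stop_usage("dropout_p must lie in [0, 1)")
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = 3L, pool = 3L,
                 pointwise_filters = as.integer(pointwise_filters),
                 bn_momentum = bn_momentum,
                 dense_units = as.integer(dense_units),
                 dropout_p = dropout_p, output_units = 2L),
            class = "model_spec")
}

#' Training configuration
#'
#' @param learning_rate constant Adam learning rate (default 1e-3)
#' @param batch_size minibatch size (default 256)
#' @param epochs training epochs (default 50)
#' @param label_smoothing smoothing parameter in \[0, 1); 0.1 maps the hard
#'   labels (1,0)/(0,1) to (0.95,0.05)/(0.05,0.95)
#' @param seed optional integer seed controlling weight initialisation
#'   order-of-use randomness (shuffling, dropout)
#' @param shuffle reshuffle the training set every epoch
#' @return object of class `train_config`
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 256L,
                         epochs = 50L, label_smoothing = 0.1,
                         seed = NULL, shuffle = TRUE) {
  if (label_smoothing < 0 || label_smoothing >= 1)
    stop_usage("label_smoothing must lie in [0, 1)")
  if (batch_size < 1) stop_usage("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 label_smoothing = label_smoothing,
                 seed = seed, shuffle = isTRUE(shuffle)),
            class = "train_config")
}

# spatial size after each of the three stride-3 floor poolings
pooled_dims <- function(input_shape) {
  stages <- list()
  h <- input_shape[1]; w <- input_shape[2]
  for (i in 1:3) {
    h <- h %/% 3L; w <- w %/% 3L
    stages[[i]] <- c(h, w)
  }
  stages
}

#' Build the pileup classifier
#'
#' Initialises all weights (Glorot-uniform, seeded) for the pinned layer
#' stack on a given input shape. Convolutions use same-padding; pooling uses
#' floor ("valid") size reduction, so an input of `(101, 200, depth)`
#' flattens to `3 * 7 * 32 = 672` features before the dense head.
#'
#' @param spec a [model_spec()]
#' @param input_shape integer vector `(d_window, d_reads, depth)`
#' @param seed optional seed for weight initialisation
#' @return object of class `cnn_model`
#' @export
build_model <- function(spec = model_spec(), input_shape, seed = NULL) {
  stopifnot(length(input_shape) == 3)
  input_shape <- as.integer(input_shape)
  h <- input_shape[1]; w <- input_shape[2]; depth <- input_shape[3]
  st <- pooled_dims(input_shape)
  if (any(vapply(st, min, numeric(1)) < 1))
    stop_usage("input spatial dimensions (", h, " x ", w,
               ") collapse under three 3x3 poolings; need both >= 27")
  if (!is.null(seed)) set.seed(seed)
  f <- spec$conv_filters
  f4 <- spec$pointwise_filters
  flat <- st[[3]][1] * st[[3]][2] * f4

  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  weights <- list(
    W1 = glorot(9L * depth, f[1], 9L * depth, 9L * f[1]), b1 = numeric(f[1]),
    W2 = glorot(9L * f[1], f[2], 9L * f[1], 9L * f[2]), b2 = numeric(f[2]),
    W3 = glorot(9L * f[2], f[3], 9L * f[2], 9L * f[3]), b3 = numeric(f[3]),
    W4 = glorot(f[3], f4, f[3], f4), b4 = numeric(f4),
    gamma = rep(1, f4), beta = numeric(f4),
    moving_mean = numeric(f4), moving_var = rep(1, f4),
    W5 = glorot(flat, spec$dense_units, flat, spec$dense_units),
    b5 = numeric(spec$dense_units),
    W6 = glorot(spec$dense_units, spec$output_units, spec$dense_units,
                spec$output_units),
    b6 = numeric(spec$output_units))

  structure(list(spec = spec, input_shape = input_shape,
                 stages = st, flat = flat, weights = weights,
                 trained = FALSE, history = NULL, seed = seed),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(paste0("<cnn_model> input (%s), conv %s + 1x1(%d), flatten %d,",
                     " dense %d -> 2 softmax; %d parameters; %s\n"),
              paste(x$input_shape, collapse = ","),
              paste(x$spec$conv_filters, collapse = "/"),
              x$spec$pointwise_filters, x$flat, x$spec$dense_units,
              count_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Count stored model parameters
#'
#' Total number of stored parameters, including the batch-norm scale, shift
#' and both moving statistics. For the pinned architecture on a
#' `(101, 200, 35)` input this is 27,312.
#'
#' @param model a [build_model()] object
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' Smooth one-hot labels
#'
#' `y -> y * (1 - eps) + eps / 2` per component, so with `eps = 0.1` the
#' hard labels (1,0) and (0,1) become (0.95,0.05) and (0.05,0.95).
#'
#' @param labels numeric vector of length 2 or an `n x 2` matrix of one-hot
#'   rows
#' @param eps smoothing parameter in \[0, 1)
#' @return smoothed labels, same shape as the input
#' @export
smooth_labels <- function(labels, eps) {
  if (!is.numeric(eps) || length(eps) != 1 || eps < 0 || eps >= 1)
    stop_usage("eps must lie in [0, 1)")
  labels * (1 - eps) + eps / 2
}

# stack composite samples into the d x n matrix consumed by the C++ core
dataset_matrix <- function(samples) {
  stopifnot(length(samples) > 0)
  d <- length(samples[[1]]$values)
  X <- matrix(0, d, length(samples))
  for (i in seq_along(samples)) {
    v <- samples[[i]]$values
    if (length(v) != d) stop_data("sample ", i, " has inconsistent shape")
    X[, i] <- as.numeric(v)
  }
  X
}

sample_list <- function(data) {
  if (inherits(data, "labelled_dataset")) data$samples else data
}

label_matrix <- function(samples) {
  labs <- vapply(samples, function(s) s$label %||% NA_character_, character(1))
  if (anyNA(labs))
    stop_data(sum(is.na(labs)), " sample(s) carry no label; ",
              "training requires labelled data")
  bad <- !labs %in% c("mutation", "artefact")
  if (any(bad)) stop_data("unknown label(s): ", paste(unique(labs[bad]), collapse = ", "))
  cbind(mutation = as.numeric(labs == "mutation"),
        artefact = as.numeric(labs == "artefact"))
}

#' Train the pileup classifier
#'
#' Optimises label-smoothed binary cross-entropy with Adam at a constant
#' learning rate. Training is bit-reproducible for a fixed
#' `config$seed`: the seed drives epoch shuffling and dropout masks.
#'
#' @param model an untrained or previously trained [build_model()] object
#' @param data a `labelled_dataset` or list of labelled `composite_sample`s
#' @param config a [train_config()]
#' @return the model with updated weights, `trained = TRUE`, and a
#'   `history` data.frame (epoch, loss, accuracy)
#' @export
train_cnn <- function(model, data, config = train_config()) {
  samples <- sample_list(data)
  Y <- label_matrix(samples)
  X <- dataset_matrix(samples)
  sh <- model$input_shape
  if (nrow(X) != prod(sh))
    stop_data("sample tensors have length ", nrow(X),
              " but the model expects ", prod(sh))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- cnn_train_cpp(X, Y, model$weights,
                       sh[1], sh[2], sh[3],
                       config$learning_rate, config$batch_size,
                       config$epochs, config$label_smoothing,
                       model$spec$dropout_p, model$spec$bn_momentum,
                       config$shuffle)
  model$weights <- res$weights
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(res$loss),
                              loss = res$loss, accuracy = res$accuracy)
  model$train_config <- config
  model
}

#' Classify composite samples
#'
#' Runs the network in inference mode (moving batch-norm statistics, no
#' dropout) and returns the per-sample probability of "mutation" together
#' with the argmax hard class.
#'
#' @param object a [build_model()] (normally [train_cnn()]-trained) model
#' @param data a `labelled_dataset` or list of `composite_sample`s
#' @param batch_size inference batch size
#' @param ... unused
#' @return data.frame with columns `prob_mutation`, `prob_artefact`, `class`
#' @export
predict.cnn_model <- function(object, data, batch_size = 256L, ...) {
  samples <- sample_list(data)
  X <- dataset_matrix(samples)
  sh <- object$input_shape
  if (nrow(X) != prod(sh))
    stop_data("sample tensors have length ", nrow(X),
              " but the model expects ", prod(sh))
  p <- cnn_predict_cpp(X, object$weights, sh[1], sh[2], sh[3],
                       as.integer(batch_size))
  data.frame(prob_mutation = p[, 1], prob_artefact = p[, 2],
             class = ifelse(p[, 1] >= p[, 2], "mutation", "artefact"),
             stringsAsFactors = FALSE)
}

#' Save a trained model checkpoint
#'
#' Serialises the model object and writes a JSON sidecar carrying the
#' architecture, training configuration and a hash of the encoding
#' configuration, so that refinement can verify tensor compatibility.
#'
#' @param model a `cnn_model`
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`
#' @param encoding the [encoding_config()] the training tensors used
#' @return invisibly, the checkpoint path
#' @export
save_model <- function(model, path, encoding = NULL) {
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec),
                  input_shape = model$input_shape,
                  train_config = if (!is.null(model$train_config))
                    unclass(model$train_config),
                  encoding = if (!is.null(encoding)) unclass(encoding),
                  encoding_hash = if (!is.null(encoding)) config_hash(unclass(encoding)),
                  parameters = count_parameters(model))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' Load a model checkpoint saved by [save_model()]
#'
#' @param path checkpoint path
#' @return list with elements `model` and `sidecar`
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE) else NULL
  list(model = model, sidecar = sidecar)
}
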