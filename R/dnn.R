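#' Specify a feed-forward classifier
#'
#' A model spec describes a stack of fully connected layers: rectified
#' linear hidden layers followed by a single sigmoid unit (binary) or a
#' softmax layer (multiclass). Optional dropout may be attached per hidden
#' layer.
#'
#' @param input_dim Number of input features (= windows of the grid).
#' @param hidden Integer vector of hidden-layer sizes (at least one).
#' @param n_classes Number of classes (>= 2). Two classes use one sigmoid
#'   output unit; more use `n_classes` softmax units.
#' @param dropout Optional numeric vector of per-hidden-layer dropout
#'   fractions in `[0, 1)`.
#' @return A `ModelSpec`.
#' @export
model_spec <- function(input_dim, hidden, n_classes = 2L, dropout = NULL) {
  input_dim <- as.integer(input_dim)
  hidden <- as.integer(hidden)
  n_classes <- as.integer(n_classes)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  if (length(hidden) < 1L || any(hidden < 1L))
    stop("need at least one hidden layer with positive unit count")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (!is.null(dropout)) {
    stopifnot(length(dropout) == length(hidden),
              all(dropout >= 0), all(dropout < 1))
  }
  out_units <- if (n_classes == 2L) 1L else n_classes
  structure(
    list(input_dim = input_dim, hidden = hidden, n_classes = n_classes,
         output_units = out_units,
         output_activation = if (n_classes == 2L) "sigmoid" else "softmax",
         dropout = dropout),
    class = "ModelSpec"
  )
}

#' Default three-layer classifier spec
#'
#' The library default is a three-dense-layer network: two rectified-linear
#' hidden layers and the output layer. For the canonical 1024-feature input
#' with binary output the hidden sizes are (56, 41), giving a trainable
#' parameter total of 59,779 (1024*56+56 + 56*41+41 + 41*1+1). Other input
#' dimensions scale the hidden sizes proportionally (rounded, floor 1
#' unit); the parameter count is then whatever the closed form gives.
#'
#' @param input_dim Number of input features.
#' @param n_classes Number of classes (>= 2).
#' @return A `ModelSpec`.
#' @examples
#' count_parameters(default_model_spec(1024, 2))  # 59779
#' @export
default_model_spec <- function(input_dim, n_classes = 2L) {
  input_dim <- as.integer(input_dim)
  if (input_dim < 1L) stop("input_dim must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  h <- pmax(1L, as.integer(round(c(56L, 41L) * input_dim / 1024)))
  model_spec(input_dim, hidden = h, n_classes = n_classes)
}

layer_dims <- function(spec) c(spec$input_dim, spec$hidden, spec$output_units)

#' Count trainable parameters of a spec
#'
#' Sum over consecutive layer pairs of `n_in * n_out + n_out` (weights plus
#' biases); dropout contributes nothing.
#'
#' @param spec A `ModelSpec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "ModelSpec"))
  d <- layer_dims(spec)
  sum(d[-length(d)] * d[-1] + d[-1])
}

#' @export
print.ModelSpec <- function(x, ...) {
  cat(sprintf("ModelSpec: %d -> %s -> %d (%s), %d trainable parameters\n",
              x$input_dim, paste(x$hidden, collapse = " -> "),
              x$output_units, x$output_activation, count_parameters(x)))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Minibatch size.
#' @param learning_rate Step size of the adaptive-moment (Adam) optimizer.
#' @param seed Integer seed fixing initialization, shuffling and dropout.
#' @param validation_fraction Fraction of rows held out for per-epoch
#'   validation metrics, in `[0, 0.5)`. Validation rows never contribute
#'   gradients.
#' @param class_weights If `TRUE`, weight each sample's loss by the inverse
#'   frequency of its class.
#' @return A `TrainingConfig` list.
#' @export
training_config <- function(epochs = 30L, batch_size = 128L,
                            learning_rate = 1e-3, seed = 1L,
                            validation_fraction = 0.1,
                            class_weights = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            validation_fraction >= 0, validation_fraction < 0.5)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 class_weights = isTRUE(class_weights)),
            class = "TrainingConfig")
}

# He-uniform init for rectifier layers, Glorot-uniform for the output.
init_weights <- function(spec) {
  d <- layer_dims(spec)
  L <- length(d) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- if (l < L) sqrt(6 / d[l]) else sqrt(6 / (d[l] + d[l + 1]))
    W[[l]] <- matrix(stats::runif(d[l] * d[l + 1], -lim, lim), d[l], d[l + 1])
    b[[l]] <- numeric(d[l + 1])
  }
  list(W = W, b = b)
}

forward_pass <- function(spec, wts, X, dropout_masks = NULL) {
  L <- length(wts$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% wts$W[[l]]
    Z <- sweep(Z, 2L, wts$b[[l]], "+")
    if (l < L) {
      Z[Z < 0] <- 0
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]]))
        Z <- Z * dropout_masks[[l]]
    } else if (spec$output_activation == "sigmoid") {
      Z <- 1 / (1 + exp(-Z))
    } else {
      Z <- Z - apply(Z, 1L, max)
      E <- exp(Z)
      Z <- E / rowSums(E)
    }
    A[[l + 1L]] <- Z
  }
  A
}

# cross-entropy loss matched to the output activation
ce_loss <- function(P, Y, w = NULL) {
  eps <- 1e-12
  if (ncol(P) == 1L) {
    ll <- -(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
  } else {
    ll <- -rowSums(Y * log(P + eps))
  }
  if (is.null(w)) mean(ll) else sum(w * ll) / sum(w)
}

#' Train the scan classifier
#'
#' Minibatch gradient descent with the Adam optimizer on cross-entropy
#' loss. All stochastic choices (weight init, shuffling, the validation
#' split, dropout) are driven by `config$seed`, so a fixed
#' (data, spec, config) triple reproduces the same weights and predictions.
#'
#' @param features A normalized `IntensityMatrix`, or a plain numeric matrix
#'   of feature rows.
#' @param labels Integer class label per row; at least two classes must be
#'   present.
#' @param spec A `ModelSpec` (default: [default_model_spec()] sized to the
#'   input).
#' @param config A `TrainingConfig`.
#' @return A `TrainedModel` with fields `spec`, `weights`, `class_levels`
#'   and `training_log` (per-epoch loss/accuracy).
#' @export
train_model <- function(features, labels, spec = NULL,
                        config = training_config()) {
  X <- feature_values(features, require_normalized = TRUE)
  labels <- as.integer(labels)
  if (nrow(X) != length(labels))
    stop("feature row count (", nrow(X), ") != label count (", length(labels), ")")
  levels <- sort(unique(labels))
  if (length(levels) < 2L)
    stop("training labels contain a single class (", levels,
         "); need at least two")
  if (is.null(spec)) spec <- default_model_spec(ncol(X), length(levels))
  stopifnot(inherits(spec, "ModelSpec"), inherits(config, "TrainingConfig"))
  if (spec$input_dim != ncol(X))
    stop("spec expects ", spec$input_dim, " features, data has ", ncol(X))
  if (spec$n_classes != length(levels))
    stop("spec expects ", spec$n_classes, " classes, labels have ",
         length(levels))

  binary <- spec$n_classes == 2L
  if (binary) {
    Y <- matrix(as.numeric(labels == levels[2L]), ncol = 1L)
  } else {
    Y <- outer(labels, levels, "==") * 1
  }
  w_cls <- NULL
  if (config$class_weights) {
    freq <- table(factor(labels, levels = levels))
    wmap <- as.numeric(length(labels) / (length(levels) * freq))
    w_cls <- wmap[match(labels, levels)]
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  n <- nrow(X)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val > 0L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  wts <- init_weights(spec)
  L <- length(wts$W)
  # Adam state
  mW <- lapply(wts$W, function(w) w * 0); vW <- mW
  mb <- lapply(wts$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t <- 0L
  lr <- config$learning_rate
  log_rows <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    starts <- seq(1L, length(ord), by = config$batch_size)
    loss_sum <- 0; acc_sum <- 0; n_seen <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      masks <- NULL
      if (!is.null(spec$dropout)) {
        masks <- lapply(seq_along(spec$hidden), function(l) {
          p <- spec$dropout[l]
          if (p <= 0) return(NULL)
          matrix(stats::rbinom(length(idx) * spec$hidden[l], 1L, 1 - p) / (1 - p),
                 length(idx), spec$hidden[l])
        })
      }
      A <- forward_pass(spec, wts, Xb, masks)
      m <- length(idx)
      wb <- if (is.null(w_cls)) NULL else w_cls[idx]
      loss_sum <- loss_sum + m * ce_loss(A[[L + 1L]], Yb, wb)
      acc_sum <- acc_sum + m * prediction_accuracy(A[[L + 1L]], Yb)
      n_seen <- n_seen + m
      # output delta is identical for sigmoid+BCE and softmax+CE
      delta <- (A[[L + 1L]] - Yb)
      if (!is.null(wb)) delta <- delta * (wb / mean(wb))
      delta <- delta / m
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(wts$W[[l]])
          if (!is.null(masks) && !is.null(masks[[l - 1L]]))
            delta <- delta * masks[[l - 1L]]
          delta[A[[l]] <= 0] <- 0  # ReLU gate
        }
        t_l <- t + 1L
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t_l; corr2 <- 1 - beta2^t_l
        wts$W[[l]] <- wts$W[[l]] - lr * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + adam_eps)
        wts$b[[l]] <- wts$b[[l]] - lr * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + adam_eps)
      }
      t <- t + 1L
    }
    # epoch loss/accuracy are running means over minibatches (pre-update),
    # the same convention deep-learning frameworks log
    loss <- loss_sum / n_seen
    acc <- acc_sum / n_seen
    if (!is.finite(loss))
      stop("training diverged: non-finite loss at epoch ", epoch,
           " (learning rate ", lr, ", batch ", config$batch_size, ")")
    vloss <- NA_real_; vacc <- NA_real_
    if (n_val > 0L) {
      Pv <- forward_pass(spec, wts, X[val_idx, , drop = FALSE])[[L + 1L]]
      vloss <- ce_loss(Pv, Y[val_idx, , drop = FALSE])
      vacc <- prediction_accuracy(Pv, Y[val_idx, , drop = FALSE])
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch, loss = loss, accuracy = acc,
                                    val_loss = vloss, val_accuracy = vacc)
  }
  structure(
    list(spec = spec, weights = wts, class_levels = levels,
         training_log = do.call(rbind, log_rows), config = config),
    class = "TrainedModel"
  )
}

prediction_accuracy <- function(P, Y) {
  if (ncol(P) == 1L) mean((P >= 0.5) == (Y == 1))
  else mean(max.col(P, ties.method = "first") == max.col(Y, ties.method = "first"))
}

#' @export
print.TrainedModel <- function(x, ...) {
  last <- x$training_log[nrow(x$training_log), ]
  cat(sprintf(
    "TrainedModel (%d params, classes %s): %d epochs, final loss %.4f, acc %.3f\n",
    count_parameters(x$spec), paste(x$class_levels, collapse = "/"),
    nrow(x$training_log), last$loss, last$accuracy))
  invisible(x)
}

feature_values <- function(features, require_normalized = FALSE) {
  if (inherits(features, "IntensityMatrix")) {
    if (require_normalized && !features$normalized)
      stop("features must be a normalized intensity matrix; call normalize_rows()")
    return(features$values)
  }
  if (!is.matrix(features)) stop("features must be a matrix or IntensityMatrix")
  features
}

#' Predict a class for every scan
#'
#' Runs the forward pass and thresholds: binary models predict the positive
#' class when its probability is >= 0.5 (ties go to the positive class, the
#' same convention as the sample-verdict rule); multiclass models take the
#' argmax of the softmax row, first class winning exact ties.
#'
#' @param model A `TrainedModel`.
#' @param features Normalized `IntensityMatrix` or plain matrix with
#'   `spec$input_dim` columns.
#' @return List with `labels` (integer, in the training label coding) and
#'   `probs` (matrix of per-class probabilities, one column per class
#'   level; binary models report both `1 - p` and `p`).
#' @export
predict_scans <- function(model, features) {
  stopifnot(inherits(model, "TrainedModel"))
  X <- feature_values(features)
  if (ncol(X) != model$spec$input_dim)
    stop("model expects ", model$spec$input_dim, " features, input has ",
         ncol(X), " columns")
  P <- forward_pass(model$spec, model$weights, X)[[length(model$weights$W) + 1L]]
  lv <- model$class_levels
  if (model$spec$n_classes == 2L) {
    p <- as.numeric(P[, 1L])
    probs <- cbind(1 - p, p)
    labels <- ifelse(p >= 0.5, lv[2L], lv[1L])
  } else {
    probs <- P
    labels <- lv[max.col(P, ties.method = "first")]
  }
  colnames(probs) <- as.character(lv)
  list(labels = as.integer(labels), probs = probs)
}
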