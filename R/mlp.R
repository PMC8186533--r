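#' Network and training configuration
#'
#' The classifier is a feedforward multilayer perceptron with 17 input
#' units (12 kinematic features + 5 subtest indicators), one tanh hidden
#' layer of `n_hidden` units and a 2-unit softmax output. Weights are
#' initialized with Xavier uniform limits `sqrt(6 / (fan_in + fan_out))`,
#' biases at 0. Training is full-batch Adam on the categorical
#' cross-entropy of integer class labels (ASD = 0, TD = 1).
#'
#' @param n_inputs number of input units (default 17).
#' @param n_hidden hidden units (>= 1).
#' @param n_outputs output units (2).
#' @return a `mlp_spec` list.
#' @export
mlp_spec <- function(n_inputs = 17L, n_hidden = 5L, n_outputs = 2L) {
  if (n_inputs < 1 || n_hidden < 1 || n_outputs < 1) {
    tk_stop("touchkin_config_error", "layer sizes must be positive")
  }
  structure(list(n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
                 n_outputs = as.integer(n_outputs)), class = "mlp_spec")
}

#' @rdname mlp_spec
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of full-batch epochs (>= 1).
#' @param beta1,beta2,epsilon Adam moment-decay and stabilizer constants.
#' @param seed integer seed controlling weight initialization.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 500L, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, seed = 1L) {
  if (learning_rate <= 0) tk_stop("touchkin_config_error", "learning_rate must be > 0")
  if (epochs < 1) tk_stop("touchkin_config_error", "epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)), class = "train_config")
}

xavier_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

#' Build an untrained network
#'
#' @param spec an [mlp_spec()].
#' @param seed integer seed; identical seeds give identical initial weights.
#' @return an `mlp_model`: weight matrices `W1` (inputs x hidden), `W2`
#'   (hidden x outputs), bias vectors `b1`, `b2`, plus the spec.
#' @export
build_model <- function(spec, seed = 1L) {
  set.seed(seed)
  l1 <- xavier_limit(spec$n_inputs, spec$n_hidden)
  l2 <- xavier_limit(spec$n_hidden, spec$n_outputs)
  structure(list(
    spec = spec,
    W1 = matrix(runif(spec$n_inputs * spec$n_hidden, -l1, l1), spec$n_inputs, spec$n_hidden),
    b1 = rep(0, spec$n_hidden),
    W2 = matrix(runif(spec$n_hidden * spec$n_outputs, -l2, l2), spec$n_hidden, spec$n_outputs),
    b2 = rep(0, spec$n_outputs),
    scaler = NULL, trace = NULL
  ), class = "mlp_model")
}

#' Number of trainable parameters
#' @param model an `mlp_model`.
#' @export
n_parameters <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass
#'
#' @param model an `mlp_model`.
#' @param X numeric matrix, rows = samples, columns in the model's input
#'   order.
#' @return list with `probs` (n x 2 class probabilities, rows sum to 1) and
#'   `hidden` (tanh activations).
#' @export
mlp_forward <- function(model, X) {
  A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
  P <- softmax_rows(sweep(A1 %*% model$W2, 2, model$b2, `+`))
  list(probs = P, hidden = A1)
}

# Design matrix + integer labels (ASD = 0, TD = 1) from a feature table.
model_matrix <- function(table) {
  bad <- setdiff(unique(table$label), c("ASD", "TD"))
  if (length(bad)) tk_stop("touchkin_label_error", "unknown label(s): %s", paste(bad, collapse = ", "))
  X <- as.matrix(table[, feature_columns(), with = FALSE])
  dimnames(X) <- NULL
  y <- ifelse(table$label == "ASD", 0L, 1L)
  list(X = X, y = y)
}

#' Train the network with full-batch Adam
#'
#' Runs `cfg$epochs` full-batch Adam steps on the cross-entropy loss,
#' recording the loss and training accuracy at every epoch. Deterministic
#' given `(data, cfg, seed)` since the batch is the whole dataset.
#'
#' @param model an `mlp_model` (typically from [build_model()]).
#' @param table standardized `feature_table` with binary labels.
#' @param cfg a [train_config()].
#' @return the trained `mlp_model`, with `$trace` a `data.table`
#'   (`epoch`, `loss`, `accuracy`).
#' @export
train <- function(model, table, cfg = train_config()) {
  mm <- model_matrix(table)
  X <- mm$X; y <- mm$y
  n <- nrow(X)
  Y <- matrix(0, n, 2); Y[cbind(seq_len(n), y + 1L)] <- 1
  pars <- c("W1", "b1", "W2", "b2")
  m <- v <- lapply(model[pars], function(p) p * 0)
  names(m) <- names(v) <- pars
  loss_tr <- acc_tr <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    A1 <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
    P <- softmax_rows(sweep(A1 %*% model$W2, 2, model$b2, `+`))
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-300)))
    if (!is.finite(loss)) {
      tk_stop("touchkin_divergence_error", "non-finite training loss at epoch %d", epoch)
    }
    loss_tr[epoch] <- loss
    acc_tr[epoch] <- mean(max.col(P) == y + 1L)
    dZ2 <- (P - Y) / n
    g <- list(W1 = NULL, b1 = NULL,
              W2 = crossprod(A1, dZ2), b2 = colSums(dZ2))
    dZ1 <- (dZ2 %*% t(model$W2)) * (1 - A1^2)
    g$W1 <- crossprod(X, dZ1)
    g$b1 <- colSums(dZ1)
    for (p in pars) {
      m[[p]] <- cfg$beta1 * m[[p]] + (1 - cfg$beta1) * g[[p]]
      v[[p]] <- cfg$beta2 * v[[p]] + (1 - cfg$beta2) * g[[p]]^2
      mhat <- m[[p]] / (1 - cfg$beta1^epoch)
      vhat <- v[[p]] / (1 - cfg$beta2^epoch)
      model[[p]] <- model[[p]] - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$epsilon)
    }
  }
  model$trace <- data.table::data.table(epoch = seq_len(cfg$epochs),
                                        loss = loss_tr, accuracy = acc_tr)
  model
}

#' Class-probability scores for a table
#'
#' @param model trained `mlp_model`.
#' @param table standardized `feature_table`.
#' @return numeric vector of ASD-class probabilities.
#' @export
predict_scores <- function(model, table) {
  mlp_forward(model, model_matrix(table)$X)$probs[, 1]
}

#' Serialize / restore a trained model as a flat text file
#'
#' Weights, biases and scaler parameters are written as `key: value` lines
#' (one value per line), so artifacts stay diffable.
#'
#' @param model trained `mlp_model` (with `$scaler` attached).
#' @param path text file path.
#' @export
write_model <- function(model, path) {
  kv <- list(n_inputs = model$spec$n_inputs, n_hidden = model$spec$n_hidden,
             n_outputs = model$spec$n_outputs)
  flat <- function(prefix, x) setNames(as.list(as.numeric(x)),
                                       paste0(prefix, ".", seq_along(x)))
  kv <- c(kv, flat("W1", model$W1), flat("b1", model$b1),
          flat("W2", model$W2), flat("b2", model$b2))
  if (!is.null(model$scaler)) {
    kv <- c(kv, setNames(as.list(model$scaler$mean), paste0("scaler.mean.", names(model$scaler$mean))),
            setNames(as.list(model$scaler$sd), paste0("scaler.sd.", names(model$scaler$sd))))
  }
  write_config(kv, path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  kv <- read_config(path)
  spec <- mlp_spec(kv$n_inputs, kv$n_hidden, kv$n_outputs)
  grab <- function(prefix, len) unlist(kv[paste0(prefix, ".", seq_len(len))], use.names = FALSE)
  model <- structure(list(
    spec = spec,
    W1 = matrix(grab("W1", spec$n_inputs * spec$n_hidden), spec$n_inputs, spec$n_hidden),
    b1 = grab("b1", spec$n_hidden),
    W2 = matrix(grab("W2", spec$n_hidden * spec$n_outputs), spec$n_hidden, spec$n_outputs),
    b2 = grab("b2", spec$n_outputs),
    scaler = NULL, trace = NULL
  ), class = "mlp_model")
  feats <- kinematic_feature_names()
  if (!is.null(kv[[paste0("scaler.mean.", feats[1])]])) {
    mu <- unlist(kv[paste0("scaler.mean.", feats)]); names(mu) <- feats
    sig <- unlist(kv[paste0("scaler.sd.", feats)]); names(sig) <- feats
    model$scaler <- structure(list(mean = mu, sd = sig), class = "scaler_params")
  }
  model
}
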