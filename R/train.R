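#' Training configuration
#'
#' Optimizer and loop settings for [train_classifier()]. The seed fixes
#' shuffling, the validation split and dropout masks, making training runs
#' exactly reproducible.
#'
#' @param epochs Number of passes over the training windows.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param rng_seed Integer seed.
#' @param validation_fraction Fraction of windows held out for the per-epoch
#'   validation loss (0 disables the split).
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 8, batch_size = 16, learning_rate = 1e-3,
                            rng_seed = 1, validation_fraction = 0.15) {
  stopifnot(epochs > 0, batch_size > 0, learning_rate > 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 rng_seed = as.integer(rng_seed),
                 validation_fraction = validation_fraction),
            class = "training_config")
}

#' Train a blink classifier on labeled windows
#'
#' Minimizes the binary cross-entropy (simple CNN, ResNet) or the composite
#' classification + reconstruction loss (autoencoder) with Adam over
#' mini-batches. Deterministic given the configuration seed: the same seed
#' yields bit-identical loss histories.
#'
#' @param model A `blink_model` from one of the builders.
#' @param data A `labeled_windows` set from [export_training_set()]; both
#'   classes must be present.
#' @param cfg A [training_config()].
#' @return An object of class `blink_fit`: the trained model plus a loss
#'   history tibble (`epoch`, `train_loss`, `val_loss`). [tidy()] returns
#'   the history, [glance()] the final epoch.
#' @export
train_classifier <- function(model, data, cfg = training_config()) {
  stopifnot(inherits(model, "blink_model"), inherits(data, "labeled_windows"))
  labels <- data$labels
  if (length(unique(labels)) < 2L) {
    abort("Training data must contain both classes.",
          class = "blinkdetect_single_class")
  }
  n <- length(data$windows)
  history <- vector("list", cfg$epochs)
  with_local_seed(cfg$rng_seed, {
    n_val <- floor(cfg$validation_fraction * n)
    val_idx <- if (n_val > 0) sample(n, n_val) else integer()
    train_idx <- setdiff(seq_len(n), val_idx)
    state <- adam_state(model$params)
    for (epoch in seq_len(cfg$epochs)) {
      order_idx <- sample(train_idx)
      batch_losses <- numeric()
      for (b0 in seq(1, length(order_idx), by = cfg$batch_size)) {
        batch <- order_idx[b0:min(b0 + cfg$batch_size - 1L, length(order_idx))]
        grads <- NULL
        loss_sum <- 0
        for (i in batch) {
          fwd <- model_forward(model, data$windows[[i]], train = TRUE)
          loss_sum <- loss_sum + model_loss(model, fwd, labels[i])
          grads <- grad_accumulate(grads,
                                   model_backward(model, fwd, labels[i],
                                                  lazy = TRUE))
        }
        grads <- grad_scale(materialize_grads(grads), 1 / length(batch))
        upd <- adam_step(model$params, grads, state, lr = cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
        batch_losses <- c(batch_losses, loss_sum / length(batch))
      }
      val_loss <- if (length(val_idx)) {
        mean(vapply(val_idx, function(i) {
          fwd <- model_forward(model, data$windows[[i]], train = FALSE)
          model_loss(model, fwd, labels[i])
        }, numeric(1)))
      } else {
        NA_real_
      }
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = mean(batch_losses),
                                 val_loss = val_loss)
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = cfg),
            class = "blink_fit")
}

#' @export
print.blink_fit <- function(x, ...) {
  last <- tail(x$history, 1)
  cat(sprintf("<blink_fit> %s, %d epochs; final train loss %.4f, val loss %s\n",
              x$model$arch, nrow(x$history), last$train_loss,
              ifelse(is.na(last$val_loss), "-", sprintf("%.4f", last$val_loss))))
  invisible(x)
}

#' @export
predict.blink_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
tidy.blink_fit <- function(x, ...) x$history

#' @export
glance.blink_fit <- function(x, ...) {
  dplyr::mutate(tail(x$history, 1),
                architecture = x$model$arch,
                n_params = n_params(x$model))
}

#' @export
autoplot.blink_fit <- function(object, ...) {
  df <- object$history
  long <- dplyr::bind_rows(
    tibble(epoch = df$epoch, loss = df$train_loss, set = "train"),
    tibble(epoch = df$epoch, loss = df$val_loss, set = "validation")
  )
  long <- long[!is.na(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Save or load a model checkpoint
#'
#' Weights are serialized to `<path>`; a plain-text YAML manifest describing
#' the architecture and hyperparameters is written next to it at
#' `<path>.yml`. Loading rebuilds the model and checks the manifest against
#' the weights.
#'
#' @param model A `blink_model` or `blink_fit`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `blink_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "blink_fit")) model <- model$model
  stopifnot(inherits(model, "blink_model"))
  manifest <- list(package = "blinkdetect",
                   architecture = model$arch,
                   ns = model$spec$ns,
                   latent_units = model$spec$latent_units,
                   width = model$spec$width,
                   head_units = as.list(model$spec$head_units),
                   dropout_rate = model$spec$dropout_rate,
                   head_dropout = model$spec$head_dropout,
                   loss_weights = as.list(model$spec$loss_weights),
                   n_params = n_params(model))
  yaml::write_yaml(manifest, paste0(path, ".yml"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "blink_model")) {
    abort("Checkpoint does not contain a blink model.",
          class = "blinkdetect_bad_checkpoint")
  }
  manifest_path <- paste0(path, ".yml")
  if (file.exists(manifest_path)) {
    manifest <- yaml::read_yaml(manifest_path)
    if (!identical(manifest$architecture, model$arch) ||
        manifest$n_params != n_params(model)) {
      abort("Checkpoint manifest does not match the serialized weights.",
            class = "blinkdetect_bad_checkpoint")
    }
  }
  model
}
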