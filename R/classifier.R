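#' Configuration of the two-stream MI/MCI classifier
#'
#' The classifier has one stream per feature family (kinematic angle
#' features and PROMs).  Each stream batch-normalises its inputs, applies a
#' square linear layer (as many outputs as inputs) and a ReLU; the streams
#' are concatenated and a final linear layer with sigmoid output yields the
#' probability of the positive class (MI).  Feature-subset masks select
#' which features of each family are active; a stream with no active
#' features is dropped entirely, enabling angle-only and PROMs-only models.
#'
#' @param angle_mask Logical vector of length 9 over
#'   [angle_feature_names()].
#' @param proms_mask Logical vector of length 7 over
#'   [proms_feature_names()].
#' @param learning_rate Gradient-descent step size (default 0.05).
#' @param epochs Training epochs (default 500).
#' @param batch_size Mini-batch size; 0 (default) trains full-batch, which
#'   is exact and reproducible at cohort sizes of ~100.
#' @param seed Integer seed controlling initialisation and any shuffling.
#' @param decision_threshold Probability cutoff for labelling MI
#'   (default 0.5).
#' @param max_restarts Maximum number of deterministic re-initialisations
#'   when training ends no better than the base-rate loss, i.e. when a
#'   ReLU stream has died (default 3; see Details).
#' @param bn_momentum Momentum of the batch-norm running statistics
#'   (default 0.1).
#' @param bn_eps Batch-norm variance stabiliser (default 1e-5).
#' @details ReLU units behind a learnable shift can reach an absorbing
#' all-negative state from which gradient descent cannot recover ("dying
#' ReLU"), which matters for the very small streams used here.  Two
#' measures keep training reliable: the stream linear layer carries no
#' bias (the batch-norm shift already provides it, and the redundant bias
#' is empirically the main route into the dead state), and training
#' restarts from a derived seed, up to `max_restarts` times, whenever the
#' final loss is indistinguishable from predicting the base rate.  Both
#' are deterministic under the config seed.
#' @return An object of class `spineflex_config`.
#' @export
model_config <- function(angle_mask = rep(TRUE, 9),
                         proms_mask = rep(TRUE, 7),
                         learning_rate = 0.05, epochs = 500,
                         batch_size = 0, seed = 1,
                         decision_threshold = 0.5, max_restarts = 3,
                         bn_momentum = 0.1, bn_eps = 1e-5) {
  angle_mask <- as.logical(angle_mask)
  proms_mask <- as.logical(proms_mask)
  stopifnot(length(angle_mask) == 9, length(proms_mask) == 7,
            !anyNA(angle_mask), !anyNA(proms_mask))
  if (!any(angle_mask) && !any(proms_mask)) {
    stop("at least one feature must be active across the two masks",
         call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(angle_mask = angle_mask, proms_mask = proms_mask,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 max_restarts = as.integer(max_restarts),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "spineflex_config")
}

with_local_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("MI", "MCI"))
    if (length(bad)) {
      stop(sprintf("unknown label(s): %s (expected MI or MCI)",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    as.integer(labels == "MI")
  } else if (is.numeric(labels) || is.logical(labels)) {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) {
      stop("numeric labels must be 0 (MCI) or 1 (MI)", call. = FALSE)
    }
    labels
  } else {
    stop("labels must be MI/MCI strings, a factor, or 0/1", call. = FALSE)
  }
}

active_streams <- function(config) {
  streams <- list()
  if (any(config$angle_mask)) {
    streams$angle <- ANGLE_FEATURES[config$angle_mask]
  }
  if (any(config$proms_mask)) {
    streams$proms <- PROMS_FEATURES[config$proms_mask]
  }
  streams
}

feature_matrix <- function(features, cols) {
  if (is.vector(features) && !is.null(names(features))) {
    features <- as.data.frame(as.list(features))
  }
  if (is.data.frame(features)) {
    features <- as.matrix(features[, intersect(names(features),
                                               c(ANGLE_FEATURES,
                                                 PROMS_FEATURES)),
                                   drop = FALSE])
  }
  missing_cols <- setdiff(cols, colnames(features))
  if (length(missing_cols)) {
    stop(sprintf("feature matrix missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  m <- features[, cols, drop = FALSE]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite feature values", call. = FALSE)
  m
}

#' Initialise classifier parameters
#'
#' Allocates untrained parameters for the model defined by `config`:
#' per-stream batch-norm statistics (running mean 0, running variance 1)
#' and affine scale/shift (1/0), per-stream square linear maps (bias-free;
#' the batch-norm shift provides the offset) and the final linear map with
#' bias, all weights drawn uniformly in \eqn{\pm 1/\sqrt{d}} under the
#' config seed.
#'
#' @param config A [model_config()].
#' @return An object of class `spineflex_model` with `trained = FALSE`.
#' @export
init_classifier <- function(config) {
  stopifnot(inherits(config, "spineflex_config"))
  streams_def <- active_streams(config)
  with_local_seed(config$seed, {
    streams <- lapply(streams_def, function(cols) {
      d <- length(cols)
      lim <- 1 / sqrt(d)
      list(features = cols,
           gamma = rep(1, d), beta = rep(0, d),
           run_mean = rep(0, d), run_var = rep(1, d),
           W = matrix(stats::runif(d * d, -lim, lim), d, d))
    })
    D <- sum(vapply(streams, function(s) length(s$features), integer(1)))
    lim <- 1 / sqrt(D)
    final <- list(w = matrix(stats::runif(D, -lim, lim), D, 1L),
                  b = stats::runif(1, -lim, lim))
    structure(list(config = config, streams = streams, final = final,
                   trained = FALSE, loss_history = numeric(0)),
              class = "spineflex_model")
  })
}

#' @export
print.spineflex_model <- function(x, ...) {
  sizes <- vapply(x$streams, function(s) length(s$features), integer(1))
  cat(sprintf("<spineflex_model> streams: %s; %s\n",
              paste(sprintf("%s(%d)", names(sizes), sizes), collapse = " + "),
              if (x$trained) sprintf("trained (%d epochs, final BCE %.4f)",
                                     length(x$loss_history),
                                     utils::tail(x$loss_history, 1))
              else "untrained"))
  invisible(x)
}

# forward pass; training=TRUE uses batch statistics and returns caches
nn_forward <- function(model, X_by_stream, training = FALSE) {
  eps <- model$config$bn_eps
  caches <- list()
  H_list <- list()
  for (nm in names(model$streams)) {
    st <- model$streams[[nm]]
    X <- X_by_stream[[nm]]
    if (training) {
      mu <- colMeans(X)
      v <- colMeans(sweep(X, 2L, mu)^2)   # biased batch variance
    } else {
      mu <- st$run_mean
      v <- st$run_var
    }
    xhat <- sweep(sweep(X, 2L, mu), 2L, sqrt(v + eps), "/")
    Z <- sweep(sweep(xhat, 2L, st$gamma, "*"), 2L, st$beta, "+")
    A <- Z %*% st$W
    H <- pmax(A, 0)
    caches[[nm]] <- list(mu = mu, v = v, xhat = xhat, Z = Z, A = A, H = H)
    H_list[[nm]] <- H
  }
  H_all <- do.call(cbind, H_list)
  z <- drop(H_all %*% model$final$w) + model$final$b
  p <- stats::plogis(z)
  list(p = p, H_all = H_all, caches = caches)
}

#' Forward pass through the classifier
#'
#' Computes the MI probability and label for one or more feature records
#' using the model's stored (inference) batch-norm statistics.
#'
#' @param model A `spineflex_model` (see [init_classifier()],
#'   [train_classifier()]).
#' @param features Named numeric vector, matrix or data frame holding at
#'   least the model's active features; extra columns are ignored.
#' @return Data frame with columns `probability` and `label` (`"MI"` iff
#'   probability >= the config decision threshold).
#' @export
model_forward <- function(model, features) {
  stopifnot(inherits(model, "spineflex_model"))
  X_by_stream <- lapply(model$streams, function(s)
    feature_matrix(features, s$features))
  p <- nn_forward(model, X_by_stream, training = FALSE)$p
  data.frame(probability = p,
             label = ifelse(p >= model$config$decision_threshold,
                            "MI", "MCI"))
}

#' Train the two-stream classifier
#'
#' Gradient descent on binary cross-entropy loss.  With `batch_size = 0`
#' (the default) every epoch is one full-batch step, which makes training
#' deterministic under the config seed; positive `batch_size` gives
#' shuffled mini-batch SGD.  Batch normalisation uses batch statistics
#' during training and exponentially-averaged running statistics (momentum
#' `bn_momentum`, unbiased variance) at inference.
#'
#' @param features Matrix or data frame of feature columns (canonical
#'   names); must cover the active features of `config`.
#' @param labels MI/MCI labels (character, factor, or 0/1 with MI = 1).
#' @param config A [model_config()].
#' @return A trained `spineflex_model` with the per-epoch loss in
#'   `$loss_history`.
#' @export
train_classifier <- function(features, labels, config = model_config()) {
  stopifnot(inherits(config, "spineflex_config"))
  y_all <- encode_labels(labels)
  if (length(unique(y_all)) < 2L) {
    stop("training set contains a single class; both MI and MCI are required",
         call. = FALSE)
  }
  if (min(table(y_all)) < 2L) {
    stop("at least 2 examples per class are required", call. = FALSE)
  }
  n <- length(y_all)
  lr <- config$learning_rate
  mom <- config$bn_momentum
  # base-rate loss: what a model that learned nothing would achieve
  q <- mean(y_all)
  base_rate_loss <- -(q * log(q) + (1 - q) * log(1 - q))
  attempt <- 0L
  repeat {
    attempt_config <- config
    attempt_config$seed <- config$seed + attempt * 100003L
    model <- train_classifier_once(features, y_all, attempt_config)
    converged <- utils::tail(model$loss_history, 1) < base_rate_loss - 1e-3
    if (converged || attempt >= config$max_restarts) break
    attempt <- attempt + 1L
  }
  model$config <- config
  model$restarts <- attempt
  model
}

# one seeded training run (full restart policy lives in train_classifier)
train_classifier_once <- function(features, y_all, config) {
  model <- init_classifier(config)
  X_all <- lapply(model$streams, function(s)
    feature_matrix(features, s$features))
  n <- length(y_all)
  lr <- config$learning_rate
  mom <- config$bn_momentum
  losses <- numeric(config$epochs)
  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      batches <- if (config$batch_size <= 0L || config$batch_size >= n) {
        list(seq_len(n))
      } else {
        idx <- sample.int(n)
        split(idx, ceiling(seq_along(idx) / config$batch_size))
      }
      epoch_loss <- 0
      for (batch in batches) {
        nb <- length(batch)
        Xb <- lapply(X_all, function(X) X[batch, , drop = FALSE])
        yb <- y_all[batch]
        fwd <- nn_forward(model, Xb, training = TRUE)
        p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d, learning rate %g",
                       epoch, lr), call. = FALSE)
        }
        epoch_loss <- epoch_loss + loss * nb / n
        dz <- matrix((fwd$p - yb) / nb, ncol = 1L)
        dW3 <- crossprod(fwd$H_all, dz)
        db3 <- sum(dz)
        dH <- dz %*% t(model$final$w)
        col0 <- 0L
        for (nm in names(model$streams)) {
          st <- model$streams[[nm]]
          cache <- fwd$caches[[nm]]
          d <- length(st$features)
          dHs <- dH[, col0 + seq_len(d), drop = FALSE]
          col0 <- col0 + d
          dA <- dHs * (cache$A > 0)
          dW <- crossprod(cache$Z, dA)
          dZ <- dA %*% t(st$W)
          dgamma <- colSums(dZ * cache$xhat)
          dbeta <- colSums(dZ)
          st$W <- st$W - lr * dW
          st$gamma <- st$gamma - lr * dgamma
          st$beta <- st$beta - lr * dbeta
          unbias <- if (nb > 1L) nb / (nb - 1L) else 1
          st$run_mean <- (1 - mom) * st$run_mean + mom * cache$mu
          st$run_var <- (1 - mom) * st$run_var + mom * cache$v * unbias
          model$streams[[nm]] <- st
        }
        model$final$w <- model$final$w - lr * dW3
        model$final$b <- model$final$b - lr * db3
      }
      losses[epoch] <- epoch_loss
    }
  })
  model$loss_history <- losses
  model$trained <- TRUE
  # drop incidental dimnames picked up from the data so that parameters
  # serialise canonically
  model$streams <- lapply(model$streams, function(s) {
    for (f in c("gamma", "beta", "run_mean", "run_var", "W")) {
      s[[f]] <- unname(s[[f]])
    }
    s
  })
  model$final$w <- unname(model$final$w)
  model
}

#' Predict MI/MCI labels for a dataset
#'
#' @param object A trained `spineflex_model`.
#' @param features Matrix or data frame of feature columns; features
#'   outside the model's masks are ignored.  May have zero rows.
#' @param ... Unused.
#' @return Data frame with one `probability` and `label` per record.
#' @export
predict.spineflex_model <- function(object, features, ...) {
  if (!isTRUE(object$trained)) {
    stop("model has not been trained; call train_classifier() first",
         call. = FALSE)
  }
  n_row <- if (is.null(dim(features))) 1L else nrow(features)
  if (n_row == 0L) {
    return(data.frame(probability = numeric(0), label = character(0)))
  }
  model_forward(object, features)
}

MODEL_JSON_VERSION <- "1.0"

#' Save a classifier to JSON
#'
#' Serialises the config, masks, all weights and batch-norm statistics to a
#' versioned JSON file that [load_model()] restores exactly.
#'
#' @param model A `spineflex_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "spineflex_model"))
  payload <- list(
    version = MODEL_JSON_VERSION,
    config = unclass(model$config),
    trained = model$trained,
    loss_history = model$loss_history,
    streams = lapply(model$streams, function(s) {
      list(features = s$features, gamma = s$gamma, beta = s$beta,
           run_mean = s$run_mean, run_var = s$run_var, W = s$W)
    }),
    final = list(w = as.numeric(model$final$w), b = model$final$b))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a classifier saved by [save_model()]
#'
#' @param path Path to the model JSON file.
#' @return A `spineflex_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$version, MODEL_JSON_VERSION)) {
    stop(sprintf("unsupported model file version: %s", payload$version),
         call. = FALSE)
  }
  cfg <- payload$config
  config <- model_config(angle_mask = cfg$angle_mask,
                         proms_mask = cfg$proms_mask,
                         learning_rate = cfg$learning_rate,
                         epochs = cfg$epochs, batch_size = cfg$batch_size,
                         seed = cfg$seed,
                         decision_threshold = cfg$decision_threshold,
                         max_restarts = cfg$max_restarts,
                         bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps)
  streams <- lapply(payload$streams, function(s) {
    d <- length(s$features)
    W <- s$W
    if (is.list(W)) W <- do.call(rbind, lapply(W, unlist))
    list(features = s$features, gamma = s$gamma, beta = s$beta,
         run_mean = s$run_mean, run_var = s$run_var,
         W = matrix(as.numeric(W), d, d))
  })
  structure(list(config = config, streams = streams,
                 final = list(w = matrix(payload$final$w, ncol = 1L),
                              b = payload$final$b),
                 trained = isTRUE(payload$trained),
                 loss_history = payload$loss_history),
            class = "spineflex_model")
}
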