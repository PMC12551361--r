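#' Specification of the single-hidden-layer perceptron
#'
#' The robustness classifier is a multilayer perceptron with exactly one
#' hidden layer, rectified-linear (ReLU) activation, a softmax output over
#' the three clinical classes, cross-entropy loss, and early stopping on an
#' internal validation split: training halts once the validation loss fails
#' to improve for `patience_epochs` consecutive epochs (or at `max_epochs`),
#' and the weights from the epoch with the best validation loss are restored.
#'
#' @param hidden_units width of the hidden layer (default 32).
#' @param validation_fraction fraction of the training data held out for the
#'   early-stopping monitor.
#' @param patience_epochs epochs without validation improvement tolerated
#'   before stopping.
#' @param max_epochs hard epoch cap.
#' @param learning_rate fixed step size of the mini-batch gradient descent.
#' @param batch_size mini-batch size.
#' @param seed integer seed (weight initialization, shuffling, split).
#' @return an object of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden_units = 32, validation_fraction = 0.15,
                     patience_epochs = 10, max_epochs = 300,
                     learning_rate = 0.05, batch_size = 32, seed = 1) {
  stopifnot(hidden_units >= 1, validation_fraction > 0, validation_fraction < 1,
            patience_epochs >= 0, max_epochs >= 1, learning_rate > 0,
            batch_size >= 1)
  structure(
    list(hidden_units = as.integer(hidden_units),
         activation = "relu",
         validation_fraction = validation_fraction,
         patience_epochs = as.integer(patience_epochs),
         max_epochs = as.integer(max_epochs),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "mlp_spec"
  )
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the single-hidden-layer perceptron
#'
#' Features are standardized internally (mean 0, SD 1 on the training split);
#' optimization is plain mini-batch gradient descent with a fixed learning
#' rate, which keeps training deterministic under a fixed seed.
#'
#' @param X numeric feature matrix.
#' @param y labels among `"dementia"`, `"cind"`, `"normal"` (at least two
#'   classes present).
#' @param spec an [mlp_spec()].
#' @return an object of class `trained_mlp` with the weights, the
#'   standardization constants, the stopping epoch and the loss traces.
#' @export
train_mlp <- function(X, y, spec = mlp_spec()) {
  stopifnot(inherits(spec, "mlp_spec"))
  X <- as.matrix(X)
  y <- as.character(y)
  if (!all(y %in% CLASS_LEVELS)) {
    stop("labels must be among: ", paste(CLASS_LEVELS, collapse = ", "))
  }
  if (length(unique(y)) < 2L) stop("need at least two classes")
  n <- nrow(X); p <- ncol(X); K <- 3L; H <- spec$hidden_units
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), match(y, CLASS_LEVELS))] <- 1

  with_seed(substream_seed(spec$seed, "mlp"), {
    n_val <- max(1L, round(n * spec$validation_fraction))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)

    mu <- colMeans(X[tr_idx, , drop = FALSE])
    sdev <- apply(X[tr_idx, , drop = FALSE], 2, stats::sd)
    sdev[!is.finite(sdev) | sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xva <- Xs[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

    # He initialization for the ReLU layer
    W1 <- matrix(stats::rnorm(p * H, 0, sqrt(2 / max(p, 1))), p, H)
    b1 <- rep(0, H)
    W2 <- matrix(stats::rnorm(H * K, 0, sqrt(2 / H)), H, K)
    b2 <- rep(0, K)

    forward <- function(Xm) {
      A1 <- pmax(sweep(Xm %*% W1, 2, b1, "+"), 0)
      P <- softmax_rows(sweep(A1 %*% W2, 2, b2, "+"))
      list(A1 = A1, P = P)
    }
    xent <- function(P, Ym) -mean(rowSums(Ym * log(pmax(P, 1e-12))))

    ntr <- length(tr_idx)
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = 0L)
    bad_epochs <- 0L
    tr_trace <- va_trace <- numeric(0)
    lr <- spec$learning_rate

    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(ntr)
      for (start in seq(1L, ntr, by = spec$batch_size)) {
        bi <- ord[start:min(start + spec$batch_size - 1L, ntr)]
        Xb <- Xtr[bi, , drop = FALSE]; Yb <- Ytr[bi, , drop = FALSE]
        fw <- forward(Xb)
        m <- length(bi)
        dZ2 <- (fw$P - Yb) / m
        gW2 <- crossprod(fw$A1, dZ2); gb2 <- colSums(dZ2)
        dA1 <- dZ2 %*% t(W2)
        dZ1 <- dA1 * (fw$A1 > 0)
        gW1 <- crossprod(Xb, dZ1); gb1 <- colSums(dZ1)
        W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
        W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
      }
      tr_loss <- xent(forward(Xtr)$P, Ytr)
      va_loss <- xent(forward(Xva)$P, Yva)
      if (!is.finite(tr_loss) || !is.finite(va_loss)) {
        stop("non-finite loss at epoch ", epoch,
             " (learning rate ", lr, "); reduce the learning rate")
      }
      tr_trace <- c(tr_trace, tr_loss); va_trace <- c(va_trace, va_loss)
      if (va_loss < best$loss - 1e-10) {
        best <- list(loss = va_loss, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                     epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > spec$patience_epochs) break
      }
    }

    structure(
      list(spec = spec, W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
           mu = mu, sdev = sdev, feature_names = colnames(X),
           best_epoch = best$epoch, epochs_run = epoch,
           train_loss = tr_trace, val_loss = va_trace),
      class = "trained_mlp"
    )
  })
}

#' Class probabilities from a trained perceptron
#'
#' @param object a `trained_mlp`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return data frame `p_dementia`, `p_cind`, `p_normal` (rows sum to 1).
#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$mu)) {
    stop("feature dimension mismatch: model has ", length(object$mu),
         ", input has ", ncol(X))
  }
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sdev, "/")
  A1 <- pmax(sweep(Xs %*% object$W1, 2, object$b1, "+"), 0)
  P <- softmax_rows(sweep(A1 %*% object$W2, 2, object$b2, "+"))
  colnames(P) <- c("p_dementia", "p_cind", "p_normal")
  as.data.frame(P)
}

#' Evaluate a trained perceptron against gold-standard labels
#'
#' Same validity definition and report type as [compute_validity()]: percent
#' agreement of the predicted binary dementia status (class with the largest
#' softmax probability) with the clinical status, on the validation split.
#'
#' @param model a `trained_mlp`.
#' @param features a [build_features()] set for the model's respondent kind.
#' @param gold gold-standard labels (validation split used).
#' @param kind respondent kind recorded in the report.
#' @return a `validation_report`.
#' @export
evaluate_mlp <- function(model, features, gold, kind = features$kind) {
  P <- predict(model, features$X)
  pred <- data.frame(
    person_id = features$meta$person_id,
    wave = features$meta$wave,
    kind = kind,
    dementia_hat = as.integer(P$p_dementia >= P$p_cind &
                                P$p_dementia >= P$p_normal),
    stringsAsFactors = FALSE
  )
  compute_validity(pred, gold)
}

#' Serialize / restore trained perceptron weights as structured text
#'
#' @param model a `trained_mlp`.
#' @param path output path.
#' @export
write_mlp <- function(model, path) {
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  lines <- c(
    paste0("hidden_units: ", ncol(model$W1)),
    paste0("features: ", paste(model$feature_names %||% seq_along(model$mu),
                               collapse = " ")),
    paste0("mu: ", num(model$mu)),
    paste0("sdev: ", num(model$sdev)),
    paste0("b1: ", num(model$b1)),
    paste0("b2: ", num(model$b2)),
    "W1:", apply(model$W1, 1, num),
    "W2:", apply(model$W2, 1, num)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  lines <- readLines(path)
  val <- function(key) {
    as.numeric(strsplit(trimws(sub(paste0("^", key, ": "), "",
                                   grep(paste0("^", key, ": "), lines,
                                        value = TRUE))),
                        " +")[[1]])
  }
  i1 <- which(lines == "W1:"); i2 <- which(lines == "W2:")
  parse_block <- function(from, to) {
    do.call(rbind, lapply(lines[from:to],
                          function(l) as.numeric(strsplit(trimws(l), " +")[[1]])))
  }
  W1 <- parse_block(i1 + 1L, i2 - 1L)
  W2 <- parse_block(i2 + 1L, length(lines))
  structure(
    list(W1 = W1, b1 = val("b1"), W2 = W2, b2 = val("b2"),
         mu = val("mu"), sdev = val("sdev"),
         feature_names = strsplit(sub("^features: ", "",
                                      grep("^features: ", lines, value = TRUE)),
                                  " ")[[1]]),
    class = "trained_mlp"
  )
}
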