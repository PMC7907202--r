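#' Logistic sigmoid activation
#'
#' \eqn{\sigma(t) = 1/(1+e^{-t})}, the unit activation of every
#' autoencoder layer; computed via `plogis` for numerical stability.
#'
#' @param t numeric.
#' @export
sigmoid <- function(t) stats::plogis(t)

#' Stacked-autoencoder classifier configuration
#'
#' `layer_sizes` are the hidden-layer widths (strictly decreasing, last =
#' bottleneck); an empty vector means a plain softmax (logistic) head on
#' the raw inputs. Training is full-batch gradient descent with classical
#' momentum: each hidden layer is pre-trained greedily as a sigmoid
#' autoencoder (squared reconstruction error), then the whole stack plus
#' softmax head is fine-tuned on the cross-entropy.
#'
#' @param layer_sizes integer vector of hidden widths.
#' @param epochs_pretrain,epochs_finetune epoch budgets.
#' @param learning_rate gradient-descent step size.
#' @param momentum classical momentum coefficient in `[0, 1)`.
#' @param seed integer seed for the weight initialization.
#' @return An `ae_config` list.
#' @export
ae_config <- function(layer_sizes, epochs_pretrain = 60L,
                      epochs_finetune = 200L, learning_rate = 0.5,
                      momentum = 0.9, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) > 1 && any(diff(layer_sizes) >= 0))
    nf_value_error("layer sizes must be strictly decreasing")
  if (length(layer_sizes) && any(layer_sizes < 1))
    nf_value_error("bottleneck must be >= 1")
  structure(list(layer_sizes = layer_sizes,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "ae_config")
}

.init_mat <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -r, r), nin, nout)
}

.softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Greedy pretraining of one autoencoder layer: sigmoid encoder, linear
# decoder (the inputs are real-valued, not binary), squared reconstruction
# error. The encoder bias starts at -mean(A W) so the sigmoid operates
# around its linear regime instead of saturating on the all-positive
# activations of the previous layer. Returns the encoder weights.
.pretrain_layer <- function(A, h, epochs, lr, mom) {
  n <- nrow(A); m <- ncol(A)
  W <- .init_mat(m, h); b <- -colMeans(A %*% W)
  V <- .init_mat(h, m); cvec <- colMeans(A)
  vW <- 0 * W; vb <- 0 * b; vV <- 0 * V; vc <- 0 * cvec
  for (e in seq_len(epochs)) {
    H <- sigmoid(sweep(A %*% W, 2, b, `+`))
    R <- sweep(H %*% V, 2, cvec, `+`)
    dZr <- 2 * (R - A) / (n * m)
    gV <- crossprod(H, dZr); gc <- colSums(dZr)
    dH <- tcrossprod(dZr, V)
    dZh <- dH * H * (1 - H)
    gW <- crossprod(A, dZh); gb <- colSums(dZh)
    vW <- mom * vW - lr * gW; W <- W + vW
    vb <- mom * vb - lr * gb; b <- b + vb
    vV <- mom * vV - lr * gV; V <- V + vV
    vc <- mom * vc - lr * gc; cvec <- cvec + vc
  }
  list(W = W, b = b)
}

.forward_stack <- function(X, layers) {
  A <- X
  acts <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    A <- sigmoid(sweep(A %*% layers[[k]]$W, 2, layers[[k]]$b, `+`))
    acts[[k]] <- A
  }
  list(h = A, acts = acts)
}

#' Train one branch classifier (stacked AE + softmax)
#'
#' Inputs are min-max scaled to `[0, 1]` per feature (scaling learned from
#' the training set), hidden layers are pre-trained greedily as sigmoid
#' autoencoders, and the full stack with a 2-class softmax head is
#' fine-tuned by full-batch gradient descent on the cross-entropy.
#' Deterministic given `config$seed`.
#'
#' @param features numeric matrix, one row per training sample.
#' @param labels `"benign"`/`"malignant"` per row, both classes present
#'   with at least 2 samples each.
#' @param config an [ae_config()]; its `layer_sizes` must be narrower than
#'   `ncol(features)`.
#' @return A `branch_classifier`.
#' @export
train_branch <- function(features, labels, config) {
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    nf_schema_error("non-finite values in training features")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2)
    nf_training_error("need >= 2 training samples in each class")
  if (length(config$layer_sizes) && config$layer_sizes[1] >= ncol(features) + 1)
    nf_value_error("first hidden layer must be narrower than the input")
  lo <- apply(features, 2, min)
  hi <- apply(features, 2, max)
  width <- pmax(hi - lo, 1e-12)
  X <- sweep(sweep(features, 2, lo), 2, width, `/`)
  Yhot <- cbind(benign = labels == "benign", malignant = labels == "malignant") * 1
  n <- nrow(X)
  lr <- config$learning_rate; mom <- config$momentum

  withr::with_seed(config$seed, {
    layers <- list()
    A <- X
    for (h in config$layer_sizes) {
      layers[[length(layers) + 1L]] <-
        .pretrain_layer(A, h, config$epochs_pretrain, lr, mom)
      A <- sigmoid(sweep(A %*% layers[[length(layers)]]$W, 2,
                         layers[[length(layers)]]$b, `+`))
    }
    dbot <- if (length(layers)) ncol(A) else ncol(X)
    Wo <- .init_mat(dbot, 2L)
    bo <- -colMeans((if (length(layers)) A else X) %*% Wo)

    vWo <- 0 * Wo; vbo <- 0 * bo
    vW <- lapply(layers, function(l) 0 * l$W)
    vb <- lapply(layers, function(l) 0 * l$b)
    for (e in seq_len(config$epochs_finetune)) {
      fw <- .forward_stack(X, layers)
      H <- fw$h
      P <- .softmax_rows(sweep(H %*% Wo, 2, bo, `+`))
      dS <- (P - Yhot) / n
      gWo <- crossprod(H, dS); gbo <- colSums(dS)
      dA <- tcrossprod(dS, Wo)
      gW <- vector("list", length(layers)); gb <- gW
      for (k in rev(seq_along(layers))) {
        Ak <- fw$acts[[k]]
        dZ <- dA * Ak * (1 - Ak)
        Aprev <- if (k == 1) X else fw$acts[[k - 1]]
        gW[[k]] <- crossprod(Aprev, dZ)
        gb[[k]] <- colSums(dZ)
        if (k > 1) dA <- tcrossprod(dZ, layers[[k]]$W)
      }
      vWo <- mom * vWo - lr * gWo; Wo <- Wo + vWo
      vbo <- mom * vbo - lr * gbo; bo <- bo + vbo
      for (k in seq_along(layers)) {
        vW[[k]] <- mom * vW[[k]] - lr * gW[[k]]
        layers[[k]]$W <- layers[[k]]$W + vW[[k]]
        vb[[k]] <- mom * vb[[k]] - lr * gb[[k]]
        layers[[k]]$b <- layers[[k]]$b + vb[[k]]
      }
    }
  })
  structure(list(layers = layers, Wo = Wo, bo = bo,
                 scale_lo = lo, scale_width = width,
                 input_dim = ncol(features),
                 bottleneck_dim = if (length(config$layer_sizes))
                   tail(config$layer_sizes, 1) else ncol(features),
                 config = config),
            class = "branch_classifier")
}

#' Class probabilities from a branch classifier
#'
#' @param clf a [train_branch()] result.
#' @param features matrix (or vector) of inputs with the training dimension.
#' @return Matrix `n x 2` of class probabilities (columns `benign`,
#'   `malignant`), rows summing to 1.
#' @export
predict_branch <- function(clf, features) {
  stopifnot(inherits(clf, "branch_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != clf$input_dim)
    nf_schema_error("expected %d features, got %d", clf$input_dim,
                    ncol(features))
  if (any(!is.finite(features)))
    nf_schema_error("non-finite values in features")
  X <- sweep(sweep(features, 2, clf$scale_lo), 2, clf$scale_width, `/`)
  H <- .forward_stack(X, clf$layers)$h
  P <- .softmax_rows(sweep(H %*% clf$Wo, 2, clf$bo, `+`))
  colnames(P) <- c("benign", "malignant")
  P
}

#' Bottleneck activations of a branch classifier
#'
#' The reduced feature representation (output of the last hidden layer).
#'
#' @inheritParams predict_branch
#' @return Matrix `n x bottleneck_dim`.
#' @export
encode_branch <- function(clf, features) {
  stopifnot(inherits(clf, "branch_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  X <- sweep(sweep(as.matrix(features), 2, clf$scale_lo), 2,
             clf$scale_width, `/`)
  .forward_stack(X, clf$layers)$h
}
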