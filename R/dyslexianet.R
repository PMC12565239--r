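#' Compact CNN architecture for 28x28x3 scalogram images
#'
#' Defines the DyslexiaNet layer ledger: four convolution blocks with 16,
#' 32, 64 and 64 filters of size 4x4 (stride 1, 'same' padding), each
#' followed by batch normalisation and ReLU; max pooling after the first two
#' blocks; 50 % dropout; a 2-unit fully connected layer; softmax. The first
#' pooling stage downsamples 28 -> 7 (pool 4, stride 4) and the second
#' 7 -> 3 (pool 2, stride 2, floor), so the final spatial map is 3x3x64 and
#' the fully connected layer sees 576 inputs. Per-layer learnable counts:
#' conv blocks 784/32, 8224/64, 32832/128, 65600/128 (conv/batchnorm) and fc
#' 1154.
#'
#' @param input_shape `(H, W, C)` of the input images, default `c(28, 28, 3)`.
#' @param n_classes Number of output classes (default 2).
#' @param filters Filter counts of the four conv blocks.
#' @param kernel Square conv kernel size (default 4).
#' @param pools Pool size after each block (`NA` = no pooling).
#' @param dropout_p Dropout probability before the fc layer.
#' @return A `dyslexianet_spec`: list of layer descriptors plus shapes.
#' @export
#' @examples
#' spec <- dyslexianet_spec()
#' spec$fc_in  # 576
dyslexianet_spec <- function(input_shape = c(28, 28, 3), n_classes = 2L,
                             filters = c(16, 32, 64, 64), kernel = 4L,
                             pools = c(4, 2, NA, NA), dropout_p = 0.5) {
  if (length(input_shape) != 3) abort("`input_shape` must be (H, W, C)")
  if (length(pools) != length(filters)) abort("`pools` must match `filters` in length")
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1)")
  layers <- list(list(name = "input", kind = "input", shape = input_shape))
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  for (i in seq_along(filters)) {
    f <- filters[i]
    layers <- c(layers, list(
      list(name = paste0("conv_", i), kind = "conv", kernel = kernel,
           n_filters = f, stride = 1L, padding = "same"),
      list(name = paste0("batchnorm_", i), kind = "batchnorm", channels = f),
      list(name = paste0("relu_", i), kind = "relu")
    ))
    C <- f
    if (!is.na(pools[i])) {
      layers <- c(layers, list(
        list(name = paste0("maxpool_", i), kind = "maxpool",
             pool = as.integer(pools[i]), stride = as.integer(pools[i]))
      ))
      H <- H %/% pools[i]; W <- W %/% pools[i]
      if (H < 1 || W < 1) {
        abort(sprintf("pooling after block %d collapses the spatial map", i))
      }
    }
  }
  fc_in <- H * W * C
  layers <- c(layers, list(
    list(name = "dropout", kind = "dropout", p = dropout_p),
    list(name = "fc", kind = "fully_connected", units = as.integer(n_classes),
         in_features = fc_in),
    list(name = "softmax", kind = "softmax")
  ))
  structure(list(layers = layers, input_shape = input_shape,
                 n_classes = as.integer(n_classes), fc_in = fc_in),
            class = "dyslexianet_spec")
}

# --- geometry helpers ------------------------------------------------------
# Activations are stored "wide": a matrix (N, H*W*C), with (h, w, c) flattened
# column-major (h fastest). A reshape to (N*H*W, C) is a plain dim<- because
# both share the (N, HW, C) flattening order.

conv_geometry <- function(H, W, C, k) {
  pb <- (k - 1L) %/% 2L  # leading pad; trailing pad = k - 1 - pb
  Hp <- H + k - 1L; Wp <- W + k - 1L
  h <- rep(seq_len(H), times = W * C)
  w <- rep(rep(seq_len(W), each = H), times = C)
  cc <- rep(seq_len(C), each = H * W)
  inner <- (cc - 1L) * Hp * Wp + (w - 1L + pb) * Hp + (h + pb)
  y <- rep(seq_len(H), times = W); x <- rep(seq_len(W), each = H)
  K <- k * k * C
  idx <- matrix(0L, H * W, K)
  j <- 0L
  for (ch in seq_len(C)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    j <- j + 1L
    idx[, j] <- (ch - 1L) * Hp * Wp + (x - 1L + dx) * Hp + (y + dy)
  }
  list(idx = idx, inner = inner, Hp = Hp, Wp = Wp, K = K, HW = H * W)
}

pool_geometry <- function(H, W, C, k) {
  Ho <- H %/% k; Wo <- W %/% k
  yo <- rep(seq_len(Ho), times = Wo); xo <- rep(seq_len(Wo), each = Ho)
  Q <- Ho * Wo * C
  Pidx <- matrix(0L, Q, k * k)
  j <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    j <- j + 1L
    base <- (xo - 1L) * k * H + (yo - 1L) * k + dx * H + dy  # 0-based within channel
    Pidx[, j] <- as.integer(outer(base + 1L, (seq_len(C) - 1L) * H * W, `+`))
  }
  list(Pidx = Pidx, Ho = Ho, Wo = Wo, Q = Q, k2 = k * k)
}

#' Build a trainable model from an architecture spec
#'
#' Initialises weights (He-scaled Gaussians for conv/fc, unit scale and zero
#' offset for batch normalisation) and precomputes the patch-index geometry
#' used by the vectorised forward/backward passes. Deterministic under
#' `seed`.
#'
#' @param spec A [dyslexianet_spec()].
#' @param seed Integer seed for weight initialisation (`NULL` = current RNG).
#' @return A `dyslexianet` model object.
#' @export
#' @examples
#' m <- build_model(dyslexianet_spec(), seed = 1)
#' count_learnables(m, "conv_1")  # 784
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "dyslexianet_spec"))
  maybe_with_seed(seed, {
    H <- spec$input_shape[1]; W <- spec$input_shape[2]; C <- spec$input_shape[3]
    layers <- list()
    for (ly in spec$layers) {
      l <- ly
      if (l$kind == "conv") {
        g <- conv_geometry(H, W, C, l$kernel)
        l$geom <- g
        l$W <- matrix(stats::rnorm(g$K * l$n_filters, 0, sqrt(2 / g$K)),
                      g$K, l$n_filters)
        l$b <- numeric(l$n_filters)
        C <- l$n_filters
      } else if (l$kind == "batchnorm") {
        if (l$channels != C) {
          abort(sprintf("layer %s: expected %d channels, spec says %d",
                        l$name, C, l$channels))
        }
        l$gamma <- rep(1, C); l$beta <- numeric(C)
        l$rmean <- numeric(C); l$rvar <- rep(1, C)
        l$momentum <- 0.1; l$eps <- 1e-5
      } else if (l$kind == "maxpool") {
        l$geom <- pool_geometry(H, W, C, l$pool)
        H <- l$geom$Ho; W <- l$geom$Wo
      } else if (l$kind == "fully_connected") {
        if (l$in_features != H * W * C) {
          abort(sprintf("layer %s: fc expects %d inputs but map is %dx%dx%d",
                        l$name, l$in_features, H, W, C))
        }
        l$W <- matrix(stats::rnorm(l$in_features * l$units, 0,
                                   sqrt(2 / l$in_features)),
                      l$in_features, l$units)
        l$b <- numeric(l$units)
        H <- 1L; W <- 1L; C <- l$units
      }
      l$out_shape <- c(H, W, C)
      layers[[l$name]] <- l
    }
    structure(list(spec = spec, layers = layers, classes = NULL,
                   input_mean = NULL, trained = FALSE),
              class = "dyslexianet")
  })
}

#' @export
print.dyslexianet <- function(x, ...) {
  cat(sprintf("<dyslexianet> input %s, %d classes, %s learnables%s\n",
              paste(x$spec$input_shape, collapse = "x"), x$spec$n_classes,
              format(sum(learnable_counts(x)$learnables), big.mark = ","),
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  print(as.data.frame(learnable_counts(x)))
  invisible(x)
}

#' Learnable-parameter counts
#'
#' `count_learnables()` returns the number of learnable parameters (weights
#' plus biases, or offsets plus scales) of one named layer;
#' `learnable_counts()` tabulates all layers. Activation, pooling, dropout
#' and softmax layers have none.
#'
#' @param model A `dyslexianet` model.
#' @param layer_name Layer name, e.g. `"conv_2"` (case-insensitive).
#' @return `count_learnables()`: an integer. `learnable_counts()`: a tibble
#'   with `layer` and `learnables`.
#' @export
count_learnables <- function(model, layer_name) {
  stopifnot(inherits(model, "dyslexianet"))
  nm <- tolower(layer_name)
  names_l <- tolower(names(model$layers))
  if (!nm %in% names_l) abort(sprintf("unknown layer '%s'", layer_name))
  l <- model$layers[[which(names_l == nm)]]
  switch(l$kind,
         conv = length(l$W) + length(l$b),
         fully_connected = length(l$W) + length(l$b),
         batchnorm = length(l$gamma) + length(l$beta),
         0L)
}

#' @rdname count_learnables
#' @export
learnable_counts <- function(model) {
  tibble(
    layer = names(model$layers),
    learnables = vapply(names(model$layers),
                        function(nm) as.integer(count_learnables(model, nm)),
                        integer(1))
  )
}

# --- forward / backward ----------------------------------------------------

nn_forward <- function(model, X, training = FALSE) {
  N <- nrow(X)
  caches <- list()
  A <- X
  for (l in model$layers) {
    kind <- l$kind
    if (kind == "input") {
      # zero-centre normalisation with the training-set mean
      if (!is.null(model$input_mean)) {
        A <- A - rep(model$input_mean, each = N)
      }
    } else if (kind == "conv") {
      g <- l$geom
      Ap <- matrix(0, N, g$Hp * g$Wp * (g$K / (l$kernel^2)))
      Ap[, g$inner] <- A
      Xc <- Ap[, as.vector(g$idx)]
      dim(Xc) <- c(N * g$HW, g$K)
      Y <- Xc %*% l$W
      Y <- Y + rep(l$b, each = nrow(Y))
      caches[[l$name]] <- list(Xc = Xc, N = N)
      dim(Y) <- c(N, g$HW * l$n_filters)
      A <- Y
    } else if (kind == "batchnorm") {
      C <- l$channels
      dim(A) <- c(length(A) / C, C)
      if (training) {
        mu <- colMeans(A)
        v <- colMeans(A^2) - mu^2
      } else {
        mu <- l$rmean; v <- l$rvar
      }
      istd <- 1 / sqrt(v + l$eps)
      xhat <- (A - rep(mu, each = nrow(A))) * rep(istd, each = nrow(A))
      Y <- xhat * rep(l$gamma, each = nrow(A)) + rep(l$beta, each = nrow(A))
      caches[[l$name]] <- list(xhat = xhat, istd = istd, mu = mu, v = v)
      dim(Y) <- c(N, length(Y) / N)
      A <- Y
    } else if (kind == "relu") {
      caches[[l$name]] <- list(mask = A > 0)
      A <- A * (A > 0)
    } else if (kind == "maxpool") {
      g <- l$geom
      G <- A[, as.vector(g$Pidx)]
      dim(G) <- c(N * g$Q, g$k2)
      M <- G[, 1]; amax <- rep(1L, N * g$Q)
      for (j in 2:g$k2) {
        upd <- G[, j] > M
        M[upd] <- G[upd, j]
        amax[upd] <- j
      }
      caches[[l$name]] <- list(amax = amax, in_cols = ncol(A))
      dim(M) <- c(N, g$Q)
      A <- M
    } else if (kind == "dropout") {
      if (training && l$p > 0) {
        mask <- matrix(stats::runif(length(A)) >= l$p, nrow(A), ncol(A)) / (1 - l$p)
        caches[[l$name]] <- list(mask = mask)
        A <- A * mask
      }
    } else if (kind == "fully_connected") {
      caches[[l$name]] <- list(Xin = A)
      A <- A %*% l$W + rep(l$b, each = N)
    } else if (kind == "softmax") {
      A <- A - apply(A, 1, max)
      E <- exp(A)
      A <- E / rowSums(E)
    }
  }
  list(probs = A, caches = caches)
}

# dLogits: gradient at the fc output (softmax + cross-entropy combined).
nn_backward <- function(model, caches, dLogits, N) {
  grads <- list()
  dA <- dLogits
  for (l in rev(model$layers)) {
    kind <- l$kind
    if (kind == "softmax" || kind == "input") {
      next
    } else if (kind == "fully_connected") {
      cache <- caches[[l$name]]
      grads[[l$name]] <- list(dW = crossprod(cache$Xin, dA), db = colSums(dA))
      dA <- tcrossprod(dA, l$W)
    } else if (kind == "dropout") {
      cache <- caches[[l$name]]
      if (!is.null(cache)) dA <- dA * cache$mask
    } else if (kind == "maxpool") {
      g <- l$geom
      cache <- caches[[l$name]]
      dM <- dA
      dim(dM) <- NULL
      qv <- rep(seq_len(g$Q), each = N)
      tcol <- g$Pidx[(cache$amax - 1L) * g$Q + qv]
      dX <- matrix(0, N, cache$in_cols)
      lin <- rep(seq_len(N), times = g$Q) + N * (tcol - 1)
      dX[lin] <- dM
      dA <- dX
    } else if (kind == "relu") {
      dA <- dA * caches[[l$name]]$mask
    } else if (kind == "batchnorm") {
      C <- l$channels
      cache <- caches[[l$name]]
      dim(dA) <- c(length(dA) / C, C)
      M <- nrow(dA)
      dgamma <- colSums(dA * cache$xhat)
      dbeta <- colSums(dA)
      grads[[l$name]] <- list(dgamma = dgamma, dbeta = dbeta)
      gi <- l$gamma * cache$istd
      dA <- (dA - rep(dbeta / M, each = M) -
               cache$xhat * rep(dgamma / M, each = M)) *
        rep(gi, each = M)
      dim(dA) <- c(N, length(dA) / N)
    } else if (kind == "conv") {
      g <- l$geom
      cache <- caches[[l$name]]
      dY <- dA
      dim(dY) <- c(N * g$HW, l$n_filters)
      grads[[l$name]] <- list(dW = crossprod(cache$Xc, dY), db = colSums(dY))
      dXc <- tcrossprod(dY, l$W)
      dim(dXc) <- c(N, g$HW * g$K)
      Cin <- g$K / (l$kernel^2)
      dAp <- matrix(0, N, g$Hp * g$Wp * Cin)
      HW <- g$HW
      for (j in seq_len(g$K)) {
        cols <- g$idx[, j]
        dAp[, cols] <- dAp[, cols] + dXc[, (j - 1L) * HW + seq_len(HW)]
      }
      dA <- dAp[, g$inner]
    }
  }
  grads
}

update_running_bn <- function(model, caches) {
  for (nm in names(model$layers)) {
    l <- model$layers[[nm]]
    if (l$kind == "batchnorm" && !is.null(caches[[nm]])) {
      m <- l$momentum
      model$layers[[nm]]$rmean <- (1 - m) * l$rmean + m * caches[[nm]]$mu
      model$layers[[nm]]$rvar <- (1 - m) * l$rvar + m * caches[[nm]]$v
    }
  }
  model
}

#' Train the CNN
#'
#' Minibatch training with the Adam optimiser and cross-entropy loss.
#' Images are scaled to `[0, 1]` and zero-centred with the per-pixel
#' training-set mean (stored on the model for prediction). Shuffling,
#' dropout and initialisation are controlled by `seed`.
#'
#' @param model A `dyslexianet` from [build_model()].
#' @param x Numeric matrix `(N, H*W*C)` of images in `[0, 1]` (see
#'   [images_to_matrix()]), or a dataset tibble from
#'   [build_image_dataset()].
#' @param y Factor (or character) of class labels, length N; ignored when
#'   `x` is a dataset tibble.
#' @param epochs,batch_size,learning_rate Training hyperparameters
#'   (defaults 20, 64, 1e-3).
#' @param seed Integer seed (`NULL` = current RNG stream).
#' @param verbose Print per-epoch loss?
#' @return The trained model.
#' @export
train_dyslexianet <- function(model, x, y = NULL, epochs = 20, batch_size = 64,
                              learning_rate = 1e-3, seed = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(model, "dyslexianet"))
  if (is.data.frame(x)) {
    y <- x$label
    x <- images_to_matrix(x$image)
  }
  y <- factor(y)
  if (nlevels(y) != model$spec$n_classes) {
    abort(sprintf("expected %d classes, got %d", model$spec$n_classes, nlevels(y)))
  }
  model$classes <- levels(y)
  model$input_mean <- colMeans(x)
  N <- nrow(x)
  Yhot <- matrix(0, N, nlevels(y))
  Yhot[cbind(seq_len(N), as.integer(y))] <- 1

  maybe_with_seed(seed, {
    adam <- list()
    t_step <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- numeric(0)
      for (start in seq(1, N, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, N)]
        fw <- nn_forward(model, x[bi, , drop = FALSE], training = TRUE)
        probs <- fw$probs
        nb <- length(bi)
        losses <- c(losses, -mean(log(pmax(probs[cbind(seq_len(nb), as.integer(y[bi]))], 1e-12))))
        dLogits <- (probs - Yhot[bi, , drop = FALSE]) / nb
        grads <- nn_backward(model, fw$caches, dLogits, nb)
        model <- update_running_bn(model, fw$caches)
        t_step <- t_step + 1
        for (nm in names(grads)) {
          l <- model$layers[[nm]]
          pnames <- if (l$kind == "batchnorm") c("gamma", "beta") else c("W", "b")
          gnames <- if (l$kind == "batchnorm") c("dgamma", "dbeta") else c("dW", "db")
          for (k in 1:2) {
            key <- paste0(nm, ".", pnames[k])
            g <- grads[[nm]][[gnames[k]]]
            st <- adam[[key]] %||% list(m = g * 0, v = g * 0)
            st$m <- b1 * st$m + (1 - b1) * g
            st$v <- b2 * st$v + (1 - b2) * g^2
            adam[[key]] <- st
            mhat <- st$m / (1 - b1^t_step)
            vhat <- st$v / (1 - b2^t_step)
            model$layers[[nm]][[pnames[k]]] <-
              l[[pnames[k]]] - learning_rate * mhat / (sqrt(vhat) + eps)
            l <- model$layers[[nm]]
          }
        }
      }
      if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, epochs, mean(losses)))
    }
    model$trained <- TRUE
    model
  })
}

#' Predict with a trained model
#'
#' @param object A `dyslexianet` model.
#' @param x Image matrix `(N, H*W*C)` in `[0, 1]`, or a dataset tibble.
#' @param type `"prob"` for class probabilities (rows sum to 1) or
#'   `"class"` for labels.
#' @param ... Unused.
#' @return Probability matrix or factor of predicted labels.
#' @export
predict.dyslexianet <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(x)) x <- images_to_matrix(x$image)
  probs <- nn_forward(object, x, training = FALSE)$probs
  if (!is.null(object$classes)) colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  cls <- object$classes %||% as.character(seq_len(ncol(probs)))
  factor(cls[max.col(probs, ties.method = "first")], levels = cls)
}

#' Flatten scalogram images into a training matrix
#'
#' @param images List of `eog_scalogram_image` objects (or raw `H x W x 3`
#'   arrays) with identical dimensions.
#' @return Numeric matrix `(N, H*W*C)` scaled to `[0, 1]`.
#' @export
images_to_matrix <- function(images) {
  vecs <- lapply(images, function(im) {
    a <- if (inherits(im, "eog_scalogram_image")) im$pixels else im
    as.vector(a) / 255
  })
  len <- lengths(vecs)
  if (length(unique(len)) != 1) abort("images have inconsistent dimensions")
  matrix(unlist(vecs, use.names = FALSE), length(vecs), len[1], byrow = TRUE)
}
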