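# Multilayer-perceptron binary classifier, trained full-batch by
# backpropagation. Small by design: the feature matrices this pipeline
# produces are a few dozen gene columns over a few hundred probands, so
# full-batch first-order optimization is both adequate and exactly
# reproducible for a fixed seed.

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z, a) 1 - a^2),
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         df = function(z, a) a * (1 - a)),
         stop("unknown activation: ", name))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a multilayer perceptron for binary classification
#'
#' Minimizes class-weighted binary cross-entropy with an L2 penalty
#' `alpha` on the weights, using full-batch Adam or momentum SGD. With
#' the `"adaptive"` schedule the learning rate is divided by 5 whenever
#' the loss fails to improve for 10 consecutive iterations.
#'
#' @param x Numeric matrix (samples x features); standardized internally.
#' @param y Binary labels (0/1).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param activation `"relu"`, `"tanh"` or `"logistic"`.
#' @param alpha L2 regularization strength.
#' @param solver `"adam"` or `"sgd"` (momentum 0.9).
#' @param learning_rate Initial learning rate.
#' @param lr_schedule `"constant"` or `"adaptive"`.
#' @param max_iter Maximum number of full-batch iterations.
#' @param class_weight Weight classes inversely to their frequency
#'   (default `TRUE`).
#' @param seed RNG seed for weight initialization.
#' @param tol Minimum loss improvement counted as progress.
#' @return A `bdvoi_mlp` model.
#' @export
mlp_fit <- function(x, y, hidden = 16L, activation = "relu", alpha = 1e-4,
                    solver = "adam", learning_rate = 1e-3,
                    lr_schedule = "constant", max_iter = 200L,
                    class_weight = TRUE, seed = 1L, tol = 1e-6) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  w <- if (class_weight) {
    tw <- n / (2 * pmax(table(factor(y, levels = c(0, 1))), 1L))
    as.numeric(tw[as.character(y)])
  } else rep(1, n)
  w <- w / mean(w)

  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  set.seed(seed)
  W <- lapply(seq_len(L), function(l) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim), sizes[l], sizes[l + 1L])
  })
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1L]))
  act <- act_fun(activation)

  forward <- function(xs) {
    zs <- vector("list", L)
    as <- vector("list", L)
    a <- xs
    for (l in seq_len(L)) {
      z <- a %*% W[[l]] + matrix(b[[l]], nrow(a), sizes[l + 1L], byrow = TRUE)
      zs[[l]] <- z
      a <- if (l < L) act$f(z) else sigmoid(z)
      as[[l]] <- a
    }
    list(zs = zs, as = as)
  }
  loss_of <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ce <- -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
    ce + 0.5 * alpha * sum(vapply(W, function(m) sum(m^2), numeric(1))) / n
  }

  # optimizer state
  mW <- lapply(W, function(m) m * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- learning_rate
  best_loss <- Inf
  stall <- 0L
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    fw <- forward(xs)
    p <- as.numeric(fw$as[[L]])
    delta <- matrix(w * (p - y) / n, n, 1L)  # dCE/dz_out for sigmoid + CE
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      a_prev <- if (l == 1L) xs else fw$as[[l - 1L]]
      gW[[l]] <- crossprod(a_prev, delta) + (alpha / n) * W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * act$df(fw$zs[[l - 1L]], fw$as[[l - 1L]])
      }
    }
    for (l in seq_len(L)) {
      if (solver == "adam") {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mh <- mW[[l]] / (1 - beta1^it); vh <- vW[[l]] / (1 - beta2^it)
        W[[l]] <- W[[l]] - lr * mh / (sqrt(vh) + eps)
        mhb <- mb[[l]] / (1 - beta1^it); vhb <- vb[[l]] / (1 - beta2^it)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      } else {  # momentum SGD
        mW[[l]] <- beta1 * mW[[l]] - lr * gW[[l]]
        W[[l]] <- W[[l]] + mW[[l]]
        mb[[l]] <- beta1 * mb[[l]] - lr * gb[[l]]
        b[[l]] <- b[[l]] + mb[[l]]
      }
    }
    cur <- loss_of(as.numeric(forward(xs)$as[[L]]))
    trace[it] <- cur
    if (!is.finite(cur)) break
    if (cur < best_loss - tol) {
      best_loss <- cur
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (lr_schedule == "adaptive" && stall >= 10L) {
        lr <- lr / 5
        stall <- 0L
        if (lr < 1e-6) break
      } else if (lr_schedule == "constant" && stall >= 20L) {
        break
      }
    }
  }
  structure(list(W = W, b = b, center = ctr, scale = scl,
                 activation = activation, hidden = hidden, alpha = alpha,
                 solver = solver, learning_rate = learning_rate,
                 lr_schedule = lr_schedule, max_iter = max_iter,
                 n_iter = length(trace), loss = utils::tail(trace, 1L),
                 seed = seed),
            class = "bdvoi_mlp")
}

#' Predict from a fitted MLP
#' @param object A `bdvoi_mlp`.
#' @param newdata Matrix with the training feature columns.
#' @param type `"prob"` for P(label = 1) or `"class"` for 0/1 labels.
#' @param ... unused.
#' @return numeric (prob) or integer (class) vector.
#' @export
predict.bdvoi_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L, object$scale, "/")
  act <- act_fun(object$activation)
  L <- length(object$W)
  a <- xs
  for (l in seq_len(L)) {
    z <- a %*% object$W[[l]] +
      matrix(object$b[[l]], nrow(a), ncol(object$W[[l]]), byrow = TRUE)
    a <- if (l < L) act$f(z) else sigmoid(z)
  }
  p <- as.numeric(a)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.bdvoi_mlp <- function(x, ...) {
  cat("bdvoi_mlp: hidden [", paste(x$hidden, collapse = ", "), "], ",
      x$activation, "/", x$solver, ", ", x$n_iter, " iterations, final loss ",
      signif(x$loss, 4), "\n", sep = "")
  invisible(x)
}
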