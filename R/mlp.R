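# Minimal feed-forward multilayer perceptron for binary classification.
# Sigmoid output + cross-entropy loss + L2 penalty alpha/(2n)*sum(W^2);
# hidden activations identity/logistic/tanh/relu; trained full-batch by
# L-BFGS-B (stats::optim, the "lbfgs" iteration scheme), plain gradient
# descent ("sgd") or ADAM, with constant/invscaling/adaptive learning-rate
# schedules.

#' Allocate a neuron budget across hidden layers
#'
#' Splits `total` neurons over hidden layers proportionally to `ratio`
#' (e.g. 100 neurons in a 1:8:1 architecture gives layers 10-80-10). Each
#' layer takes the floor of its proportional share; any remainder is added
#' to the first layer, so the sizes always sum to `total` and the allocation
#' is deterministic.
#'
#' @param total Total number of hidden neurons (>= number of layers).
#' @param ratio Positive integer vector, one entry per hidden layer.
#' @return Integer vector of layer sizes, summing to `total`.
#' @examples
#' allocate_neurons(100, c(1, 8, 1))
#' allocate_neurons(200, c(1, 4, 4, 1))
#' @export
allocate_neurons <- function(total, ratio) {
  stopifnot(length(ratio) >= 1, all(ratio > 0), all(ratio == round(ratio)))
  if (total < length(ratio)) {
    stop("total neurons (", total, ") fewer than layers (", length(ratio),
         ")", call. = FALSE)
  }
  sizes <- floor(total * ratio / sum(ratio))
  sizes[sizes == 0] <- 1L
  sizes[1] <- sizes[1] + (total - sum(sizes))
  if (sizes[1] < 1) stop("ratio incompatible with total", call. = FALSE)
  as.integer(sizes)
}

mlp_act <- function(name) {
  switch(name,
    identity = list(f = function(x) x, df = function(a) 1),
    logistic = list(f = function(x) 1 / (1 + exp(-x)),
                    df = function(a) a * (1 - a)),
    tanh = list(f = base::tanh, df = function(a) 1 - a^2),
    relu = list(f = function(x) pmax(x, 0), df = function(a) (a > 0) * 1),
    stop("unknown activation: ", name, call. = FALSE))
}

mlp_shapes <- function(n_in, hidden) {
  dims <- c(n_in, hidden, 1L)
  purrr::map(seq_len(length(dims) - 1L),
             function(i) c(dims[i], dims[i + 1L]))
}

mlp_unpack <- function(par, shapes) {
  ofs <- 0L
  purrr::map(shapes, function(sh) {
    nw <- sh[1] * sh[2]
    w <- matrix(par[ofs + seq_len(nw)], sh[1], sh[2])
    b <- par[ofs + nw + seq_len(sh[2])]
    ofs <<- ofs + nw + sh[2]
    list(w = w, b = b)
  })
}

mlp_forward <- function(layers, x, act) {
  a <- list(x)
  nl <- length(layers)
  for (i in seq_len(nl)) {
    z <- a[[i]] %*% layers[[i]]$w +
      matrix(layers[[i]]$b, nrow(x), length(layers[[i]]$b), byrow = TRUE)
    a[[i + 1L]] <- if (i < nl) act$f(z) else 1 / (1 + exp(-z))
  }
  a
}

# loss and gradient in one pass; y in {0,1}
mlp_loss_grad <- function(par, shapes, x, y, act, alpha) {
  n <- nrow(x)
  layers <- mlp_unpack(par, shapes)
  a <- mlp_forward(layers, x, act)
  p <- pmin(pmax(a[[length(a)]], 1e-12), 1 - 1e-12)
  pen <- sum(purrr::map_dbl(layers, function(l) sum(l$w^2)))
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p)) + alpha * pen / (2 * n)
  delta <- (p - y) / n
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(w = crossprod(a[[i]], delta) +
                         alpha * layers[[i]]$w / n,
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$w)) * act$df(a[[i]])
    }
  }
  gvec <- unlist(purrr::map(grads, function(g) c(as.vector(g$w), g$b)))
  list(loss = loss, grad = gvec)
}

mlp_fit <- function(x, y, hidden, activation = "relu", solver = "lbfgs",
                    learning_rate = "constant", alpha = 1e-4,
                    max_iter = 200, lr_init = 0.05, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(all(y %in% 0:1))
  act <- mlp_act(activation)
  shapes <- mlp_shapes(ncol(x), hidden)
  npar <- sum(purrr::map_int(shapes, function(s) s[1] * s[2] + s[2]))
  par0 <- with_seed(seed, {
    unlist(purrr::map(shapes, function(sh) {
      # Glorot-style scale keeps deep tanh/logistic stacks trainable
      sc <- sqrt(6 / (sh[1] + sh[2]))
      c(stats::runif(sh[1] * sh[2], -sc, sc), rep(0, sh[2]))
    }))
  })
  y <- matrix(as.numeric(y), ncol = 1)

  if (solver == "lbfgs") {
    # optim calls fn and gr separately at the same point: cache one pass
    cache <- list(par = NULL, val = NULL)
    at <- function(p) {
      if (is.null(cache$par) || !identical(p, cache$par)) {
        cache <<- list(par = p, val = mlp_loss_grad(p, shapes, x, y, act,
                                                    alpha))
      }
      cache$val
    }
    fit <- stats::optim(par0,
                        fn = function(p) at(p)$loss,
                        gr = function(p) at(p)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1e9))
    par <- fit$par
  } else if (solver %in% c("sgd", "adam")) {
    par <- par0
    m <- v <- numeric(npar)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- lr_init
    best <- Inf; stall <- 0L
    for (t in seq_len(max_iter)) {
      lg <- mlp_loss_grad(par, shapes, x, y, act, alpha)
      step_lr <- switch(learning_rate,
                        constant = lr,
                        invscaling = lr / t^0.5,
                        adaptive = lr,
                        stop("unknown learning rate schedule: ",
                             learning_rate, call. = FALSE))
      if (learning_rate == "adaptive") {
        if (lg$loss > best - 1e-6) stall <- stall + 1L else stall <- 0L
        if (stall >= 5L) { lr <- lr / 5; stall <- 0L }
      }
      best <- min(best, lg$loss)
      if (solver == "adam") {
        m <- b1 * m + (1 - b1) * lg$grad
        v <- b2 * v + (1 - b2) * lg$grad^2
        par <- par - step_lr * (m / (1 - b1^t)) /
          (sqrt(v / (1 - b2^t)) + eps)
      } else {
        par <- par - step_lr * lg$grad
      }
    }
  } else {
    stop("unknown solver: ", solver, call. = FALSE)
  }
  structure(list(par = par, shapes = shapes, activation = activation,
                 hidden = hidden),
            class = "iaqscreen_mlp")
}

mlp_predict_prob <- function(object, x) {
  layers <- mlp_unpack(object$par, object$shapes)
  a <- mlp_forward(layers, as.matrix(x), mlp_act(object$activation))
  as.vector(a[[length(a)]])
}
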