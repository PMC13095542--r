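# Minimal dense/convolutional network engine.
#
# The estimator networks are small enough that an explicit
# matrix-algebra implementation on the BLAS is both fast and dependency
# free.  Signals move through the convolutional stack as a channel x
# (batch * length) matrix whose columns are grouped in per-sample blocks;
# im2col turns each convolution into one GEMM.

# ---- layout helpers --------------------------------------------------------

# shift columns of M by d within each of B blocks of length L, zero-filling
shift_blocks <- function(M, d, B, L) {
  if (d == 0) return(M)
  idx <- rep(seq_len(L), B) + d
  ok <- idx >= 1 & idx <= L
  src <- idx + rep((seq_len(B) - 1) * L, each = L)
  out <- matrix(0, nrow(M), ncol(M))
  out[, ok] <- M[, src[ok], drop = FALSE]
  out
}

im2col <- function(M, B, L, k = 3) {
  # rows: tap offset major, channel minor -> (C*k) x (B*L)
  do.call(rbind, lapply(seq_len(k) - (k + 1) %/% 2,
                        function(d) shift_blocks(M, d, B, L)))
}

col2im <- function(dXc, B, L, k = 3, C = nrow(dXc) / k) {
  out <- matrix(0, C, B * L)
  offs <- seq_len(k) - (k + 1) %/% 2
  for (j in seq_len(k)) {
    # adjoint of shift by d is shift by -d
    out <- out + shift_blocks(dXc[(j - 1) * C + seq_len(C), , drop = FALSE],
                              -offs[j], B, L)
  }
  out
}

maxpool2_fwd <- function(M, B, L) {
  odd <- seq(1, B * L, by = 2)
  a <- M[, odd, drop = FALSE]; b <- M[, odd + 1, drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a)
}

maxpool2_bwd <- function(dY, cache, B, L) {
  out <- matrix(0, nrow(dY), B * L)
  odd <- seq(1, B * L, by = 2)
  out[, odd] <- dY * cache$take_a
  out[, odd + 1] <- dY * !cache$take_a
  out
}

# ---- network specification -------------------------------------------------

#' Dual-branch network specification
#'
#' The signal branch is a stack of kernel-3 convolutions with ReLU and a
#' factor-2 max-pool after each layer; the scalar branch is an MLP with
#' ReLU hidden layers; both are flattened, concatenated and passed through
#' a fully connected head.  Defaults follow the published architecture:
#' channels 2-16-64-256-512, three 64-unit scalar layers, head
#' 1024-64-output.
#'
#' @param channels integer vector of conv channel sizes (first entry =
#'   input channels).
#' @param mlp_hidden hidden widths of the scalar branch.
#' @param head hidden widths of the fully connected head.
#' @param out_dim output dimension (1 for the chamber-pressure networks,
#'   6 for the circulation network).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(channels = c(2, 16, 64, 256, 512),
                         mlp_hidden = c(64, 64, 64),
                         head = c(1024, 64), out_dim = 1) {
  stopifnot(length(channels) >= 2, out_dim >= 1)
  structure(list(channels = channels, mlp_hidden = mlp_hidden,
                 head = head, out_dim = out_dim),
            class = "network_spec")
}

#' Build an untrained dual-branch network
#'
#' @param spec a [network_spec()].
#' @param input_len signal length; must be divisible by
#'   `2^(number of conv layers)`.
#' @param n_scalar number of scalar-branch inputs.
#' @param seed seed for He-normal initialisation (two builds from the same
#'   seed produce identical networks).
#' @return object of class `nn_model`.
#' @export
build_network <- function(spec, input_len, n_scalar, seed = 1L) {
  n_conv <- length(spec$channels) - 1L
  if (input_len %% 2^n_conv != 0)
    stop("input length ", input_len, " must be divisible by 2^", n_conv)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc,
                                                     sd = sqrt(2 / fan_in)),
                                        nr, nc)
  conv <- list()
  for (l in seq_len(n_conv)) {
    cin <- spec$channels[l]; cout <- spec$channels[l + 1]
    conv[[l]] <- list(W = he(cout, cin * 3, cin * 3), b = numeric(cout))
  }
  mlp <- list()
  dims <- c(n_scalar, spec$mlp_hidden)
  for (l in seq_along(spec$mlp_hidden))
    mlp[[l]] <- list(W = he(dims[l + 1], dims[l], dims[l]),
                     b = numeric(dims[l + 1]))
  flat_len <- spec$channels[n_conv + 1] * input_len / 2^n_conv
  hdims <- c(flat_len + utils::tail(dims, 1), spec$head, spec$out_dim)
  head <- list()
  for (l in seq_len(length(hdims) - 1))
    head[[l]] <- list(W = he(hdims[l + 1], hdims[l], hdims[l]),
                      b = numeric(hdims[l + 1]))
  structure(list(spec = spec, input_len = input_len, n_scalar = n_scalar,
                 conv = conv, mlp = mlp, head = head, seed = seed),
            class = "nn_model")
}

# forward pass; X: (B, C, L) array or (C x B*L) matrix, S: B x n_scalar
# returns list(out = B x out_dim, cache) when train = TRUE
nn_forward <- function(model, X, S, train = FALSE) {
  spec <- model$spec
  n_conv <- length(model$conv)
  if (is.array(X) && length(dim(X)) == 3) {
    B <- dim(X)[1]
    M <- matrix(aperm(X, c(2, 3, 1)), dim(X)[2], B * dim(X)[3])
  } else stop("X must be a (batch, channel, length) array")
  L <- model$input_len
  cache <- list(conv = vector("list", n_conv))
  for (l in seq_len(n_conv)) {
    Xc <- im2col(M, B, L)
    Z <- model$conv[[l]]$W %*% Xc + model$conv[[l]]$b
    A <- Z * (Z > 0)
    pl <- maxpool2_fwd(A, B, L)
    if (train) cache$conv[[l]] <- list(Xc = Xc, relu = Z > 0, pool = pl,
                                       B = B, L = L)
    M <- pl$out
    L <- L / 2
  }
  # flatten: per-sample column of (C_last * L)
  Cl <- nrow(M)
  flat <- matrix(M, Cl * L, B)   # column b holds sample b (length-major)
  # scalar branch (column-major samples)
  A <- t(S)
  cache$mlp <- vector("list", length(model$mlp))
  for (l in seq_along(model$mlp)) {
    Z <- model$mlp[[l]]$W %*% A + model$mlp[[l]]$b
    if (train) cache$mlp[[l]] <- list(inp = A, relu = Z > 0)
    A <- Z * (Z > 0)
  }
  H <- rbind(flat, A)
  cache$head <- vector("list", length(model$head))
  for (l in seq_along(model$head)) {
    Z <- model$head[[l]]$W %*% H + model$head[[l]]$b
    last <- l == length(model$head)
    if (train) cache$head[[l]] <- list(inp = H, relu = if (!last) Z > 0)
    H <- if (last) Z else Z * (Z > 0)
  }
  if (train) {
    cache$flat_len <- Cl * L; cache$B <- B; cache$L_last <- L; cache$Cl <- Cl
    list(out = t(H), cache = cache)
  } else t(H)
}

# backward pass from dOut (B x out_dim); returns gradient list same shape
nn_backward <- function(model, cache, dOut) {
  gr <- list(conv = vector("list", length(model$conv)),
             mlp = vector("list", length(model$mlp)),
             head = vector("list", length(model$head)))
  d <- t(dOut)
  for (l in rev(seq_along(model$head))) {
    cl <- cache$head[[l]]
    gr$head[[l]] <- list(W = d %*% t(cl$inp), b = rowSums(d))
    d <- t(model$head[[l]]$W) %*% d
    if (l > 1) d <- d * cache$head[[l - 1]]$relu
  }
  # split into flat (conv) part and scalar part
  flat_len <- cache$flat_len
  d_flat <- d[seq_len(flat_len), , drop = FALSE]
  d_mlp <- d[-seq_len(flat_len), , drop = FALSE]
  if (length(model$mlp)) {
    # the stored relu mask of layer l applies to its own output
    for (l in rev(seq_along(model$mlp))) {
      d_mlp <- d_mlp * cache$mlp[[l]]$relu
      gr$mlp[[l]] <- list(W = d_mlp %*% t(cache$mlp[[l]]$inp),
                          b = rowSums(d_mlp))
      d_mlp <- t(model$mlp[[l]]$W) %*% d_mlp
    }
  }
  # conv stack
  B <- cache$B
  dM <- matrix(d_flat, cache$Cl, B * cache$L_last)
  for (l in rev(seq_along(model$conv))) {
    cl <- cache$conv[[l]]
    dA <- maxpool2_bwd(dM, cl$pool, cl$B, cl$L)
    dZ <- dA * cl$relu
    gr$conv[[l]] <- list(W = dZ %*% t(cl$Xc), b = rowSums(dZ))
    dXc <- t(model$conv[[l]]$W) %*% dZ
    dM <- col2im(dXc, cl$B, cl$L)
  }
  gr
}

# ---- Adam optimiser --------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  st <- list(t = 0)
  for (part in c("conv", "mlp", "head")) {
    st[[paste0("m_", part)]] <- lapply(model[[part]], zero_like)
    st[[paste0("v_", part)]] <- lapply(model[[part]], zero_like)
  }
  st
}

adam_step <- function(model, gr, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (part in c("conv", "mlp", "head")) {
    for (l in seq_along(model[[part]])) {
      for (p in c("W", "b")) {
        g <- gr[[part]][[l]][[p]]
        m <- st[[paste0("m_", part)]][[l]][[p]] <- beta1 *
          st[[paste0("m_", part)]][[l]][[p]] + (1 - beta1) * g
        v <- st[[paste0("v_", part)]][[l]][[p]] <- beta2 *
          st[[paste0("v_", part)]][[l]][[p]] + (1 - beta2) * g^2
        model[[part]][[l]][[p]] <- model[[part]][[l]][[p]] -
          lr * (m / bc1) / (sqrt(v / bc2) + eps)
      }
    }
  }
  list(model = model, state = st)
}

#' Training configuration
#'
#' @param lr learning rate (published value 0.001).
#' @param batch minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience in epochs without validation
#'   improvement; the best-validation weights are returned.
#' @param seed shuffling/initialisation seed.
#' @return object of class `training_config`.
#' @export
training_config <- function(lr = 1e-3, batch = 64, epochs = 150,
                            patience = 20, seed = 1L) {
  stopifnot(lr > 0, batch >= 1, epochs >= 1)
  structure(list(lr = lr, batch = batch, epochs = epochs,
                 patience = patience, seed = as.integer(seed)),
            class = "training_config")
}

# train one network on (X, S, Y) with an (Xv, Sv, Yv) validation set;
# mean-squared-error loss, Adam, early stopping with best checkpoint
nn_train <- function(model, X, S, Y, Xv, Sv, Yv, config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  st <- adam_init(model)
  n <- dim(X)[1]
  best <- list(loss = Inf, model = model, epoch = 0L)
  history <- numeric(0)
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1, n)]
      fw <- nn_forward(model, X[idx, , , drop = FALSE],
                       S[idx, , drop = FALSE], train = TRUE)
      err <- fw$out - Y[idx, , drop = FALSE]
      gr <- nn_backward(model, fw$cache, 2 * err / length(err))
      up <- adam_step(model, gr, st, lr = config$lr)
      model <- up$model; st <- up$state
      if (!is.finite(sum(err^2)))
        stop("training diverged (non-finite loss) at epoch ", ep)
    }
    pv <- nn_forward(model, Xv, Sv)
    vloss <- mean((pv - Yv)^2)
    history <- c(history, vloss)
    if (vloss < best$loss) {
      best <- list(loss = vloss, model = model, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(model = best$model, val_loss = best$loss, best_epoch = best$epoch,
       history = history)
}
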