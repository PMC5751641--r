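# Minimal neural-network machinery shared by the trigger and argument
# models: a dense ReLU stack with inverted dropout and a softmax
# cross-entropy head, trained with Adadelta. Everything is plain matrix
# algebra on the caller's RNG stream, so a run is bit-reproducible from its
# seed in single-threaded BLAS.

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot-uniform dense parameters for layer sizes c(in, hidden..., out).
dense_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass; hidden layers are ReLU with inverted dropout at train time.
dense_forward <- function(params, X, dropout = 0, train = FALSE) {
  L <- length(params$W)
  A <- X
  As <- vector("list", L)   # input to each layer
  Pre <- vector("list", L)  # pre-dropout activation (for ReLU grad)
  Masks <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    As[[l]] <- A
    Z <- A %*% params$W[[l]] + rep(params$b[[l]], each = nrow(A))
    A <- relu(Z)
    Pre[[l]] <- A
    if (train && dropout > 0) {
      m <- matrix(stats::runif(length(A)) >= dropout, nrow(A)) / (1 - dropout)
      A <- A * m
      Masks[[l]] <- m
    }
  }
  As[[L]] <- A
  logits <- A %*% params$W[[L]] + rep(params$b[[L]], each = nrow(A))
  list(logits = logits, As = As, Pre = Pre, Masks = Masks)
}

# Backward pass from d(loss)/d(logits); returns parameter grads and dX.
dense_backward <- function(params, cache, dlogits) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dlogits
  for (l in seq(L, 1L)) {
    gW[[l]] <- crossprod(cache$As[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params$W[[l]])
      if (!is.null(cache$Masks[[l - 1L]])) delta <- delta * cache$Masks[[l - 1L]]
      delta <- delta * (cache$Pre[[l - 1L]] > 0)
    } else {
      delta <- delta %*% t(params$W[[l]])
    }
  }
  list(W = gW, b = gb, dX = delta)
}

# Mean cross-entropy and d(loss)/d(logits) for integer class targets.
softmax_xent <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  ll <- -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  d <- P
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  list(loss = ll, dlogits = d / n, probs = P)
}

# ---- Adadelta ---------------------------------------------------------

adadelta_state <- function(param) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(Eg2 = zero(param), Edx2 = zero(param))
}

# One Adadelta update on a single array; returns list(param, state).
adadelta_apply <- function(param, grad, state, rho = 0.95, eps = 1e-6) {
  state$Eg2 <- rho * state$Eg2 + (1 - rho) * grad^2
  dx <- -sqrt(state$Edx2 + eps) / sqrt(state$Eg2 + eps) * grad
  state$Edx2 <- rho * state$Edx2 + (1 - rho) * dx^2
  list(param = param + dx, state = state)
}

# Update a nested list of parameters in lockstep with its state.
adadelta_step <- function(params, grads, state, rho = 0.95, eps = 1e-6) {
  walk <- function(p, g, eg, ed) {
    if (is.list(p)) {
      out_p <- p; out_eg <- eg; out_ed <- ed
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], eg[[i]], ed[[i]])
        out_p[[i]] <- r$p; out_eg[[i]] <- r$eg; out_ed[[i]] <- r$ed
      }
      list(p = out_p, eg = out_eg, ed = out_ed)
    } else {
      eg <- rho * eg + (1 - rho) * g^2
      dx <- -sqrt(ed + eps) / sqrt(eg + eps) * g
      ed <- rho * ed + (1 - rho) * dx^2
      list(p = p + dx, eg = eg, ed = ed)
    }
  }
  r <- walk(params, grads, state$Eg2, state$Edx2)
  list(params = r$p, state = list(Eg2 = r$eg, Edx2 = r$ed))
}

# Accumulate per-row gradient contributions into a table-shaped matrix.
accumulate_rows <- function(G, idx, contrib) {
  r <- rowsum(contrib, idx)
  rows <- as.integer(rownames(r))
  G[rows, ] <- G[rows, ] + r
  G
}

# Seeded minibatch index blocks covering 1..n in shuffled order.
minibatches <- function(n, batch) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch))
}
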