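# Differentiable primitives for the 3-D segmentation network.
# Arrays are [D,H,W,C]; convolution weights are (27*Cin x Cout) matrices in
# im2col layout (column = offset * Cin + channel); heads are (Cin x K).
# Forward functions return caches sufficient for the manual backward pass.

nn_relu_fwd <- function(x) x * (x > 0)
nn_relu_bwd <- function(pre, gy) gy * (pre > 0)

# Instance normalization: per-channel standardization over the spatial
# voxels of the (single-patch) activation, with learned gain/offset.
nn_inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xh, 2, gamma, "*"), 2, beta, "+")
  list(y = array(y, d), xh = xh, istd = istd)
}
nn_inorm_bwd <- function(cache, gamma, gy) {
  d <- dim(gy); n <- prod(d[1:3]); C <- d[4]
  g <- matrix(gy, n, C)
  xh <- cache$xh
  ggamma <- colSums(g * xh)
  gbeta <- colSums(g)
  gh <- sweep(g, 2, gamma, "*")
  m1 <- colMeans(gh)
  m2 <- colMeans(gh * xh)
  gx <- sweep(sweep(gh, 2, m1) - sweep(xh, 2, m2, "*"), 2, cache$istd, "*")
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# One conv unit: 3x3x3 conv (+ optional instance norm) + ReLU.
nn_unit_fwd <- function(x, p, norm) {
  y <- cpp_conv3d_fwd(x, p$W, p$b)
  if (norm == "instance") {
    nc <- nn_inorm_fwd(y, p$gamma, p$beta)
    list(y = nn_relu_fwd(nc$y), x = x, pre = nc$y, norm_cache = nc)
  } else {
    list(y = nn_relu_fwd(y), x = x, pre = y)
  }
}
nn_unit_bwd <- function(cache, p, norm, gy) {
  g <- nn_relu_bwd(cache$pre, gy)
  grads <- list()
  if (norm == "instance") {
    nb <- nn_inorm_bwd(cache$norm_cache, p$gamma, g)
    grads$gamma <- nb$ggamma
    grads$beta <- nb$gbeta
    g <- nb$gx
  }
  cb <- cpp_conv3d_bwd(cache$x, p$W, g)
  grads$W <- cb$gW
  grads$b <- as.numeric(cb$gb)
  list(gx = cb$gx, grads = grads)
}

nn_pool_fwd <- function(x) {
  out <- cpp_maxpool3d_fwd(x)
  out$din <- dim(x)
  out
}
nn_pool_bwd <- function(cache, gy) cpp_maxpool3d_bwd(cache$arg, gy, cache$din)

# Trilinear x2 upsampling as a separable linear map (align_corners = FALSE);
# the backward pass is the transpose applied per axis.
nn_up_mat <- function(n) {
  P <- matrix(0, 2L * n, n)
  for (o in seq_len(2L * n)) {
    src <- (o - 0.5) / 2 - 0.5
    lo <- floor(src); w <- src - lo
    lo0 <- min(max(lo, 0), n - 1); hi0 <- min(max(lo + 1, 0), n - 1)
    P[o, lo0 + 1] <- P[o, lo0 + 1] + (1 - w)
    P[o, hi0 + 1] <- P[o, hi0 + 1] + w
  }
  P
}
nn_apply_ax <- function(P, x, axis) {
  d <- dim(x)
  if (axis == 1L) {
    array(P %*% matrix(x, d[1], prod(d[-1])), c(nrow(P), d[-1]))
  } else {
    perm <- seq_along(d); perm[c(1, axis)] <- c(axis, 1L)
    y <- aperm(x, perm)
    dy <- dim(y)
    y <- array(P %*% matrix(y, dy[1], prod(dy[-1])), c(nrow(P), dy[-1]))
    aperm(y, perm)
  }
}
nn_up_fwd <- function(x) {
  y <- nn_apply_ax(nn_up_mat(dim(x)[1]), x, 1L)
  y <- nn_apply_ax(nn_up_mat(dim(x)[2]), y, 2L)
  nn_apply_ax(nn_up_mat(dim(x)[3]), y, 3L)
}
nn_up_bwd <- function(din, gy) {
  y <- nn_apply_ax(t(nn_up_mat(din[1])), gy, 1L)
  y <- nn_apply_ax(t(nn_up_mat(din[2])), y, 2L)
  nn_apply_ax(t(nn_up_mat(din[3])), y, 3L)
}

# Voxel-wise softmax + cross-entropy against integer labels (0-based).
# Returns mean loss and the gradient w.r.t. the logits.
nn_softmax <- function(logits) {
  d <- dim(logits); K <- d[4]
  L <- matrix(logits, ncol = K)
  m <- L[, 1]
  for (k in seq_len(K)[-1]) m <- pmax(m, L[, k])
  E <- exp(L - m)
  E / rowSums(E)
}
nn_xent <- function(logits, labels_vec) {
  d <- dim(logits)
  P <- nn_softmax(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), labels_vec + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, g = array(G / n, d))
}

# He-scaled orthogonal initialization: orthonormal columns (QR of a
# Gaussian matrix) scaled to the He column norm sqrt(2). Orthogonality
# maximizes the diversity of the random feature basis, which matters when
# a layer has only a handful of channels; plain Gaussian columns can come
# out nearly collinear by bad luck.
nn_he_init <- function(cin, cout) {
  n <- 27L * cin
  if (cout <= n) {
    A <- matrix(rnorm(n * cout), n, cout)
    Q <- qr.Q(qr(A))
    # fix signs so the decomposition is unique given the draw
    Q <- sweep(Q, 2, sign(diag(qr.R(qr(A)))), "*")
    Q * sqrt(2)
  } else {
    matrix(rnorm(n * cout, 0, sqrt(2 / n)), n, cout)
  }
}

# Dirac/He hybrid: the first min(cin, cout) output channels start as
# identity (centered delta) kernels copying input channel q, with their He
# noise scaled down; the remaining channels are plain He. Identity-
# preserving initialization keeps unsmoothed intensity available to the
# decision layers from the first iteration — which matters under short
# training budgets — while the He channels provide diverse random features.
nn_dirac_he_init <- function(cin, cout, noise = 0.25) {
  W <- nn_he_init(cin, cout)
  center <- 13L  # offset (1,1,1) of the 3x3x3 kernel, i + 3j + 9k
  for (q in seq_len(min(cin, cout))) {
    W[, q] <- W[, q] * noise
    W[center * cin + q, q] <- W[center * cin + q, q] + 1
  }
  W
}

nn_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}
nn_adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
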