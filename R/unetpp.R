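#' Network configuration for the 3-D nested U-Net
#'
#' The network is the nested (UNet++) encoder-decoder: nodes `X(i,j)` for
#' `i + j <= n_levels - 1`, where `X(i,0)` is the encoder column and every
#' decoder node receives the 2x-upsampled `X(i+1,j-1)` concatenated with all
#' same-level predecessors `X(i,0..j-1)`, each passed through its own
#' convolutional skip unit. With deep supervision on, every top-row node
#' `X(0,j)`, `j >= 1`, carries a 1x1x1 softmax head.
#'
#' @param n_levels number of resolution levels (>= 2).
#' @param base_channels channels at the top level; doubled per level.
#' @param n_labels number of classes including background (>= 2).
#' @param deep_supervision logical; one head per top-row decoder node.
#' @param normalization `"none"` (default) or `"instance"` inside conv
#'   units. With batch size 1 and small step budgets at the default Adam
#'   rate, normalization layers cap the attainable logit magnitude, so the
#'   plain conv + ReLU unit is the default; instance normalization is
#'   available for long training schedules.
#' @param init convolution weight initialization: `"he"` (default) or
#'   `"he_dirac"` (identity-preserving Dirac kernels plus scaled-down He
#'   noise on the leading channels). Plain He is the default: with a
#'   three-class intensity ordering, sign-diverse random features let the
#'   zero-initialized heads separate a middle-intensity class within short
#'   step budgets, which an intensity-passthrough basis cannot.
#' @param block_units 3x3x3 conv units per conv block (1 or 2). Two units
#'   is the reference UNet++ block; one unit halves the compute and the
#'   minimum receptive field, which sharpens boundaries under short
#'   training budgets.
#' @param in_channels input channels (1 for T1-weighted MRI).
#' @return list of class `network_config`.
#' @export
network_config <- function(n_levels = 4L, base_channels = 16L,
                           n_labels = 2L, deep_supervision = TRUE,
                           normalization = c("none", "instance"),
                           init = c("he", "he_dirac"),
                           block_units = 2L,
                           in_channels = 1L) {
  normalization <- match.arg(normalization)
  init <- match.arg(init)
  stopifnot(n_levels >= 2L, base_channels >= 2L, n_labels >= 2L,
            in_channels >= 1L, block_units %in% c(1L, 2L))
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 n_labels = as.integer(n_labels),
                 deep_supervision = isTRUE(deep_supervision),
                 normalization = normalization, init = init,
                 block_units = as.integer(block_units),
                 in_channels = as.integer(in_channels)),
            class = "network_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size fixed at 1 (one patch per iteration).
#' @param n_iterations number of optimization steps.
#' @param patch_size cubic patch edge in voxels; must be divisible by
#'   `2^(n_levels - 1)`.
#' @param split_ratio train:validation ratio within the non-test data
#'   (default 9.5:0.5).
#' @param beta1,beta2 Adam moment decay rates. `beta2 = 0.99` by default:
#'   the second-moment estimate then adapts within tens of iterations,
#'   which matters for the short schedules this package runs; 0.999 is the
#'   conventional long-schedule value.
#' @param prior_bias_init initialize the (otherwise zero) head biases to
#'   the log class frequencies of the training labels before the first
#'   step (default TRUE). Per-parameter Adam movement is bounded by
#'   `learning_rate * n_iterations`, so biases can barely move during a
#'   short schedule; starting them at the log priors spends the step
#'   budget on discrimination instead of on re-learning class frequencies
#'   through the weights. Applied only when `patches` is a list.
#' @param seed RNG seed making patch sampling and initialization
#'   reproducible.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 1L,
                         n_iterations = 300L, patch_size = 96L,
                         split_ratio = c(9.5, 0.5),
                         beta1 = 0.9, beta2 = 0.99,
                         prior_bias_init = TRUE, seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size == 1L, n_iterations >= 0,
            patch_size >= 4L, length(split_ratio) == 2L, all(split_ratio > 0),
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1)
  structure(list(learning_rate = learning_rate, batch_size = 1L,
                 n_iterations = as.integer(n_iterations),
                 patch_size = as.integer(patch_size),
                 split_ratio = split_ratio,
                 beta1 = beta1, beta2 = beta2,
                 prior_bias_init = isTRUE(prior_bias_init),
                 seed = as.integer(seed)),
            class = "train_config")
}

unet_node_key <- function(i, j) paste0("X", i, ".", j)
unet_channels <- function(config, i) config$base_channels * 2L^i

unet_heads <- function(config) {
  if (config$deep_supervision) seq_len(config$n_levels - 1L) else config$n_levels - 1L
}

unit_params <- function(cin, cout, norm, init = "he") {
  W <- if (init == "he_dirac") nn_dirac_he_init(cin, cout)
       else nn_he_init(cin, cout)
  p <- list(W = W, b = numeric(cout))
  if (norm == "instance") {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  }
  p
}

#' Build an untrained nested U-Net model
#'
#' Convolution weights use the configured initialization (He by default);
#' the 1x1x1 heads start at zero so the initial prediction is uniform and
#' early optimization is driven by the loss rather than by the random
#' initialization.
#'
#' @param config [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `unetpp_model` with elements `config`, `params`
#'   (named flat list), and `training_log`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  L <- config$n_levels
  norm <- config$normalization
  init <- if (is.null(config$init)) "he" else config$init
  params <- list()
  add <- function(prefix, p) {
    for (nm in names(p)) params[[paste0(prefix, ".", nm)]] <<- p[[nm]]
  }
  for (j in 0:(L - 1L)) {
    for (i in 0:(L - 1L - j)) {
      ch <- unet_channels(config, i)
      key <- unet_node_key(i, j)
      cin_block <- if (j == 0L) {
        if (i == 0L) config$in_channels else unet_channels(config, i - 1L)
      } else {
        (j + 1L) * ch
      }
      if (j > 0L) {
        for (p_ in 0:(j - 1L))
          add(paste0(key, ".sk", p_), unit_params(ch, ch, norm, init))
        add(paste0(key, ".up"),
            unit_params(unet_channels(config, i + 1L), ch, norm, init))
      }
      add(paste0(key, ".u1"), unit_params(cin_block, ch, norm, init))
      if (is.null(config$block_units) || config$block_units == 2L)
        add(paste0(key, ".u2"), unit_params(ch, ch, norm, init))
    }
  }
  for (j in unet_heads(config)) {
    params[[paste0("H", j, ".W")]] <-
      matrix(0, config$base_channels, config$n_labels)
    params[[paste0("H", j, ".b")]] <- numeric(config$n_labels)
  }
  structure(list(config = config, params = params,
                 training_log = data.frame()),
            class = "unetpp_model")
}

# Forward pass on one patch; returns head logits and caches for backprop.
unet_forward <- function(model, x, with_cache = TRUE) {
  config <- model$config
  params <- model$params
  norm <- config$normalization
  L <- config$n_levels
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  ps <- dim(x)[1:3]
  if (any(ps %% 2L^(L - 1L) != 0L))
    stop("patch size must be divisible by 2^(n_levels-1)")
  vals <- list()
  caches <- list()
  getp <- function(prefix) {
    nm <- grep(paste0("^", gsub("\\.", "\\\\.", prefix), "\\."),
               names(params), value = TRUE)
    out <- params[nm]
    names(out) <- sub(paste0(prefix, "."), "", nm, fixed = TRUE)
    out
  }
  for (j in 0:(L - 1L)) {
    for (i in 0:(L - 1L - j)) {
      key <- unet_node_key(i, j)
      if (j == 0L) {
        if (i == 0L) {
          inp <- x
        } else {
          pl <- nn_pool_fwd(vals[[unet_node_key(i - 1L, 0L)]])
          caches[[paste0(key, ".pool")]] <- pl
          inp <- pl$y
        }
      } else {
        parts <- vector("list", j + 1L)
        for (p_ in 0:(j - 1L)) {
          u <- nn_unit_fwd(vals[[unet_node_key(i, p_)]],
                           getp(paste0(key, ".sk", p_)), norm)
          caches[[paste0(key, ".sk", p_)]] <- u
          parts[[p_ + 1L]] <- u$y
        }
        below <- vals[[unet_node_key(i + 1L, j - 1L)]]
        upsampled <- nn_up_fwd(below)
        caches[[paste0(key, ".updim")]] <- dim(below)
        uu <- nn_unit_fwd(upsampled, getp(paste0(key, ".up")), norm)
        caches[[paste0(key, ".up")]] <- uu
        parts[[j + 1L]] <- uu$y
        widths <- vapply(parts, function(p) dim(p)[4], integer(1))
        inp <- array(unlist(parts, use.names = FALSE),
                     c(dim(parts[[1]])[1:3], sum(widths)))
        caches[[paste0(key, ".widths")]] <- widths
      }
      u1 <- nn_unit_fwd(inp, getp(paste0(key, ".u1")), norm)
      caches[[paste0(key, ".u1")]] <- u1
      if (is.null(config$block_units) || config$block_units == 2L) {
        u2 <- nn_unit_fwd(u1$y, getp(paste0(key, ".u2")), norm)
        caches[[paste0(key, ".u2")]] <- u2
        vals[[key]] <- u2$y
      } else {
        vals[[key]] <- u1$y
      }
    }
  }
  heads <- list()
  for (j in unet_heads(config)) {
    feat <- vals[[unet_node_key(0L, j)]]
    d <- dim(feat)
    W <- params[[paste0("H", j, ".W")]]
    lg <- matrix(feat, ncol = d[4]) %*% W
    lg <- sweep(lg, 2, params[[paste0("H", j, ".b")]], "+")
    heads[[as.character(j)]] <- array(lg, c(d[1:3], ncol(W)))
  }
  out <- list(heads = heads, vals = vals)
  if (with_cache) out$caches <- caches
  out
}

# Backward pass; ghead is a named list (by head j) of gradients w.r.t. the
# head logits. Returns the named list of parameter gradients.
unet_backward <- function(model, fwd, ghead) {
  config <- model$config
  params <- model$params
  norm <- config$normalization
  L <- config$n_levels
  caches <- fwd$caches
  vals <- fwd$vals
  grads <- list()
  gval <- list()
  addg <- function(prefix, g) {
    for (nm in names(g)) {
      full <- paste0(prefix, ".", nm)
      grads[[full]] <<- if (is.null(grads[[full]])) g[[nm]] else grads[[full]] + g[[nm]]
    }
  }
  addv <- function(key, g) {
    gval[[key]] <<- if (is.null(gval[[key]])) g else gval[[key]] + g
  }
  getp <- function(prefix) {
    nm <- grep(paste0("^", gsub("\\.", "\\\\.", prefix), "\\."),
               names(params), value = TRUE)
    out <- params[nm]
    names(out) <- sub(paste0(prefix, "."), "", nm, fixed = TRUE)
    out
  }
  for (j in names(ghead)) {
    key <- unet_node_key(0L, as.integer(j))
    feat <- vals[[key]]
    d <- dim(feat)
    G <- matrix(ghead[[j]], ncol = config$n_labels)
    Fm <- matrix(feat, ncol = d[4])
    grads[[paste0("H", j, ".W")]] <- crossprod(Fm, G)
    grads[[paste0("H", j, ".b")]] <- colSums(G)
    addv(key, array(tcrossprod(G, params[[paste0("H", j, ".W")]]), d))
  }
  for (j in (L - 1L):0) {
    for (i in (L - 1L - j):0) {
      key <- unet_node_key(i, j)
      g <- gval[[key]]
      if (is.null(g)) next
      if (is.null(config$block_units) || config$block_units == 2L) {
        b2 <- nn_unit_bwd(caches[[paste0(key, ".u2")]],
                          getp(paste0(key, ".u2")), norm, g)
        addg(paste0(key, ".u2"), b2$grads)
        g <- b2$gx
      }
      b1 <- nn_unit_bwd(caches[[paste0(key, ".u1")]],
                        getp(paste0(key, ".u1")), norm, g)
      addg(paste0(key, ".u1"), b1$grads)
      gin <- b1$gx
      if (j == 0L) {
        if (i > 0L) {
          gx <- nn_pool_bwd(caches[[paste0(key, ".pool")]], gin)
          addv(unet_node_key(i - 1L, 0L), gx)
        }
      } else {
        widths <- caches[[paste0(key, ".widths")]]
        offs <- c(0L, cumsum(widths))
        for (p_ in 0:(j - 1L)) {
          gpart <- gin[, , , (offs[p_ + 1L] + 1L):offs[p_ + 2L], drop = FALSE]
          bs <- nn_unit_bwd(caches[[paste0(key, ".sk", p_)]],
                            getp(paste0(key, ".sk", p_)), norm, gpart)
          addg(paste0(key, ".sk", p_), bs$grads)
          addv(unet_node_key(i, p_), bs$gx)
        }
        gup <- gin[, , , (offs[j + 1L] + 1L):offs[j + 2L], drop = FALSE]
        bu <- nn_unit_bwd(caches[[paste0(key, ".up")]],
                          getp(paste0(key, ".up")), norm, gup)
        addg(paste0(key, ".up"), bu$grads)
        addv(unet_node_key(i + 1L, j - 1L),
             nn_up_bwd(caches[[paste0(key, ".updim")]], bu$gx))
      }
    }
  }
  grads
}

#' Train the nested U-Net on a patch stream
#'
#' One uniformly sampled patch per iteration (batch size 1), voxel-wise
#' cross-entropy averaged with equal weights over all deep-supervision
#' heads, Adam updates. The loss trace (total and per head) is appended to
#' the model's `training_log`.
#'
#' @param model [build_model()] output.
#' @param patches either a list of `list(image =, labels =)` 3-D array
#'   pairs (patches are cropped from them at random) or a function
#'   `function(iter)` returning such a pair already at patch size.
#' @param config [train_config()].
#' @return the trained `unetpp_model`.
#' @export
train_model <- function(model, patches, config = train_config()) {
  stopifnot(inherits(model, "unetpp_model"), inherits(config, "train_config"))
  K <- model$config$n_labels
  div <- 2L^(model$config$n_levels - 1L)
  if (config$patch_size %% div != 0L)
    stop("patch_size must be divisible by 2^(n_levels-1)")
  if (is.list(patches)) {
    for (p in patches) {
      if (!all(dim(p$image) == dim(p$labels)))
        stop("image/label patch shape mismatch")
      if (max(p$labels) >= K)
        stop("label id >= n_labels in training data")
    }
  }
  if (is.list(patches) && isTRUE(config$prior_bias_init)) {
    counts <- numeric(K)
    for (p in patches) counts <- counts + tabulate(p$labels + 1L, K)
    logpri <- log(pmax(counts, 1) / sum(counts))
    logpri <- logpri - mean(logpri)
    for (j in unet_heads(model$config))
      model$params[[paste0("H", j, ".b")]] <- logpri
  }
  set.seed(config$seed)
  adam <- nn_adam_init(model$params)
  log_ <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    pair <- if (is.function(patches)) {
      patches(it)
    } else {
      sample_patch_pair(patches[[sample.int(length(patches), 1L)]],
                        config$patch_size)
    }
    if (max(pair$labels) >= K) stop("label id >= n_labels in training data")
    fwd <- unet_forward(model, pair$image)
    yvec <- as.integer(pair$labels)
    nh <- length(fwd$heads)
    ghead <- list()
    head_losses <- numeric(nh)
    for (h in seq_along(fwd$heads)) {
      ce <- nn_xent(fwd$heads[[h]], yvec)
      head_losses[h] <- ce$loss
      ghead[[names(fwd$heads)[h]]] <- ce$g / nh
    }
    grads <- unet_backward(model, fwd, ghead)
    st <- nn_adam_step(model$params, grads, adam, config$learning_rate,
                       beta1 = config$beta1 %||% 0.9,
                       beta2 = config$beta2 %||% 0.99)
    model$params <- st$params
    adam <- st$state
    if (any(!is.finite(head_losses))) stop("non-finite training loss")
    log_[[it]] <- c(iteration = it, loss = mean(head_losses),
                    setNames(head_losses, paste0("head", names(fwd$heads))))
  }
  if (config$n_iterations > 0L) {
    new_log <- as.data.frame(do.call(rbind, log_))
    model$training_log <- rbind(model$training_log, new_log)
  }
  model
}

# Uniformly crop a patch-size cube (and its labels) from a volume pair.
sample_patch_pair <- function(pair, patch_size) {
  d <- dim(pair$image)
  if (any(d < patch_size)) stop("volume smaller than patch size")
  o <- vapply(d, function(n) sample.int(n - patch_size + 1L, 1L), integer(1))
  ix <- lapply(1:3, function(a) o[a] + seq_len(patch_size) - 1L)
  list(image = pair$image[ix[[1]], ix[[2]], ix[[3]]],
       labels = pair$labels[ix[[1]], ix[[2]], ix[[3]]])
}

#' Per-voxel class probabilities for one patch
#'
#' @param model trained [build_model()] output.
#' @param patch 3-D intensity array at a patch-compatible shape.
#' @param head supervision head index (1-based over the top-row decoder
#'   nodes) or `"last"` for the deepest nested output.
#' @return 4-D array `[D,H,W,n_labels]` of probabilities summing to 1 per
#'   voxel.
#' @export
predict_patch <- function(model, patch, head = "last") {
  fwd <- unet_forward(model, patch, with_cache = FALSE)
  keys <- names(fwd$heads)
  key <- if (identical(head, "last")) keys[length(keys)] else {
    if (!as.character(head) %in% keys) stop("unknown head index: ", head)
    as.character(head)
  }
  logits <- fwd$heads[[key]]
  array(nn_softmax(logits), dim(logits))
}

#' Save / load a model checkpoint
#'
#' Weights are serialized with `saveRDS`; a JSON sidecar (`<path>.json`)
#' records the network configuration and the tail of the training log.
#'
#' @param model `unetpp_model`.
#' @param path checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config),
               n_parameters = sum(vapply(model$params, length, numeric(1))),
               final_loss = if (nrow(model$training_log))
                 tail(model$training_log$loss, 1) else NA)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unetpp_model"))
  model
}
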