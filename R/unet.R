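#' Segmenter architecture configuration
#'
#' Describes the 2-D encoder--decoder ("U" topology) segmenter: encoder block
#' style, number of down/up-sampling stages, width of the first stage, input
#' plane size and class count. The encoder family modulates the block style of
#' both paths: `vgg-like` plain double convolutions, `resnet-like` residual
#' blocks, `inception-like` parallel 3x3/1x1 branches, `efficient-like`
#' depthwise-separable convolutions (fewest parameters).
#'
#' @param encoder_family block style tag.
#' @param depth number of resolution stages (input size must be divisible by
#'   `2^depth`).
#' @param base_channels channel width of the first stage.
#' @param input_size input plane size in pixels (square slices).
#' @param n_classes number of softmax classes (>= 2; background + target).
#' @return Object of class `model_config`.
#' @export
model_config <- function(encoder_family = c("efficient-like", "vgg-like",
                                            "resnet-like", "inception-like"),
                         depth = 2L, base_channels = 8L, input_size = 32L,
                         n_classes = 2L) {
  encoder_family <- match.arg(encoder_family)
  depth <- as.integer(depth); input_size <- as.integer(input_size)
  if (n_classes < 2L) stop_param("n_classes must be >= 2")
  if (depth < 1L) stop_param("depth must be >= 1")
  if (input_size %% (2L^depth) != 0L)
    stop_param("config error: input_size (%d) must be divisible by 2^depth (%d)",
               input_size, 2L^depth)
  structure(list(encoder_family = encoder_family, depth = depth,
                 base_channels = as.integer(base_channels),
                 input_size = input_size, n_classes = as.integer(n_classes)),
            class = "model_config")
}

#' Training protocol configuration
#'
#' Slice-wise training protocol: adaptive-moment (Adam) optimization with step
#' size 0.001 and moment decays 0.9/0.999, loss = categorical cross-entropy +
#' soft-Jaccard, early stopping on the validation loss, and restoration of the
#' best-validation-epoch weights.
#'
#' @param batch_size slices per optimization step.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation-loss improvement before stopping.
#' @param learning_rate,beta1,beta2 Adam parameters.
#' @param iou_target optional validation-IoU level at which training stops
#'   early (quality-based stop in addition to the patience rule); `NULL`
#'   disables it.
#' @param seed integer seed controlling initialization order and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, max_epochs = 25L, patience = 10L,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         iou_target = NULL, seed = 1L) {
  if (batch_size < 1L) stop_param("batch_size must be >= 1")
  if (patience > max_epochs) stop_param("patience must be <= max_epochs")
  if (!is.null(iou_target) && (iou_target <= 0 || iou_target > 1))
    stop_param("iou_target must lie in (0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 iou_target = iou_target,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- parameter initialization ------------------------------------------------

he_conv3 <- function(cin, cout) {
  array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), c(3, 3, cin, cout))
}
he_conv1 <- function(cin, cout) {
  matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}
he_dw3 <- function(c_) matrix(rnorm(9 * c_, 0, sqrt(2 / 9)), 9, c_)

block_params <- function(family, cin, cout) {
  switch(family,
    "vgg-like" = list(
      c1.W = he_conv3(cin, cout), c1.b = numeric(cout),
      c2.W = he_conv3(cout, cout), c2.b = numeric(cout)),
    "resnet-like" = list(
      c1.W = he_conv3(cin, cout), c1.b = numeric(cout),
      c2.W = he_conv3(cout, cout), c2.b = numeric(cout),
      p.W = he_conv1(cin, cout), p.b = numeric(cout)),
    "inception-like" = {
      h1 <- ceiling(cout / 2); h2 <- cout - h1
      list(b1.W = he_conv3(cin, h1), b1.b = numeric(h1),
           b2.W = he_conv1(cin, h2), b2.b = numeric(h2),
           c2.W = he_conv3(cout, cout), c2.b = numeric(cout))
    },
    "efficient-like" = list(
      d1.W = he_dw3(cin), d1.b = numeric(cin),
      p1.W = he_conv1(cin, cout), p1.b = numeric(cout),
      d2.W = he_dw3(cout), d2.b = numeric(cout),
      p2.W = he_conv1(cout, cout), p2.b = numeric(cout)))
}

# --- block forward / backward ------------------------------------------------

relu <- function(X) { X[X < 0] <- 0; X }

block_fwd <- function(P, family, X) {
  if (family == "vgg-like") {
    f1 <- conv3_fwd(X, P$c1.W, P$c1.b); A1 <- relu(f1$Y)
    f2 <- conv3_fwd(A1, P$c2.W, P$c2.b); Y <- relu(f2$Y)
    list(Y = Y, cache = list(X = X, M1 = f1$M, A1 = A1, M2 = f2$M, Y = Y))
  } else if (family == "resnet-like") {
    f1 <- conv3_fwd(X, P$c1.W, P$c1.b); A1 <- relu(f1$Y)
    f2 <- conv3_fwd(A1, P$c2.W, P$c2.b)
    fp <- conv1_fwd(X, P$p.W, P$p.b)
    Y <- relu(f2$Y + fp$Y)
    list(Y = Y, cache = list(X = X, M1 = f1$M, A1 = A1, M2 = f2$M,
                             Xm = fp$Xm, Y = Y))
  } else if (family == "inception-like") {
    f1 <- conv3_fwd(X, P$b1.W, P$b1.b); A1 <- relu(f1$Y)
    f2 <- conv1_fwd(X, P$b2.W, P$b2.b); A2 <- relu(f2$Y)
    Ccat <- cat_channels(A1, A2)
    f3 <- conv3_fwd(Ccat, P$c2.W, P$c2.b); Y <- relu(f3$Y)
    list(Y = Y, cache = list(X = X, M1 = f1$M, A1 = A1, Xm = f2$Xm, A2 = A2,
                             Ccat = Ccat, M3 = f3$M, Y = Y))
  } else {  # efficient-like
    f1 <- dw3_fwd(X, P$d1.W, P$d1.b)
    g1 <- conv1_fwd(f1$Y, P$p1.W, P$p1.b); A1 <- relu(g1$Y)
    f2 <- dw3_fwd(A1, P$d2.W, P$d2.b)
    g2 <- conv1_fwd(f2$Y, P$p2.W, P$p2.b); Y <- relu(g2$Y)
    list(Y = Y, cache = list(X = X, M1 = f1$M, Z1 = f1$Y, Xm1 = g1$Xm,
                             A1 = A1, M2 = f2$M, Z2 = f2$Y, Xm2 = g2$Xm,
                             Y = Y))
  }
}

block_bwd <- function(P, family, cache, dY) {
  G <- list()
  g <- dY * (cache$Y > 0)
  if (family == "vgg-like") {
    b2 <- conv3_bwd(cache$A1, P$c2.W, cache$M2, g)
    G$c2.W <- b2$dW; G$c2.b <- b2$db
    b1 <- conv3_bwd(cache$X, P$c1.W, cache$M1, b2$dX * (cache$A1 > 0))
    G$c1.W <- b1$dW; G$c1.b <- b1$db
    dX <- b1$dX
  } else if (family == "resnet-like") {
    b2 <- conv3_bwd(cache$A1, P$c2.W, cache$M2, g)
    G$c2.W <- b2$dW; G$c2.b <- b2$db
    bp <- conv1_bwd(cache$X, P$p.W, cache$Xm, g)
    G$p.W <- bp$dW; G$p.b <- bp$db
    b1 <- conv3_bwd(cache$X, P$c1.W, cache$M1, b2$dX * (cache$A1 > 0))
    G$c1.W <- b1$dW; G$c1.b <- b1$db
    dX <- b1$dX + bp$dX
  } else if (family == "inception-like") {
    b3 <- conv3_bwd(cache$Ccat, P$c2.W, cache$M3, g)
    G$c2.W <- b3$dW; G$c2.b <- b3$db
    h1 <- dim(cache$A1)[3]
    dA1 <- b3$dX[, , seq_len(h1), , drop = FALSE]
    dA2 <- b3$dX[, , -seq_len(h1), , drop = FALSE]
    b1 <- conv3_bwd(cache$X, P$b1.W, cache$M1, dA1 * (cache$A1 > 0))
    G$b1.W <- b1$dW; G$b1.b <- b1$db
    b2 <- conv1_bwd(cache$X, P$b2.W, cache$Xm, dA2 * (cache$A2 > 0))
    G$b2.W <- b2$dW; G$b2.b <- b2$db
    dX <- b1$dX + b2$dX
  } else {  # efficient-like
    g2 <- conv1_bwd(cache$Z2, P$p2.W, cache$Xm2, g)
    G$p2.W <- g2$dW; G$p2.b <- g2$db
    b2 <- dw3_bwd(cache$A1, P$d2.W, cache$M2, g2$dX)
    G$d2.W <- b2$dW; G$d2.b <- b2$db
    gA1 <- b2$dX * (cache$A1 > 0)
    g1 <- conv1_bwd(cache$Z1, P$p1.W, cache$Xm1, gA1)
    G$p1.W <- g1$dW; G$p1.b <- g1$db
    b1 <- dw3_bwd(cache$X, P$d1.W, cache$M1, g1$dX)
    G$d1.W <- b1$dW; G$d1.b <- b1$db
    dX <- b1$dX
  }
  list(dX = dX, grads = G)
}

# --- model -------------------------------------------------------------------

#' Build an untrained encoder--decoder segmenter
#'
#' Constructs the U-topology network described by a [model_config()]: a
#' contracting path of `depth` stages with 2x2 max pooling, a bottleneck, and
#' a symmetric expanding path with nearest-neighbour upsampling and skip
#' connections at every resolution, ending in a per-pixel softmax.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the (He) weight initialization.
#' @return Object of class `hypo_unet`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  fam <- config$encoder_family; D <- config$depth; B <- config$base_channels
  with_seed(seed, {
    params <- list(); arch <- list()
    cin <- 1L
    for (d in seq_len(D)) {
      cout <- B * 2L^(d - 1L)
      arch[[paste0("enc", d)]] <- list(cin = cin, cout = cout)
      params[[paste0("enc", d)]] <- block_params(fam, cin, cout)
      cin <- cout
    }
    arch$bott <- list(cin = cin, cout = B * 2L^D)
    params$bott <- block_params(fam, cin, B * 2L^D)
    cin <- B * 2L^D
    for (d in rev(seq_len(D))) {
      cout <- B * 2L^(d - 1L)
      params[[paste0("up", d)]] <- list(W = he_conv3(cin, cout),
                                        b = numeric(cout))
      params[[paste0("dec", d)]] <- block_params(fam, 2L * cout, cout)
      arch[[paste0("dec", d)]] <- list(cin = 2L * cout, cout = cout)
      cin <- cout
    }
    params$out <- list(W = he_conv1(cin, config$n_classes),
                       b = numeric(config$n_classes))
    structure(list(config = config, params = params, arch = arch,
                   trained = FALSE, history = NULL, best_epoch = NA_integer_,
                   init_seed = as.integer(seed)),
              class = "hypo_unet")
  })
}

# forward pass; X: (H, W, 1, N). Returns softmax probabilities (K x H*W*N)
# plus caches when training.
unet_fwd <- function(model, X, keep_cache = FALSE) {
  fam <- model$config$encoder_family; D <- model$config$depth
  P <- model$params
  cur <- X
  skips <- list(); caches <- list(); pools <- list()
  for (d in seq_len(D)) {
    bf <- block_fwd(P[[paste0("enc", d)]], fam, cur)
    skips[[d]] <- bf$Y
    if (keep_cache) caches[[paste0("enc", d)]] <- bf$cache
    pf <- pool_fwd(bf$Y)
    if (keep_cache) pools[[d]] <- pf else pf$a <- pf$b <- pf$cc <- pf$e <- NULL
    cur <- pf$Y
  }
  bf <- block_fwd(P$bott, fam, cur)
  if (keep_cache) caches$bott <- bf$cache
  cur <- bf$Y
  ups <- list(); cats <- list()
  for (d in rev(seq_len(D))) {
    U <- up_fwd(cur)
    uf <- conv3_fwd(U, P[[paste0("up", d)]]$W, P[[paste0("up", d)]]$b)
    A <- relu(uf$Y)
    if (keep_cache) ups[[d]] <- list(U = U, M = uf$M, A = A)
    Ccat <- cat_channels(A, skips[[d]])
    if (keep_cache) cats[[d]] <- dim(A)[3]
    bf <- block_fwd(P[[paste0("dec", d)]], fam, Ccat)
    if (keep_cache) {
      caches[[paste0("dec", d)]] <- bf$cache
      caches[[paste0("cat", d)]] <- Ccat
    }
    cur <- bf$Y
  }
  of <- conv1_fwd(cur, P$out$W, P$out$b)
  d <- dim(of$Y)
  Zm <- matrix(aperm(of$Y, c(3, 1, 2, 4)), nrow = d[3])
  Pm <- softmax_cols(Zm)
  list(Pm = Pm, out_dim = d,
       cache = if (keep_cache) list(caches = caches, pools = pools, ups = ups,
                                    skips = skips, last = cur, out_Xm = of$Xm)
       else NULL)
}

# backward pass from dZ (K x n); returns flat-named gradient list
unet_bwd <- function(model, fwd, dZ) {
  fam <- model$config$encoder_family; D <- model$config$depth
  P <- model$params; cc <- fwd$cache
  d <- fwd$out_dim
  dZarr <- aperm(array(dZ, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  G <- list()
  ob <- conv1_bwd(cc$last, P$out$W, cc$out_Xm, dZarr)
  G$out <- list(W = ob$dW, b = ob$db)
  dcur <- ob$dX
  dskips <- vector("list", D)
  for (d_ in seq_len(D)) {  # decoder stages, deepest-first order = d = 1..D reversed at build; walk 1..D here
    bb <- block_bwd(P[[paste0("dec", d_)]], fam, cc$caches[[paste0("dec", d_)]], dcur)
    G[[paste0("dec", d_)]] <- bb$grads
    hA <- dim(cc$ups[[d_]]$A)[3]
    dA <- bb$dX[, , seq_len(hA), , drop = FALSE]
    dskips[[d_]] <- bb$dX[, , -seq_len(hA), , drop = FALSE]
    ub <- conv3_bwd(cc$ups[[d_]]$U, P[[paste0("up", d_)]]$W, cc$ups[[d_]]$M,
                    dA * (cc$ups[[d_]]$A > 0))
    G[[paste0("up", d_)]] <- list(W = ub$dW, b = ub$db)
    dcur <- up_bwd(ub$dX)
  }
  bb <- block_bwd(P$bott, fam, cc$caches$bott, dcur)
  G$bott <- bb$grads
  dcur <- bb$dX
  for (d_ in seq_len(D)) {  # encoder stages, deepest-first
    dd <- D - d_ + 1L
    dpool <- pool_bwd(cc$pools[[dd]], dcur, dim(cc$skips[[dd]]))
    denc <- dpool + dskips[[dd]]
    bb <- block_bwd(P[[paste0("enc", dd)]], fam, cc$caches[[paste0("enc", dd)]],
                    denc)
    G[[paste0("enc", dd)]] <- bb$grads
    dcur <- bb$dX
  }
  G
}

#' Number of trainable parameters
#' @param model a `hypo_unet`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

#' @export
print.hypo_unet <- function(x, ...) {
  cat(sprintf("<hypo_unet> %s, depth %d, base %d, input %dpx, %d classes\n",
              x$config$encoder_family, x$config$depth, x$config$base_channels,
              x$config$input_size, x$config$n_classes))
  cat(sprintf("  parameters: %d  trained: %s\n", n_params(x),
              ifelse(x$trained, sprintf("yes (best epoch %d)", x$best_epoch),
                     "no")))
  invisible(x)
}

#' @export
summary.hypo_unet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Combined categorical cross-entropy + Jaccard loss
#'
#' Training loss of the segmenter: mean per-pixel categorical cross-entropy
#' plus one minus the soft Jaccard index of the foreground class (pooled over
#' the batch). Nonnegative, and zero only when the prediction equals the
#' one-hot target up to numerical epsilon.
#'
#' @param predicted array of class probabilities; last-but-one axis (or the
#'   rows of a `K x n` matrix) indexes classes and must sum to 1.
#' @param target one-hot array of the same shape.
#' @return Scalar loss with attributes `ce` and `jaccard` holding the two
#'   terms.
#' @export
combined_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)))
    stop_param("shape mismatch between prediction and target")
  if (is.matrix(predicted)) {
    Pm <- predicted; Tm <- target
  } else {
    d <- dim(predicted); nd <- length(d)
    K <- d[nd - 1]
    perm <- c(nd - 1, seq_len(nd)[-(nd - 1)])
    Pm <- matrix(aperm(predicted, perm), nrow = K)
    Tm <- matrix(aperm(target, perm), nrow = K)
  }
  if (any(Pm < -1e-9) || any(Pm > 1 + 1e-9))
    stop_param("probabilities must lie in [0, 1]")
  if (max(abs(colSums(Pm) - 1)) > 1e-6)
    stop_param("class probabilities must sum to 1 per pixel")
  r <- softmax_loss_grad(Pm, Tm)
  structure(r$ce + r$jaccard, ce = r$ce, jaccard = r$jaccard)
}

#' Early-stopping rule on a validation-loss sequence
#'
#' Pure stopping logic used by [train_unet()]: training halts after `patience`
#' consecutive epochs without improvement of the running-best validation loss,
#' and the best epoch is the argmin of the sequence seen so far.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience integer patience in epochs.
#' @return `list(best_epoch, stop_epoch)`; `stop_epoch` is the epoch at which
#'   training halts (the length of the sequence if patience is never
#'   exhausted).
#' @export
#' @examples
#' early_stopping(c(1.0, 1.1, 1.2, 1.3), patience = 2)  # stops at epoch 3
early_stopping <- function(val_losses, patience) {
  stopifnot(length(val_losses) >= 1, patience >= 1)
  best <- 1L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best]) best <- e
    if (e - best >= patience)
      return(list(best_epoch = best, stop_epoch = e))
  }
  list(best_epoch = best, stop_epoch = length(val_losses))
}

# assemble a batch: list of slices -> list(X = (H,W,1,N), Tm = (K x H*W*N))
make_batch <- function(slices, n_classes) {
  N <- length(slices)
  d <- dim(slices[[1]]$x)
  X <- array(0, c(d[1], d[2], 1L, N))
  Tm <- matrix(0, n_classes, d[1] * d[2] * N)
  for (i in seq_len(N)) {
    X[, , 1L, i] <- slices[[i]]$x
    y <- as.integer(slices[[i]]$y > 0)
    cols <- (i - 1L) * d[1] * d[2] + seq_len(d[1] * d[2])
    Tm[cbind(y + 1L, cols)] <- 1
  }
  list(X = X, Tm = Tm)
}

eval_slices <- function(model, slices, batch_size = 16L) {
  K <- model$config$n_classes
  tot_loss <- 0; nb <- 0L
  tp <- fp <- fn <- 0
  for (start in seq(1, length(slices), by = batch_size)) {
    b <- slices[start:min(start + batch_size - 1L, length(slices))]
    bt <- make_batch(b, K)
    fw <- unet_fwd(model, bt$X)
    r <- softmax_loss_grad(fw$Pm, bt$Tm)
    tot_loss <- tot_loss + r$loss * length(b)
    nb <- nb + length(b)
    pred_fg <- fw$Pm[K, ] >= apply_max_others(fw$Pm, K)
    true_fg <- bt$Tm[K, ] > 0
    tp <- tp + sum(pred_fg & true_fg)
    fp <- fp + sum(pred_fg & !true_fg)
    fn <- fn + sum(!pred_fg & true_fg)
  }
  list(loss = tot_loss / nb,
       iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_)
}

apply_max_others <- function(Pm, K) {
  mx <- rep(-Inf, ncol(Pm))
  for (k in seq_len(K)[-K]) mx <- pmax(mx, Pm[k, ])
  mx
}

#' Train the segmenter
#'
#' Slice-wise training with Adam on the combined cross-entropy + Jaccard loss,
#' validation-loss early stopping, and restoration of the weights of the
#' best-validation epoch. Fully seeded: two runs with the same inputs, seeds
#' and configuration produce identical histories and weights.
#'
#' @param model an untrained (or warm) `hypo_unet` from [build_model()].
#' @param train_slices,val_slices slice sets from [as_slice_set()] /
#'   [build_augmented_set()]; both must be nonempty.
#' @param config a [train_config()].
#' @return The fitted `hypo_unet`; `$history` holds the per-epoch
#'   train/validation loss and validation IoU, `$best_epoch` the argmin of the
#'   validation loss.
#' @export
train_unet <- function(model, train_slices, val_slices,
                       config = train_config()) {
  stopifnot(inherits(model, "hypo_unet"), inherits(config, "train_config"))
  if (length(train_slices) == 0 || length(val_slices) == 0)
    stop_param("training and validation sets must be nonempty")
  d1 <- dim(train_slices[[1]]$x)
  if (d1[1] != model$config$input_size || d1[2] != model$config$input_size)
    stop_param("slice size %dx%d does not match model input_size %d",
               d1[1], d1[2], model$config$input_size)
  K <- model$config$n_classes
  with_seed(config$seed, {
    m_state <- rapply(model$params, function(a) a * 0, how = "replace")
    v_state <- m_state
    t_step <- 0L
    restarts <- 0L
    best <- list(epoch = 0L, loss = Inf, params = model$params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), val_iou = numeric())
    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample(length(train_slices))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, length(ord), by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        bt <- make_batch(train_slices[sel], K)
        fw <- unet_fwd(model, bt$X, keep_cache = TRUE)
        r <- softmax_loss_grad(fw$Pm, bt$Tm)
        G <- unet_bwd(model, fw, r$dZ)
        t_step <- t_step + 1L
        upd <- adam_update(model$params, G, m_state, v_state, t_step, config)
        model$params <- upd$params; m_state <- upd$m; v_state <- upd$v
        ep_loss <- ep_loss + r$loss * length(sel); nb <- nb + length(sel)
      }
      ev <- eval_slices(model, val_slices)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                     val_loss = ev$loss, val_iou = ev$iou))
      # degenerate initialization: no foreground learned after three epochs.
      # Reinitialize deterministically and restart (at most twice).
      if (epoch == 3L && config$max_epochs > 3L && restarts < 2L &&
          all(hist$val_iou[hist$epoch <= 3] < 0.05, na.rm = TRUE)) {
        restarts <- restarts + 1L
        fresh <- build_model(model$config,
                             seed = derive_seed(model$init_seed,
                                                paste0("restart-", restarts)))
        model$params <- fresh$params
        m_state <- rapply(model$params, function(a) a * 0, how = "replace")
        v_state <- m_state
        t_step <- 0L
        best <- list(epoch = 0L, loss = Inf, params = model$params)
        hist <- hist[0, ]
        epoch <- 0L
        next
      }
      if (ev$loss < best$loss)
        best <- list(epoch = epoch, loss = ev$loss, params = model$params)
      # quality-based stop: validation IoU has reached the requested level
      if (!is.null(config$iou_target) && is.finite(ev$iou) &&
          ev$iou >= config$iou_target) break
      # same rule as early_stopping(): halt once `patience` epochs have
      # passed without a new validation-loss minimum
      if (epoch - best$epoch >= config$patience) break
    }
    model$params <- best$params
    model$trained <- TRUE
    model$history <- hist
    model$best_epoch <- best$epoch
    model$train_config <- config
    model$restarts <- restarts
    model
  })
}

# Adam step over the nested parameter list (blocks -> named arrays)
adam_update <- function(params, grads, m, v, t, cfg) {
  lr <- cfg$learning_rate; b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- 1e-8
  for (blk in names(params)) {
    for (nm in names(params[[blk]])) {
      g <- grads[[blk]][[nm]]
      m[[blk]][[nm]] <- b1 * m[[blk]][[nm]] + (1 - b1) * g
      v[[blk]][[nm]] <- b2 * v[[blk]][[nm]] + (1 - b2) * g * g
      mh <- m[[blk]][[nm]] / (1 - b1^t)
      vh <- v[[blk]][[nm]] / (1 - b2^t)
      params[[blk]][[nm]] <- params[[blk]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, m = m, v = v)
}

#' Plot the training history
#' @param x a fitted `hypo_unet`.
#' @param ... ignored.
#' @export
plot.hypo_unet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop_param("model has no training history")
  plot(h$epoch, h$train_loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "loss", ylim = range(c(h$train_loss, h$val_loss)),
       main = "training history")
  lines(h$epoch, h$val_loss, type = "b", pch = 1, col = 2)
  abline(v = x$best_epoch, lty = 3)
  legend("topright", legend = c("train", "validation"), col = c(1, 2),
         pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Predict class probabilities for slices
#'
#' @param object a `hypo_unet`.
#' @param x a single slice matrix or a `(H, W, 1, N)` batch array.
#' @param type `"prob"` for foreground probabilities, `"mask"` for the argmax
#'   mask.
#' @param ... ignored.
#' @return Array of foreground probabilities or binary labels, same plane
#'   shape as the input.
#' @export
predict.hypo_unet <- function(object, x, type = c("prob", "mask"), ...) {
  type <- match.arg(type)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  d <- dim(x)
  if (d[1] != object$config$input_size || d[2] != object$config$input_size)
    stop_param("grid mismatch: slices are %dx%d but model input_size is %d",
               d[1], d[2], object$config$input_size)
  K <- object$config$n_classes
  fw <- unet_fwd(object, x)
  pfg <- fw$Pm[K, ]
  if (type == "prob") {
    out <- array(pfg, c(d[1], d[2], d[4]))
  } else {
    lab <- as.integer(pfg >= apply_max_others(fw$Pm, K))
    out <- array(lab, c(d[1], d[2], d[4]))
  }
  if (d[4] == 1L) out[, , 1L] else out
}

#' Segment a whole volume slice-wise
#'
#' Applies the trained 2-D segmenter to every slice of a volume (third axis),
#' recording per-image prediction time, and flags empty predictions (zero
#' foreground voxels) for quality control.
#'
#' @param model a trained `hypo_unet`.
#' @param volume a [labeled_volume()] on the model's grid.
#' @param batch_size slices per forward pass.
#' @return Object of class `volume_prediction`: `mask` (binary 3-D array),
#'   `empty` flag, `ms_per_image` mean prediction time, `subject_id`.
#' @export
predict_volume <- function(model, volume, batch_size = 16L) {
  stopifnot(inherits(model, "hypo_unet"), inherits(volume, "labeled_volume"))
  if (!model$trained) warning("predicting with an untrained model")
  d <- dim(volume$intensity)
  if (d[1] != model$config$input_size || d[2] != model$config$input_size)
    stop_param("grid mismatch: volume is %dx%d in-plane but model input_size is %d",
               d[1], d[2], model$config$input_size)
  K <- model$config$n_classes
  mask <- array(0L, d)
  t0 <- proc.time()[["elapsed"]]
  for (start in seq(1, d[3], by = batch_size)) {
    ks <- start:min(start + batch_size - 1L, d[3])
    X <- array(volume$intensity[, , ks], c(d[1], d[2], 1L, length(ks)))
    fw <- unet_fwd(model, X)
    lab <- as.integer(fw$Pm[K, ] >= apply_max_others(fw$Pm, K))
    mask[, , ks] <- array(lab, c(d[1], d[2], length(ks)))
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(mask = mask, empty = sum(mask) == 0L,
                 ms_per_image = 1000 * elapsed / d[3],
                 voxel_size = volume$voxel_size,
                 subject_id = volume$subject_id),
            class = "volume_prediction")
}

#' @export
print.volume_prediction <- function(x, ...) {
  cat(sprintf("<volume_prediction> %s: %d foreground voxels%s (%.1f ms/image)\n",
              ifelse(is.na(x$subject_id), "(unnamed)", x$subject_id),
              sum(x$mask), ifelse(x$empty, " [EMPTY - QC flag]", ""),
              x$ms_per_image))
  invisible(x)
}
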