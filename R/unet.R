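#' U-Net configuration
#'
#' The masking network is a 2D U-Net operating on axial slices: repeated
#' blocks of two 3x3 convolutions + ReLU; 2x2 max-pooling after every
#' second convolution on the contracting path; 2x2 nearest-neighbour
#' upsampling on the expanding path; skip feature maps concatenated along
#' the channel dimension; a final 1x1 convolution to one channel per
#' class. All convolutions are same-padded, so spatial dimensions are
#' preserved end to end.
#'
#' @param depth number of pooling levels (default 4).
#' @param base_filters feature maps at the first level (default 32);
#'   every pooling level doubles the width.
#' @param in_shape in-plane slice shape; must be divisible by `2^depth`.
#' @param out_classes number of output classes (2: background, brain).
#' @export
unet_config <- function(depth = 4, base_filters = 32, in_shape = c(96, 96),
                        out_classes = 2) {
  in_shape <- as.integer(in_shape)
  stopifnot(depth >= 1, base_filters >= 1, length(in_shape) == 2, out_classes == 2)
  if (any(in_shape %% 2^depth != 0))
    stop(sprintf("in-plane shape (%s) must be divisible by 2^depth = %d",
                 paste(in_shape, collapse = "x"), 2^depth))
  structure(list(depth = depth, base_filters = as.integer(base_filters),
                 in_shape = in_shape, out_classes = 2L),
            class = "unet_config")
}

# Named conv layers with (in, out) channel counts, in forward order.
unet_layer_plan <- function(cfg) {
  d <- cfg$depth; f <- cfg$base_filters
  plan <- list()
  for (l in seq_len(d)) {
    cin <- if (l == 1) 1L else f * 2^(l - 2)
    plan[[sprintf("enc%d_1", l)]] <- c(cin, f * 2^(l - 1))
    plan[[sprintf("enc%d_2", l)]] <- c(f * 2^(l - 1), f * 2^(l - 1))
  }
  plan[["bot_1"]] <- c(f * 2^(d - 1), f * 2^d)
  plan[["bot_2"]] <- c(f * 2^d, f * 2^d)
  for (l in rev(seq_len(d))) {
    plan[[sprintf("dec%d_1", l)]] <- c(f * 2^l + f * 2^(l - 1), f * 2^(l - 1))
    plan[[sprintf("dec%d_2", l)]] <- c(f * 2^(l - 1), f * 2^(l - 1))
  }
  plan[["final"]] <- c(f, cfg$out_classes) # 1x1 convolution
  plan
}

#' Build a U-Net with randomly initialized weights
#'
#' Weights use He initialization (`N(0, 2 / fan_in)`), fully determined by
#' `seed`. The final layer's brain-class bias is initialized to the
#' log-odds of `foreground_prior`, so the untrained network already
#' predicts the right base rate for the heavily background-dominated
#' masking problem and the first training batches are spent on the
#' discriminative signal rather than on learning the class prior.
#'
#' @param cfg a [unet_config()].
#' @param seed integer RNG seed for initialization.
#' @param foreground_prior expected foreground voxel fraction used to
#'   initialize the output bias.
#' @return a `unet_model` (configuration + parameter list).
#' @export
build_unet <- function(cfg = unet_config(), seed = 1, foreground_prior = 0.02) {
  plan <- unet_layer_plan(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  for (nm in names(plan)) {
    ch <- plan[[nm]]
    k <- if (nm == "final") 1L else 9L
    fan_in <- k * ch[1]
    params[[nm]] <- list(
      w = matrix(stats::rnorm(fan_in * ch[2], sd = sqrt(2 / fan_in)), fan_in, ch[2]),
      b = numeric(ch[2])
    )
  }
  params$final$b[2] <- log(foreground_prior / (1 - foreground_prior))
  structure(list(cfg = cfg, params = params, plan = plan), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), 0))
  cat(sprintf("<unet_model> depth %d, base %d filters, %s in-plane, %d classes, %s parameters\n",
              x$cfg$depth, x$cfg$base_filters, paste(x$cfg$in_shape, collapse = "x"),
              x$cfg$out_classes, format(np, big.mark = ",")))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

conv_fwd <- function(x, p) cpp_conv3x3_fwd(x, dim(x), p$w, p$b)

# 1x1 convolution as a channel-mixing matrix product.
conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  y <- sweep(xm %*% p$w, 2, p$b, "+")
  aperm(array(y, c(d[1], d[2], d[4], ncol(p$w))), c(1, 2, 4, 3))
}

conv1x1_bwd <- function(x, p, dy) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = ncol(p$w))
  list(dx = aperm(array(dym %*% t(p$w), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)),
       dw = crossprod(xm, dym), db = colSums(dym))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass over a slice batch [H, W, 1, N]. With cache = TRUE, every
# post-ReLU activation and pooling argmax needed by the backward pass is
# retained.
unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$cfg; d <- cfg$depth; P <- model$params
  cc <- if (cache) list(x0 = x) else NULL
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    a1 <- relu(conv_fwd(x, P[[sprintf("enc%d_1", l)]]))
    a2 <- relu(conv_fwd(a1, P[[sprintf("enc%d_2", l)]]))
    skips[[l]] <- a2
    mp <- cpp_maxpool2_fwd(a2, dim(a2))
    if (cache) { cc[[sprintf("enc%d_a1", l)]] <- a1; cc[[sprintf("enc%d_arg", l)]] <- mp$argmax }
    x <- mp$y
  }
  b1 <- relu(conv_fwd(x, P$bot_1))
  b2 <- relu(conv_fwd(b1, P$bot_2))
  if (cache) { cc$bot_in <- x; cc$bot_a1 <- b1; cc$bot_a2 <- b2 }
  x <- b2
  for (l in rev(seq_len(d))) {
    up <- cpp_upsample2_fwd(x, dim(x))
    xin <- cat_channels(up, skips[[l]])
    a1 <- relu(conv_fwd(xin, P[[sprintf("dec%d_1", l)]]))
    a2 <- relu(conv_fwd(a1, P[[sprintf("dec%d_2", l)]]))
    if (cache) { cc[[sprintf("dec%d_in", l)]] <- xin; cc[[sprintf("dec%d_a1", l)]] <- a1
                 cc[[sprintf("dec%d_a2", l)]] <- a2 }
    x <- a2
  }
  logits <- conv1x1_fwd(x, P$final)
  if (cache) { cc$pre_final <- x; cc$skips <- skips }
  list(logits = logits, cache = cc)
}

# Stable 2-class softmax along the channel dimension of [H, W, 2, N].
softmax2 <- function(logits) {
  m <- pmax(logits[, , 1, , drop = FALSE], logits[, , 2, , drop = FALSE])
  e1 <- exp(logits[, , 1, , drop = FALSE] - m)
  e2 <- exp(logits[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  out <- logits
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}

# Mean per-pixel 2-class cross-entropy and its gradient with respect to
# the logits. `y` is the binary brain label [H, W, 1, N].
softmax_ce <- function(logits, y) {
  p <- softmax2(logits)
  npix <- length(y)
  pb <- p[, , 2, , drop = FALSE]
  eps <- 1e-12
  loss <- -sum(y * log(pb + eps) + (1 - y) * log(1 - pb + eps)) / npix
  dlog <- p
  dlog[, , 1, ] <- (p[, , 1, , drop = TRUE] - (1 - y[, , 1, , drop = TRUE])) / npix
  dlog[, , 2, ] <- (p[, , 2, , drop = TRUE] - y[, , 1, , drop = TRUE]) / npix
  list(loss = loss, prob = p, dlogits = dlog)
}

# Full backward pass; returns gradients in the same shape as the params.
unet_backward <- function(model, cc, dlogits) {
  cfg <- model$cfg; d <- cfg$depth; P <- model$params
  G <- list()
  fb <- conv1x1_bwd(cc$pre_final, P$final, dlogits)
  G$final <- list(w = fb$dw, b = fb$db)
  dx <- fb$dx
  for (l in seq_len(d)) { # expanding path, from the surface down
    a2 <- cc[[sprintf("dec%d_a2", l)]]
    dx <- dx * (a2 > 0)
    b2 <- cpp_conv3x3_bwd(cc[[sprintf("dec%d_a1", l)]], dim(cc[[sprintf("dec%d_a1", l)]]),
                          P[[sprintf("dec%d_2", l)]]$w, dx)
    G[[sprintf("dec%d_2", l)]] <- list(w = b2$dw, b = b2$db)
    da1 <- b2$dx * (cc[[sprintf("dec%d_a1", l)]] > 0)
    xin <- cc[[sprintf("dec%d_in", l)]]
    b1 <- cpp_conv3x3_bwd(xin, dim(xin), P[[sprintf("dec%d_1", l)]]$w, da1)
    G[[sprintf("dec%d_1", l)]] <- list(w = b1$dw, b = b1$db)
    nup <- dim(xin)[3] - dim(cc$skips[[l]])[3]
    dup <- b1$dx[, , seq_len(nup), , drop = FALSE]
    cc[[sprintf("dskip%d", l)]] <-
      b1$dx[, , nup + seq_len(dim(cc$skips[[l]])[3]), , drop = FALSE]
    dx <- cpp_upsample2_bwd(dup, dim(dup)) # grad wrt next-deeper level's output
  }
  # bottleneck
  dx2 <- dx * (cc$bot_a2 > 0)
  bb2 <- cpp_conv3x3_bwd(cc$bot_a1, dim(cc$bot_a1), P$bot_2$w, dx2)
  G$bot_2 <- list(w = bb2$dw, b = bb2$db)
  db1 <- bb2$dx * (cc$bot_a1 > 0)
  bb1 <- cpp_conv3x3_bwd(cc$bot_in, dim(cc$bot_in), P$bot_1$w, db1)
  G$bot_1 <- list(w = bb1$dw, b = bb1$db)
  dx <- bb1$dx
  for (l in rev(seq_len(d))) { # contracting path, from the deepest level up
    dpool <- cpp_maxpool2_bwd(dx, cc[[sprintf("enc%d_arg", l)]], dim(cc$skips[[l]]))
    da2 <- (dpool + cc[[sprintf("dskip%d", l)]]) * (cc$skips[[l]] > 0)
    a1 <- cc[[sprintf("enc%d_a1", l)]]
    e2 <- cpp_conv3x3_bwd(a1, dim(a1), P[[sprintf("enc%d_2", l)]]$w, da2)
    G[[sprintf("enc%d_2", l)]] <- list(w = e2$dw, b = e2$db)
    da1 <- e2$dx * (a1 > 0)
    # input to enc l is the pooled output of enc l-1 (recomputed, not cached)
    xin <- if (l == 1) cc$x0
           else cpp_maxpool2_fwd(cc$skips[[l - 1]], dim(cc$skips[[l - 1]]))$y
    e1 <- cpp_conv3x3_bwd(xin, dim(xin), P[[sprintf("enc%d_1", l)]]$w, da1)
    G[[sprintf("enc%d_1", l)]] <- list(w = e1$dw, b = e1$db)
    dx <- e1$dx
  }
  G
}

#' Split a volume into 2D axial slices
#'
#' The network treats each axial (third-axis) slice independently; this
#' returns the slice batch in network layout `[H, W, 1, n_slices]`.
#' `restack_slices()` is its exact inverse.
#'
#' @param vol a [volume3d()] (or a plain 3D array).
#' @export
slice_volume <- function(vol) {
  arr <- if (inherits(vol, "volume3d")) vol$data else vol
  d <- dim(arr)
  array(arr, c(d[1], d[2], 1, d[3]))
}

#' @rdname slice_volume
#' @param slices array `[H, W, 1, n_slices]` (or `[H, W, n_slices]`).
#' @export
restack_slices <- function(slices) {
  d <- dim(slices)
  if (length(d) == 4) array(slices, c(d[1], d[2], d[4])) else slices
}

#' In-plane dihedral augmentation
#'
#' The fetal brain has no standard orientation, so training pairs are
#' augmented with the 8 in-plane dihedral transforms (rotations by
#' multiples of 90 degrees, optionally composed with a flip). The same
#' transform is applied to every axial slice of the volume and of the
#' mask, preserving the 3D shape. Element 0 is the identity.
#'
#' @param arr 2D slice or 3D volume array (square in-plane).
#' @param element integer 0-7: `element %% 4` quarter-turns, preceded by a
#'   horizontal flip when `element >= 4`.
#' @export
dihedral_transform <- function(arr, element) {
  stopifnot(element %in% 0:7)
  d2 <- length(dim(arr)) == 2 || is.null(dim(arr))
  if (d2 && is.null(dim(arr))) stop("arr must be a matrix or 3D array")
  if (element >= 4) { # flip along the first in-plane axis
    arr <- if (d2) arr[rev(seq_len(nrow(arr))), , drop = FALSE]
           else arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
  }
  r <- element %% 4
  if (r > 0 && dim(arr)[1] != dim(arr)[2])
    stop("quarter-turn rotations require square in-plane shape")
  for (i in seq_len(r)) { # one quarter turn: transpose then reverse rows
    arr <- if (d2) t(arr) else aperm(arr, c(2, 1, 3))
    arr <- if (d2) arr[rev(seq_len(nrow(arr))), , drop = FALSE]
           else arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
  }
  arr
}

#' @rdname dihedral_transform
#' @param vol,mask paired image and mask volumes (3D arrays or
#'   [volume3d()]); the same element is applied to both.
#' @return `augment_pair()`: list with `x`, `y` (transformed arrays) and
#'   `element`.
#' @export
augment_pair <- function(vol, mask, element) {
  x <- if (inherits(vol, "volume3d")) vol$data else vol
  y <- if (inherits(mask, "volume3d")) mask$data else mask
  list(x = dihedral_transform(x, element), y = dihedral_transform(y, element),
       element = element)
}

#' Predict per-voxel brain probability
#'
#' Runs the network slice-wise over a standardized, intensity-normalized
#' volume and restacks the softmax brain-class probability. Deterministic
#' given the weights.
#'
#' @param model a trained `unet_model`.
#' @param vol standardized [volume3d()] (values in `[0, 1]`).
#' @return a [volume3d()] of probabilities in `[0, 1]` on the same grid.
#' @export
predict_probability <- function(model, vol) {
  stopifnot(inherits(model, "unet_model"), inherits(vol, "volume3d"))
  if (!all(dim(vol$data)[1:2] == model$cfg$in_shape))
    stop(sprintf("volume in-plane shape %s does not match the network's %s",
                 paste(dim(vol$data)[1:2], collapse = "x"),
                 paste(model$cfg$in_shape, collapse = "x")))
  x <- slice_volume(vol)
  p <- softmax2(unet_forward(model, x)$logits)
  volume3d(restack_slices(p[, , 2, , drop = FALSE]), vol$spacing, vol$affine,
           frame_index = vol$frame_index)
}

# RNG bookkeeping: run seeded sections without disturbing the caller's
# random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
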