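#' Training configuration
#'
#' Training minimizes mean per-pixel 2-class cross-entropy with the Adam
#' optimizer under a staircase learning-rate schedule: the rate starts at
#' `initial_rate` and is multiplied by `decay_factor` every
#' `decay_interval` batches. Training stops early once the mean validation
#' Dice (threshold 0.5) has not improved for `patience` consecutive
#' checks; the best-validation weights are returned.
#'
#' @param initial_rate initial learning rate (default 1e-4).
#' @param decay_factor exponential decay factor (default 0.9).
#' @param decay_interval batches between decay applications (default 10000).
#' @param batch_size slices per batch.
#' @param check_every batches between validation checks.
#' @param patience validation checks without improvement before stopping.
#' @param max_batches hard cap on training batches.
#' @param seed RNG seed controlling batch order and augmentation draws.
#' @export
training_config <- function(initial_rate = 1e-4, decay_factor = 0.9,
                            decay_interval = 10000, batch_size = 8,
                            check_every = 100, patience = 6,
                            max_batches = 1000, seed = 1) {
  stopifnot(initial_rate > 0, decay_factor > 0, decay_factor <= 1,
            decay_interval >= 1, batch_size >= 1, patience >= 1)
  structure(list(initial_rate = initial_rate, decay_factor = decay_factor,
                 decay_interval = as.integer(decay_interval),
                 batch_size = as.integer(batch_size),
                 check_every = as.integer(check_every),
                 patience = as.integer(patience),
                 max_batches = as.integer(max_batches), seed = as.integer(seed)),
            class = "training_config")
}

#' Staircase learning-rate schedule
#'
#' `rate(t) = initial_rate * decay_factor ^ floor(t / decay_interval)`;
#' non-increasing in `t` and piecewise constant.
#'
#' @param cfg a [training_config()].
#' @param batch 0-based batch index (vectorized).
#' @export
learning_rate <- function(cfg, batch) {
  stopifnot(all(batch >= 0))
  cfg$initial_rate * cfg$decay_factor^floor(batch / cfg$decay_interval)
}

#' Dice coefficient between two binary arrays
#' @param a,b binary arrays of identical shape.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Assemble a training pair
#'
#' @param x standardized, intensity-normalized image (3D array or
#'   [volume3d()]).
#' @param y matching binary brain mask on the same grid.
#' @param subject subject identifier (splits must be disjoint at the
#'   subject level).
#' @param volume_id optional volume identifier.
#' @export
training_pair <- function(x, y, subject, volume_id = NA_character_) {
  x <- if (inherits(x, "volume3d")) x$data else x
  y <- if (inherits(y, "volume3d")) y$data else y
  stopifnot(all(dim(x) == dim(y)), all(y %in% c(0, 1)))
  list(x = x, y = y, subject = as.character(subject),
       volume_id = as.character(volume_id))
}

adam_init <- function(params) {
  lapply(params, function(p) list(mw = p$w * 0, vw = p$w * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w - lr * (s$mw / bc1) / (sqrt(s$vw / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

validation_dice <- function(model, val_pairs, threshold = 0.5) {
  mean(vapply(val_pairs, function(p) {
    prob <- softmax2(unet_forward(model, slice_volume(p$x))$logits)[, , 2, , drop = TRUE]
    dice_coefficient(prob >= threshold, p$y)
  }, 0))
}

#' Train the masking U-Net
#'
#' Per epoch, every training volume is given one uniformly drawn dihedral
#' augmentation (the same transform for all of its slices), then slices
#' are shuffled across volumes and consumed in batches. Validation Dice
#' is measured every `check_every` batches; the weights with the best
#' validation Dice are returned. Fully deterministic given `cfg$seed`.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param train_pairs,val_pairs lists of [training_pair()]; subjects must
#'   not overlap between the two.
#' @param cfg a [training_config()].
#' @param verbose print progress lines.
#' @return list with `model` (best weights), `history` (tibble: batch,
#'   train loss since last check, validation Dice) and `stopped_at`.
#' @export
train_unet <- function(model, train_pairs, val_pairs, cfg = training_config(),
                       verbose = FALSE) {
  stopifnot(length(train_pairs) > 0, length(val_pairs) > 0)
  ts <- unique(vapply(train_pairs, `[[`, "", "subject"))
  vs <- unique(vapply(val_pairs, `[[`, "", "subject"))
  if (length(intersect(ts, vs)) > 0)
    stop("training and validation sets share subjects: ",
         paste(intersect(ts, vs), collapse = ", "))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  nz <- dim(train_pairs[[1]]$x)[3]
  params <- model$params
  state <- adam_init(params)
  best <- list(dice = -Inf, params = params)
  hist <- list()
  t <- 0L; bad_checks <- 0L; loss_acc <- 0; loss_n <- 0L
  stopped_at <- NA_integer_
  queue <- NULL; elements <- NULL

  new_epoch <- function() {
    elements <<- sample(0:7, length(train_pairs), replace = TRUE)
    idx <- cbind(rep(seq_along(train_pairs), each = nz),
                 rep(seq_len(nz), times = length(train_pairs)))
    queue <<- idx[sample(nrow(idx)), , drop = FALSE]
  }
  new_epoch()

  while (t < cfg$max_batches) {
    if (nrow(queue) < cfg$batch_size) new_epoch()
    take <- queue[seq_len(cfg$batch_size), , drop = FALSE]
    queue <- queue[-seq_len(cfg$batch_size), , drop = FALSE]
    hw <- model$cfg$in_shape
    xb <- array(0, c(hw[1], hw[2], 1, cfg$batch_size))
    yb <- array(0, c(hw[1], hw[2], 1, cfg$batch_size))
    for (i in seq_len(cfg$batch_size)) {
      p <- train_pairs[[take[i, 1]]]
      el <- elements[take[i, 1]]
      xb[, , 1, i] <- dihedral_transform(p$x[, , take[i, 2]], el)
      yb[, , 1, i] <- dihedral_transform(p$y[, , take[i, 2]], el)
    }
    fwd <- unet_forward(structure(list(cfg = model$cfg, params = params,
                                       plan = model$plan), class = "unet_model"),
                        xb, cache = TRUE)
    ce <- softmax_ce(fwd$logits, yb)
    if (!is.finite(ce$loss))
      stop(sprintf("non-finite training loss at batch %d; aborting", t))
    grads <- unet_backward(structure(list(cfg = model$cfg, params = params),
                                     class = "unet_model"), fwd$cache, ce$dlogits)
    lr <- learning_rate(cfg, t)
    up <- adam_step(params, grads, state, lr, t + 1L)
    params <- up$params; state <- up$state
    loss_acc <- loss_acc + ce$loss; loss_n <- loss_n + 1L
    t <- t + 1L

    if (t %% cfg$check_every == 0 || t == cfg$max_batches) {
      cur <- structure(list(cfg = model$cfg, params = params, plan = model$plan),
                       class = "unet_model")
      vd <- validation_dice(cur, val_pairs)
      hist[[length(hist) + 1]] <- tibble::tibble(
        batch = t, train_loss = loss_acc / max(1L, loss_n), val_dice = vd)
      if (verbose)
        message(sprintf("batch %5d  loss %.5f  val Dice %.4f  lr %.2e",
                        t, loss_acc / max(1L, loss_n), vd, lr))
      loss_acc <- 0; loss_n <- 0L
      if (vd > best$dice + 1e-6) {
        best <- list(dice = vd, params = params)
        bad_checks <- 0L
      } else {
        bad_checks <- bad_checks + 1L
        if (bad_checks >= cfg$patience) { stopped_at <- t; break }
      }
    }
  }
  if (is.na(stopped_at)) stopped_at <- t
  out_model <- structure(list(cfg = model$cfg, params = best$params,
                              plan = model$plan), class = "unet_model")
  structure(list(model = out_model, history = dplyr::bind_rows(hist),
                 stopped_at = stopped_at, best_val_dice = best$dice,
                 config = cfg),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> stopped at batch %d, best validation Dice %.4f\n",
              x$stopped_at, x$best_val_dice))
  invisible(x)
}

#' Save / load network weights
#'
#' Weights are stored in a versioned container (`fetalmask-weights-1`)
#' holding the network configuration and parameter list.
#'
#' @param model a `unet_model` (or `unet_fit`, whose best model is saved).
#' @param path destination file.
#' @export
save_weights <- function(model, path) {
  if (inherits(model, "unet_fit")) model <- model$model
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(format = "fetalmask-weights-1",
               cfg = unclass(model$cfg), params = model$params), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fetalmask-weights-1"))
    stop("unrecognized weight container format")
  cfg <- do.call(unet_config, x$cfg[c("depth", "base_filters", "in_shape", "out_classes")])
  structure(list(cfg = cfg, params = x$params, plan = unet_layer_plan(cfg)),
            class = "unet_model")
}

#' @export
glance.unet_fit <- function(x, ...) {
  tibble::tibble(stopped_at = x$stopped_at, best_val_dice = x$best_val_dice,
                 n_checks = nrow(x$history),
                 final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @export
tidy.unet_fit <- function(x, ...) x$history
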