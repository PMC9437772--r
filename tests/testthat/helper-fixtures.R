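# Shared fixtures and independent oracles for the test suite.

# Small standardization grid used by the toy experiments: its physical
# extent (288 x 288 x 112 mm) covers the phantom's native grid, so no
# centre-cropping is involved.
toy_grid <- function() grid_spec(c(32, 32, 16), c(9, 9, 7))

toy_net <- function() unet_config(depth = 2, base_filters = 12, in_shape = c(32, 32))

toy_pairs <- function(ids, seed0, grid = toy_grid(), n_frames = 2, ...) {
  out <- list()
  for (i in seq_along(ids)) {
    ph <- generate_phantom(phantom_spec(n_frames = n_frames, seed = seed0 + i,
                                        subject = ids[i], ...))
    for (n in seq_len(n_frames)) {
      std <- standardize_volume(get_frame(ph$series, n), grid)
      msk <- standardize_mask(ph$truth_masks[[n]], grid)
      out[[length(out) + 1]] <- training_pair(std$volume, msk, ids[i],
                                              sprintf("%s_f%d", ids[i], n))
    }
  }
  out
}

# One small trained model shared across test files (trained on first use).
.toy_cache <- new.env(parent = emptyenv())
toy_fit <- function() {
  if (is.null(.toy_cache$fit)) {
    tp <- toy_pairs(sprintf("train%02d", 1:6), seed0 = 100)
    vp <- toy_pairs(sprintf("val%02d", 1:2), seed0 = 900)
    model <- build_unet(toy_net(), seed = 7)
    .toy_cache$fit <- train_unet(model, tp, vp,
                                 training_config(batch_size = 8, check_every = 50,
                                                 patience = 8, max_batches = 700,
                                                 seed = 7))
  }
  .toy_cache$fit
}

# Independent flood-fill labelling oracle (R breadth-first search).
oracle_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & (connectivity == 26 | (connectivity == 18 & m <= 2) |
                          (connectivity == 6 & m <= 1)), , drop = FALSE]
  nxt <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      k <- (cur - 1) %/% (d[1] * d[2])
      r <- (cur - 1) %% (d[1] * d[2])
      pos <- c(r %% d[1], r %/% d[1], k) + 1
      for (o in seq_len(nrow(offs))) {
        p <- pos + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        q <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (mask[q] != 0 && lab[q] == 0) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Brute-force set-arithmetic metric oracle.
oracle_metrics <- function(pred, ref, spacing = c(1, 1, 1)) {
  A <- which(pred != 0); B <- which(ref != 0)
  tp <- length(intersect(A, B))
  fp <- length(setdiff(A, B)); fn <- length(setdiff(B, A))
  list(dice = 2 * tp / (2 * tp + fp + fn),
       jaccard = tp / (tp + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = (length(pred) - length(union(A, B))) /
         (length(pred) - length(B)))
}

# All-pairs surface-distance Hausdorff oracle (plain R, no shared code
# with the implementation's C++ path).
oracle_hausdorff <- function(pred, ref, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    idx <- which(m != 0, arr.ind = TRUE)
    keep <- apply(idx, 1, function(p) {
      for (ax in 1:3) for (s in c(-1, 1)) {
        q <- p; q[ax] <- q[ax] + s
        if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]) return(TRUE)
        if (m[q[1], q[2], q[3]] == 0) return(TRUE)
      }
      FALSE
    })
    idx[keep, , drop = FALSE]
  }
  A <- sweep(surf(pred), 2, spacing, "*")
  B <- sweep(surf(ref), 2, spacing, "*")
  dmat <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
                Vectorize(function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# Random blobby binary mask on a small grid.
random_mask <- function(dim3, n_seeds = 3, p_keep = 0.5) {
  m <- array(0, dim3)
  pts <- cbind(sample(dim3[1], n_seeds, TRUE), sample(dim3[2], n_seeds, TRUE),
               sample(dim3[3], n_seeds, TRUE))
  r <- runif(n_seeds, 1, max(2, min(dim3) / 3))
  grid <- as.matrix(expand.grid(1:dim3[1], 1:dim3[2], 1:dim3[3]))
  for (s in seq_len(n_seeds)) {
    inside <- colSums((t(grid) - pts[s, ])^2) <= r[s]^2
    m[grid[inside, , drop = FALSE]] <- 1
  }
  m
}

# Random solid ellipsoid mask as a volume3d.
random_ellipsoid <- function(dim3, spacing, min_vox = 500) {
  repeat {
    ctr <- (dim3 - 1) / 2 + runif(3, -2, 2)
    semi <- runif(3, 0.15, 0.35) * dim3
    grid <- as.matrix(expand.grid(1:dim3[1], 1:dim3[2], 1:dim3[3])) - 1
    inside <- rowSums(sweep(sweep(grid, 2, ctr), 2, semi, "/")^2) <= 1
    if (sum(inside) >= min_vox) {
      m <- array(0, dim3); m[inside] <- 1
      return(volume3d(m, spacing))
    }
  }
}
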