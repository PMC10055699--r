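#' Small encoder-decoder segmenter and the curve-swap evaluation
#'
#' A compact fully-convolutional encoder-decoder with skip connections
#' (3x3 convolutions, 2x max-pooling, nearest-neighbour upsampling),
#' trained with pixelwise binary cross-entropy by Adam. It is implemented
#' directly on matrix operations so the whole pipeline runs seeded and
#' deterministically on one CPU. The evaluation protocol trains the
#' segmenter once on RGB images synthesized with one transmittance curve,
#' freezes it, and then swaps other curves into the optical-filter layer
#' to compare designs by mean IoU under an identical network and camera
#' response.
#'
#' @name segmenter
NULL

# ---- spatial index caches -------------------------------------------------

.widefilm_cache <- new.env(parent = emptyenv())

# 3x3 neighbourhood gather indices for an H x W image (column-major),
# out-of-bounds mapped to the padding row H*W + 1
conv_indices <- function(H, W) {
  key <- paste0("conv", H, "x", W)
  if (!is.null(.widefilm_cache[[key]])) return(.widefilm_cache[[key]])
  s2 <- H * W
  r <- rep(seq_len(H), W)
  c <- rep(seq_len(W), each = H)
  idx <- matrix(s2 + 1L, s2, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    idx[ok, k] <- rr[ok] + (cc[ok] - 1L) * H
  }
  .widefilm_cache[[key]] <- idx
  idx
}

# 2x2 pooling child indices: four disjoint index vectors of length s2/4
pool_indices <- function(H, W) {
  key <- paste0("pool", H, "x", W)
  if (!is.null(.widefilm_cache[[key]])) return(.widefilm_cache[[key]])
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  ro <- rep(seq_len(H / 2L), W / 2L)
  co <- rep(seq_len(W / 2L), each = H / 2L)
  at <- function(dr, dc) (2L * ro - 1L + dr) + (2L * co - 2L + dc) * H
  out <- list(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L))
  .widefilm_cache[[key]] <- out
  out
}

# ---- primitive layers (X: pixels x channels matrices) ---------------------

conv_forward <- function(X, Wt, b, H, W) {
  idx <- conv_indices(H, W)
  Xp <- rbind(X, 0)
  Xcol <- Xp[as.vector(idx), , drop = FALSE]
  dim(Xcol) <- c(H * W, 9L * ncol(X))
  Y <- Xcol %*% Wt
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, Xcol = Xcol)
}

conv_backward <- function(dY, Xcol, Wt, Cin, H, W) {
  idx <- conv_indices(H, W)
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(Wt)
  dim(dXcol) <- c(H * W * 9L, Cin)
  dXp <- matrix(0, H * W + 1L, Cin)
  s2 <- H * W
  for (k in 1:9) {
    rows <- ((k - 1L) * s2 + 1L):(k * s2)
    tgt <- idx[, k]
    dXp[tgt, ] <- dXp[tgt, , drop = FALSE] + dXcol[rows, , drop = FALSE]
  }
  list(dX = dXp[seq_len(s2), , drop = FALSE], dW = dW, db = db)
}

maxpool_forward <- function(X, H, W) {
  p <- pool_indices(H, W)
  X1 <- X[p[[1]], , drop = FALSE]; X2 <- X[p[[2]], , drop = FALSE]
  X3 <- X[p[[3]], , drop = FALSE]; X4 <- X[p[[4]], , drop = FALSE]
  M <- pmax(X1, X2, X3, X4)
  amax <- 1L * (M == X1)
  amax[amax == 0L & M == X2] <- 2L
  amax[amax == 0L & M == X3] <- 3L
  amax[amax == 0L & M == X4] <- 4L
  list(Y = M, amax = amax)
}

maxpool_backward <- function(dY, amax, H, W, C) {
  p <- pool_indices(H, W)
  dX <- matrix(0, H * W, C)
  for (k in 1:4) {
    dX[p[[k]], ] <- dX[p[[k]], , drop = FALSE] + dY * (amax == k)
  }
  dX
}

upsample_forward <- function(X, H, W) {
  # X lives on (H/2) x (W/2); output on H x W (nearest neighbour)
  p <- pool_indices(H, W)
  Y <- matrix(0, H * W, ncol(X))
  for (k in 1:4) Y[p[[k]], ] <- X
  Y
}

upsample_backward <- function(dY, H, W) {
  p <- pool_indices(H, W)
  dY[p[[1]], , drop = FALSE] + dY[p[[2]], , drop = FALSE] +
    dY[p[[3]], , drop = FALSE] + dY[p[[4]], , drop = FALSE]
}

# ---- network --------------------------------------------------------------

#' Segmenter configuration
#'
#' @param depth Number of encoder levels (2x pooling per level).
#' @param base_channels Channels at the first level; doubled per level.
#' @param epochs Training epochs.
#' @param batch_size Images per gradient step.
#' @param learning_rate Adam step size.
#' @param threshold Probability threshold for binary maps.
#' @param seed Integer seed for initialization and data order.
#' @return List of class `seg_config`.
#' @export
seg_config <- function(depth = 2L, base_channels = 8L, epochs = 30L,
                       batch_size = 1L, learning_rate = 5e-3,
                       threshold = 0.5, seed = 1L) {
  stopifnot(depth >= 1L, base_channels >= 1L, epochs >= 1L,
            batch_size >= 1L, learning_rate > 0)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, threshold = threshold,
                 seed = as.integer(seed)),
            class = "seg_config")
}

# He-initialized weights for the whole network, as a flat named list
unet_init <- function(config, in_channels = 3L) {
  d <- config$depth; base <- config$base_channels
  params <- list()
  make_conv <- function(cin, cout) {
    list(W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9L * cin, cout),
         b = numeric(cout))
  }
  cin <- in_channels
  for (i in seq_len(d)) {
    params[[paste0("enc", i)]] <- make_conv(cin, base * 2^(i - 1L))
    cin <- base * 2^(i - 1L)
  }
  params$bottleneck <- make_conv(cin, base * 2^d)
  for (i in rev(seq_len(d))) {
    cin_dec <- base * 2^i + base * 2^(i - 1L)   # upsampled + skip
    params[[paste0("dec", i)]] <- make_conv(cin_dec, base * 2^(i - 1L))
  }
  params$head <- list(W = matrix(stats::rnorm(base, 0, sqrt(2 / base)),
                                 base, 1L),
                      b = 0)
  params
}

# forward pass; X is (H*W) x 3; returns logits and a tape for backprop
unet_forward <- function(params, X, H, W, config, tape = FALSE) {
  d <- config$depth
  acts <- list(); sizes <- list()
  cur <- X; h <- H; w <- W
  enc_out <- list()
  for (i in seq_len(d)) {
    cv <- conv_forward(cur, params[[paste0("enc", i)]]$W,
                       params[[paste0("enc", i)]]$b, h, w)
    a <- pmax(cv$Y, 0)
    enc_out[[i]] <- a
    if (tape) acts[[paste0("enc", i)]] <- list(Xcol = cv$Xcol, pre = cv$Y,
                                               h = h, w = w, cin = ncol(cur))
    mp <- maxpool_forward(a, h, w)
    if (tape) acts[[paste0("pool", i)]] <- list(amax = mp$amax, h = h, w = w,
                                                C = ncol(a))
    cur <- mp$Y; h <- h / 2L; w <- w / 2L
  }
  cv <- conv_forward(cur, params$bottleneck$W, params$bottleneck$b, h, w)
  a <- pmax(cv$Y, 0)
  if (tape) acts$bottleneck <- list(Xcol = cv$Xcol, pre = cv$Y, h = h, w = w,
                                    cin = ncol(cur))
  cur <- a
  for (i in rev(seq_len(d))) {
    h2 <- h * 2L; w2 <- w * 2L
    up <- upsample_forward(cur, h2, w2)
    cat_in <- cbind(up, enc_out[[i]])
    cv <- conv_forward(cat_in, params[[paste0("dec", i)]]$W,
                       params[[paste0("dec", i)]]$b, h2, w2)
    a <- pmax(cv$Y, 0)
    if (tape) acts[[paste0("dec", i)]] <- list(Xcol = cv$Xcol, pre = cv$Y,
                                               h = h2, w = w2,
                                               cin = ncol(cat_in),
                                               up_cols = ncol(up))
    cur <- a; h <- h2; w <- w2
  }
  logits <- cur %*% params$head$W + params$head$b
  if (tape) acts$head_in <- cur
  list(logits = logits, tape = if (tape) acts else NULL)
}

# backward pass from dlogits; returns gradient list matching params
unet_backward <- function(params, tape, dlogits, config) {
  d <- config$depth
  grads <- list()
  head_in <- tape$head_in
  grads$head <- list(W = crossprod(head_in, dlogits),
                     b = sum(dlogits))
  dcur <- dlogits %*% t(params$head$W)
  dskip <- vector("list", d)
  for (i in seq_len(d)) {         # decoder levels, shallow to deep
    t_i <- tape[[paste0("dec", i)]]
    dpre <- dcur * (t_i$pre > 0)
    bk <- conv_backward(dpre, t_i$Xcol, params[[paste0("dec", i)]]$W,
                        t_i$cin, t_i$h, t_i$w)
    grads[[paste0("dec", i)]] <- list(W = bk$dW, b = bk$db)
    dup <- bk$dX[, seq_len(t_i$up_cols), drop = FALSE]
    dskip[[i]] <- bk$dX[, -seq_len(t_i$up_cols), drop = FALSE]
    dcur <- upsample_backward(dup, t_i$h, t_i$w)
  }
  tb <- tape$bottleneck
  dpre <- dcur * (tb$pre > 0)
  bk <- conv_backward(dpre, tb$Xcol, params$bottleneck$W, tb$cin, tb$h, tb$w)
  grads$bottleneck <- list(W = bk$dW, b = bk$db)
  dcur <- bk$dX
  for (i in rev(seq_len(d))) {    # encoder levels, deep to shallow
    tp <- tape[[paste0("pool", i)]]
    dcur <- maxpool_backward(dcur, tp$amax, tp$h, tp$w, tp$C)
    dcur <- dcur + dskip[[i]]
    te <- tape[[paste0("enc", i)]]
    dpre <- dcur * (te$pre > 0)
    bk <- conv_backward(dpre, te$Xcol, params[[paste0("enc", i)]]$W,
                        te$cin, te$h, te$w)
    grads[[paste0("enc", i)]] <- list(W = bk$dW, b = bk$db)
    dcur <- bk$dX
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    st <- state[[nm]]; g <- grads[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (st$mW / bc1) /
      (sqrt(st$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / bc1) /
      (sqrt(st$vb / bc2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# ---- training and evaluation ----------------------------------------------

#' Train the segmenter on RGB synthesized with one transmittance curve
#'
#' Exposure is computed once from the training scenes' no-filter images
#' and stored in the model, so that later curve swaps share the same
#' radiometric scale. The returned model is frozen.
#'
#' @param train_scenes List of scenes from [make_scene()].
#' @param filter_curve Training-time transmittance [spectral_curve()]
#'   (`NULL` for the no-filter baseline).
#' @param csr Camera spectral response (default [default_csr()]).
#' @param config A [seg_config()].
#' @param val_scenes Optional validation scenes; if given, the model
#'   carries `val_miou`.
#' @return Object of class `seg_model` with fields `params`, `config`,
#'   `exposure`, `csr`, `frozen`, `loss_trace`, and optionally `val_miou`.
#' @export
train_segmenter <- function(train_scenes, filter_curve = NULL, csr = NULL,
                            config = seg_config(), val_scenes = NULL) {
  if (length(train_scenes) == 0L) {
    stop("training set is empty", call. = FALSE)
  }
  H <- dim(train_scenes[[1]]$cube)[1]
  W <- dim(train_scenes[[1]]$cube)[2]
  if (H %% 2^config$depth != 0 || W %% 2^config$depth != 0) {
    stop("scene size must be divisible by 2^depth", call. = FALSE)
  }
  wl <- train_scenes[[1]]$wavelengths
  cs <- if (is.null(csr)) default_csr(wl) else resample_csr(csr, wl)
  exposure <- auto_exposure(train_scenes, cs)

  images <- lapply(train_scenes, function(sc) {
    img <- synthesize_rgb(sc, filter_curve, cs, exposure)
    matrix(img, ncol = 3L)
  })
  labels <- lapply(train_scenes, function(sc) as.numeric(sc$mask))

  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  params <- unet_init(config)
  state <- adam_init(params)
  tstep <- 0L
  loss_trace <- numeric(0)
  n <- length(images)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (ii in ord) {
      fw <- unet_forward(params, images[[ii]], H, W, config, tape = TRUE)
      p <- stats::plogis(fw$logits)
      y <- labels[[ii]]
      loss <- -mean(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12)))
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss / n
      dlogits <- (p - y) / length(y)
      grads <- unet_backward(params, fw$tape, dlogits, config)
      tstep <- tstep + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, tstep)
      params <- upd$params; state <- upd$state
    }
    loss_trace <- c(loss_trace, epoch_loss)
  }

  model <- structure(list(params = params, config = config,
                          exposure = exposure, csr = cs,
                          filter_curve = filter_curve,
                          height = H, width = W,
                          loss_trace = loss_trace, frozen = TRUE),
                     class = "seg_model")
  if (!is.null(val_scenes) && length(val_scenes)) {
    preds <- lapply(val_scenes, function(sc) predict_mask(model, sc,
                                                          filter_curve))
    gts <- lapply(val_scenes, function(sc) sc$mask)
    model$val_miou <- mean_iou(preds, gts)
  }
  model
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "<seg_model> depth %d, base %d | %d epochs, final loss %.4f%s%s\n",
    x$config$depth, x$config$base_channels, length(x$loss_trace),
    utils::tail(x$loss_trace, 1),
    if (!is.null(x$val_miou)) sprintf(" | val mIoU %.3f", x$val_miou) else "",
    if (isTRUE(x$frozen)) " | frozen" else ""))
  invisible(x)
}

#' Predict a binary segmentation mask for one scene
#'
#' @param model A trained [train_segmenter()] model.
#' @param scene A scene (its RGB is synthesized with the model's stored
#'   exposure and CSR).
#' @param filter_curve Transmittance curve for the optical-filter layer;
#'   `NULL` for no filter.
#' @return H x W integer matrix (1 = pepper).
#' @export
predict_mask <- function(model, scene, filter_curve = NULL) {
  img <- synthesize_rgb(scene, filter_curve, model$csr, model$exposure)
  X <- matrix(img, ncol = 3L)
  fw <- unet_forward(model$params, X, model$height, model$width,
                     model$config, tape = FALSE)
  p <- stats::plogis(fw$logits)
  matrix(as.integer(p >= model$config$threshold), model$height, model$width)
}

#' Mean intersection over union between predictions and ground truth
#'
#' `mIoU = (1/k) sum_i |P_i & G_i| / |P_i | G_i|` over the `k` classes;
#' intersections and unions are accumulated across all supplied mask
#' pairs, and classes whose union is empty everywhere are skipped from
#' the mean.
#'
#' @param predictions Integer matrix or list of matrices.
#' @param ground_truths Matching matrix or list.
#' @param num_classes Number of classes (labels `0 .. num_classes - 1`).
#' @return Scalar mIoU in `[0, 1]`.
#' @examples
#' g <- matrix(c(1, 1, 0, 0), 2)
#' p <- matrix(c(1, 0, 0, 0), 2)
#' mean_iou(p, g)  # (1/2 + 2/3) / 2 = 7/12
#' @export
mean_iou <- function(predictions, ground_truths, num_classes = 2L) {
  if (!is.list(predictions)) predictions <- list(predictions)
  if (!is.list(ground_truths)) ground_truths <- list(ground_truths)
  if (length(predictions) != length(ground_truths)) {
    stop("prediction and ground-truth lists differ in length", call. = FALSE)
  }
  inter <- numeric(num_classes); union <- numeric(num_classes)
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]; g <- ground_truths[[i]]
    if (!all(dim(p) == dim(g))) {
      stop("mask shape mismatch at pair ", i, call. = FALSE)
    }
    for (cls in seq_len(num_classes) - 1L) {
      pi <- p == cls; gi <- g == cls
      inter[cls + 1L] <- inter[cls + 1L] + sum(pi & gi)
      union[cls + 1L] <- union[cls + 1L] + sum(pi | gi)
    }
  }
  keep <- union > 0
  if (!any(keep)) stop("no class present in any mask", call. = FALSE)
  mean(inter[keep] / union[keep])
}

#' Transmittance curves of a design at normal and oblique incidence
#'
#' Emits the named curve set used in swap evaluations: the unpolarized
#' normal-incidence curve plus the s- and p-polarized curves at each
#' oblique angle.
#'
#' @param stack A [layer_stack()] (or `filter_design`, whose stack is
#'   used).
#' @param angles Oblique angles, radians (default 20 degrees).
#' @param grid Wavelength vector, nm.
#' @param prefix Name prefix for the records.
#' @return List of records `list(name, angle_deg, polarization, curve)`.
#' @export
curves_for_design <- function(stack, angles = 20 * pi / 180,
                              grid = default_grid(), prefix = "design") {
  if (inherits(stack, "filter_design")) stack <- stack$stack
  recs <- list(list(name = paste0(prefix, "_0deg"), angle_deg = 0,
                    polarization = "unpolarized",
                    curve = unpolarized_T(stack, 0, grid)))
  for (th in angles) {
    sp <- transmittance_spectrum(stack, th, grid)
    deg <- round(th * 180 / pi, 1)
    recs <- c(recs, list(
      list(name = sprintf("%s_%gdeg_s", prefix, deg), angle_deg = deg,
           polarization = "s", curve = spectral_curve(grid, sp$T_s)),
      list(name = sprintf("%s_%gdeg_p", prefix, deg), angle_deg = deg,
           polarization = "p", curve = spectral_curve(grid, sp$T_p))))
  }
  recs
}

#' Freeze-and-swap evaluation of transmittance curves
#'
#' For each curve: synthesize RGB for every test scene with the frozen
#' model's exposure and CSR, predict, and score mIoU. The model is never
#' modified; an unfrozen model is rejected.
#'
#' @param model A frozen [train_segmenter()] model.
#' @param test_scenes List of scenes.
#' @param curves Named list of [spectral_curve()]s, or a list of records
#'   as returned by [curves_for_design()]; the name `no_filter` (or a
#'   `NULL` curve) denotes the all-ones baseline.
#' @param csr Optional CSR override (default: the model's).
#' @return A tibble of class `swap_report` with columns `curve_name`,
#'   `angle_deg`, `polarization`, `miou`.
#' @export
swap_and_evaluate <- function(model, test_scenes, curves, csr = NULL) {
  if (!isTRUE(model$frozen)) {
    stop("model must be frozen before swap evaluation", call. = FALSE)
  }
  if (!is.null(csr)) model$csr <- resample_csr(csr, model$csr$wavelength)
  recs <- normalize_curve_records(curves)
  gts <- lapply(test_scenes, function(sc) sc$mask)
  rows <- purrr::map(recs, function(rec) {
    preds <- lapply(test_scenes, function(sc) {
      predict_mask(model, sc, rec$curve)
    })
    tibble::tibble(curve_name = rec$name,
                   angle_deg = rec$angle_deg,
                   polarization = rec$polarization,
                   miou = mean_iou(preds, gts))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("swap_report", class(out))
  out
}

normalize_curve_records <- function(curves) {
  purrr::imap(curves, function(x, nm) {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$name)) {
      x
    } else {
      name <- if (is.character(nm) && nzchar(nm)) nm else paste0("curve", nm)
      list(name = name, angle_deg = NA_real_, polarization = NA_character_,
           curve = if (identical(name, "no_filter")) NULL else x)
    }
  })
}

#' @export
autoplot.swap_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$curve_name, .data$miou)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mIoU")
}
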