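# 2.5D adversarial slice segmenter: each axial slice, stacked with its
# neighbours above and below as three channels, is mapped to a binary
# segmentation by a U-Net generator trained against a patch discriminator.
# The generator loss is the adversarial term plus an L1 term weighted 10:1,
# optimized with Adam (learning rate 2e-4, first-moment decay 0.5).

#' Adversarial segmenter configuration
#'
#' Clinical-scale defaults follow the training recipe the pipeline was
#' designed around: 256 x 256 inputs, 50 epochs, Adam with learning rate
#' 2e-4 and beta1 = 0.5, and a generator loss of `1.0 * L_GAN + 10.0 * L_L1`.
#' Desk-scale runs use `train_size = 64`.
#'
#' @param train_size In-plane sample size; a power of two >= 32.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param beta1 Adam first-moment decay (momentum term).
#' @param lambda_l1,lambda_gan Loss weights; both must be positive.
#' @param batch_size Samples per optimizer step.
#' @param base_width Generator channel width at the finest level; widths
#'   double per level, capped at 8x.
#' @param depth Down/upsampling levels; default `log2(train_size) - 2`
#'   (4 at size 64).
#' @param threshold Binarization threshold on the generator's sigmoid
#'   output.
#' @param gan_variant `"log"` for the classical saturating adversarial
#'   generator loss (the published form), `"nonsaturating"` for the stable
#'   `-log D(x, G(x))` alternative.
#' @param hu_window Soft-tissue intensity window (HU) used for input
#'   normalization; values are clipped to it and scaled to `[-1, 1]`.
#' @param seed Seed for weight initialization and sample shuffling.
#' @return List of class `gan_config`.
#' @export
gan_config <- function(train_size = 256, epochs = 50, lr = 2e-4,
                       beta1 = 0.5, lambda_l1 = 10, lambda_gan = 1,
                       batch_size = 8, base_width = 8, depth = NULL,
                       threshold = 0.5,
                       gan_variant = c("log", "nonsaturating"),
                       hu_window = c(-200, 300), seed = 1) {
  gan_variant <- match.arg(gan_variant)
  if (train_size < 32 || bitwAnd(train_size, train_size - 1L) != 0)
    stop("train_size must be a power of two >= 32", call. = FALSE)
  if (lambda_l1 <= 0 || lambda_gan <= 0)
    stop("loss weights must be positive", call. = FALSE)
  if (is.null(depth)) depth <- as.integer(log2(train_size)) - 2L
  structure(list(train_size = as.integer(train_size),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 lambda_l1 = lambda_l1, lambda_gan = lambda_gan,
                 batch_size = as.integer(batch_size),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth), threshold = threshold,
                 gan_variant = gan_variant, hu_window = hu_window,
                 seed = as.integer(seed)),
            class = "gan_config")
}

# normalize a HU slice to [-1, 1] over the configured soft-tissue window
#' @noRd
.normalize_hu <- function(slice, window) {
  s <- .clamp(slice, window[1], window[2])
  2 * (s - window[1]) / (window[2] - window[1]) - 1
}

#' Build 2.5D training samples from one annotated volume
#'
#' Every interior slice `z` (2 to n-1; the first and last slice lack one
#' axial neighbour) becomes one sample whose three channels are the slices
#' below, at, and above `z`, intensity-windowed and resized in-plane to
#' `train_size` (bilinear for the image, nearest-neighbour for the label so
#' it stays strictly binary).
#'
#' @param volume An [image_volume()] with at least 3 slices.
#' @param mask Its ground-truth [binary_mask()] (may be `NULL` at
#'   inference).
#' @param cfg A [gan_config()].
#' @return List of `n - 2` samples: `list(input = train_size^2 x 3 array,
#'   label = matrix or NULL, case_id, z)`.
#' @export
build_slice_samples <- function(volume, mask = NULL, cfg = gan_config()) {
  stopifnot(inherits(volume, "image_volume"))
  nz <- dim(volume$voxels)[3]
  if (nz < 3) stop("2.5D stacking needs at least 3 slices", call. = FALSE)
  if (!is.null(mask)) stop_if_grid_mismatch(volume, mask, "volume/mask")
  ts <- cfg$train_size
  norm_resized <- lapply(seq_len(nz), function(z) {
    resize2(.normalize_hu(volume$voxels[, , z], cfg$hu_window), ts, ts,
            "bilinear")
  })
  lab_resized <- if (!is.null(mask)) {
    lapply(seq_len(nz), function(z) {
      resize2(mask$voxels[, , z] * 1, ts, ts, "nearest")
    })
  }
  lapply(2:(nz - 1), function(z) {
    inp <- array(0, c(ts, ts, 3))
    inp[, , 1] <- norm_resized[[z - 1]]
    inp[, , 2] <- norm_resized[[z]]
    inp[, , 3] <- norm_resized[[z + 1]]
    list(input = inp,
         label = if (!is.null(mask)) lab_resized[[z]] else NULL,
         case_id = volume$case_id, z = z)
  })
}

#' Pixel-level L1 loss
#'
#' Mean absolute difference between the generated map and the target,
#' `E[ ||y - G(x)||_1 ]` taken per pixel; zero iff the two agree exactly.
#'
#' @param gen_out,target Arrays of identical shape.
#' @return Non-negative scalar.
#' @export
l1_loss <- function(gen_out, target) {
  if (!identical(dim(gen_out), dim(target)) &&
      length(gen_out) != length(target))
    stop("shape mismatch", call. = FALSE)
  if (any(!is.finite(gen_out)) || any(!is.finite(target)))
    stop("non-finite input to l1_loss", call. = FALSE)
  mean(abs(target - gen_out))
}

#' Adversarial loss value
#'
#' `E_y[log D(x, y)] + E_x[log(1 - D(x, G(x)))]` evaluated from the
#' discriminator's outputs on real and generated pairs. The discriminator
#' ascends this objective, the generator descends it.
#'
#' @param d_real Discriminator outputs on (image, true-mask) pairs, in
#'   (0, 1).
#' @param d_fake Discriminator outputs on (image, generated-mask) pairs.
#' @return Scalar loss value.
#' @export
gan_loss <- function(d_real, d_fake) {
  if (any(!is.finite(d_real)) || any(!is.finite(d_fake)))
    stop("non-finite discriminator output", call. = FALSE)
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1))
    stop("discriminator outputs must lie strictly in (0, 1)", call. = FALSE)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

# ---- generator (U-Net) ----

#' @noRd
.gen_widths <- function(cfg) {
  w <- pmin(cfg$base_width * 2^(0:cfg$depth), cfg$base_width * 8L)
  as.integer(w)  # w[l] feeds level l; w[depth+1] is the bottleneck width
}

#' @noRd
gen_init <- function(cfg) {
  w <- .gen_widths(cfg)
  L <- cfg$depth
  par <- list(enc = conv_init(3, 3, 3, w[1]), enc_n = inorm_init(w[1]),
              down = vector("list", L), down_n = vector("list", L),
              up = vector("list", L), up_n = vector("list", L))
  for (l in seq_len(L)) {
    par$down[[l]] <- conv_init(4, 4, w[l], w[l + 1])
    par$down_n[[l]] <- inorm_init(w[l + 1])
  }
  for (l in seq_len(L)) {
    cin <- if (l == L) w[L + 1] else 2L * w[l + 1]
    par$up[[l]] <- conv_init(3, 3, cin, w[l])
    par$up_n[[l]] <- inorm_init(w[l])
  }
  par$out <- conv_init(3, 3, 2L * w[1], 1)
  par
}

#' @noRd
gen_forward <- function(x, par, cfg, keep_cache = TRUE) {
  L <- cfg$depth
  caches <- list(enc = NULL, down = vector("list", L),
                 up = vector("list", L))
  r <- conv_fwd(x, par$enc, stride = 1, pad = 1)
  nm <- inorm_fwd(r$out, par$enc_n)
  a <- lrelu_fwd(nm$out)
  caches$enc <- list(conv = r$cache, norm = nm$cache, act = a$cache)
  h <- a$out
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    skips[[l]] <- h
    r <- conv_fwd(h, par$down[[l]], stride = 2, pad = 1)
    nm <- inorm_fwd(r$out, par$down_n[[l]])
    a <- lrelu_fwd(nm$out)
    caches$down[[l]] <- list(conv = r$cache, norm = nm$cache, act = a$cache)
    h <- a$out
  }
  for (l in rev(seq_len(L))) {
    h <- upsample2_fwd(h)
    r <- conv_fwd(h, par$up[[l]], stride = 1, pad = 1)
    nm <- inorm_fwd(r$out, par$up_n[[l]])
    a <- lrelu_fwd(nm$out)
    caches$up[[l]] <- list(conv = r$cache, norm = nm$cache, act = a$cache,
                           ch = dim(r$out)[3])
    d <- dim(a$out)
    h <- array(c(a$out, skips[[l]]), c(d[1], d[2], d[3] + dim(skips[[l]])[3]))
  }
  r <- conv_fwd(h, par$out, stride = 1, pad = 1)
  y <- sigmoid(r$out[, , 1])
  caches$out <- r$cache
  caches$y <- y
  list(y = y, caches = if (keep_cache) caches else NULL)
}

# backward through the generator given dL/dy (y = sigmoid output)
#' @noRd
gen_backward <- function(dy, par, cfg, caches) {
  L <- cfg$depth
  y <- caches$y
  dpre <- array(dy * y * (1 - y), c(dim(y), 1))
  r <- conv_bwd(dpre, par$out, caches$out)
  grads <- list(enc = NULL, enc_n = NULL, down = vector("list", L),
                down_n = vector("list", L), up = vector("list", L),
                up_n = vector("list", L), out = r$grads)
  dh <- r$dx
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    ch <- caches$up[[l]]$ch
    dup <- dh[, , seq_len(ch), drop = FALSE]
    dskips[[l]] <- dh[, , (ch + 1):dim(dh)[3], drop = FALSE]
    dup <- lrelu_bwd(dup, caches$up[[l]]$act)
    bn <- inorm_bwd(dup, par$up_n[[l]], caches$up[[l]]$norm)
    grads$up_n[[l]] <- bn$grads
    r <- conv_bwd(bn$dx, par$up[[l]], caches$up[[l]]$conv)
    grads$up[[l]] <- r$grads
    dh <- upsample2_bwd(r$dx)
  }
  for (l in rev(seq_len(L))) {
    dh <- lrelu_bwd(dh, caches$down[[l]]$act)
    bn <- inorm_bwd(dh, par$down_n[[l]], caches$down[[l]]$norm)
    grads$down_n[[l]] <- bn$grads
    r <- conv_bwd(bn$dx, par$down[[l]], caches$down[[l]]$conv)
    grads$down[[l]] <- r$grads
    dh <- r$dx + dskips[[l]]
  }
  dh <- lrelu_bwd(dh, caches$enc$act)
  bn <- inorm_bwd(dh, par$enc_n, caches$enc$norm)
  grads$enc_n <- bn$grads
  r <- conv_bwd(bn$dx, par$enc, caches$enc$conv)
  grads$enc <- r$grads
  grads
}

# ---- discriminator (3-layer patch classifier) ----

#' @noRd
disc_init <- function(cfg) {
  w <- cfg$base_width
  list(c1 = conv_init(4, 4, 4, 2L * w),
       c2 = conv_init(4, 4, 2L * w, 4L * w), c2_n = inorm_init(4L * w),
       c3 = conv_init(3, 3, 4L * w, 1))
}

#' @noRd
disc_forward <- function(x, y, par) {
  d <- dim(x)
  xy <- array(c(x, y), c(d[1], d[2], 4))
  r1 <- conv_fwd(xy, par$c1, stride = 2, pad = 1); a1 <- lrelu_fwd(r1$out)
  r2 <- conv_fwd(a1$out, par$c2, stride = 2, pad = 1)
  n2 <- inorm_fwd(r2$out, par$c2_n)
  a2 <- lrelu_fwd(n2$out)
  r3 <- conv_fwd(a2$out, par$c3, stride = 1, pad = 1)
  p <- sigmoid(r3$out[, , 1])
  list(p = p, caches = list(r1 = r1$cache, a1 = a1$cache, r2 = r2$cache,
                            n2 = n2$cache, a2 = a2$cache, r3 = r3$cache,
                            p = p))
}

# backward given dL/dp; returns grads and dL/d(y-channel of the input)
#' @noRd
disc_backward <- function(dp, par, caches) {
  p <- caches$p
  dpre <- array(dp * p * (1 - p), c(dim(p), 1))
  r3 <- conv_bwd(dpre, par$c3, caches$r3)
  d2 <- lrelu_bwd(r3$dx, caches$a2)
  b2 <- inorm_bwd(d2, par$c2_n, caches$n2)
  r2 <- conv_bwd(b2$dx, par$c2, caches$r2)
  d1 <- lrelu_bwd(r2$dx, caches$a1)
  r1 <- conv_bwd(d1, par$c1, caches$r1)
  list(grads = list(c1 = r1$grads, c2 = r2$grads, c2_n = b2$grads,
                    c3 = r3$grads),
       dy = r1$dx[, , 4])
}

# ---- training and inference ----

#' Train the adversarial segmenter
#'
#' Alternating discriminator/generator Adam updates. Per batch the
#' discriminator ascends `log D(x,y) + log(1 - D(x,G(x)))`; the generator
#' descends `lambda_gan * L_GAN + lambda_l1 * L_L1` (with the adversarial
#' part in the configured variant). Runs are repeatable for a fixed seed
#' and configuration on one machine.
#'
#' @param samples List from [build_slice_samples()] (labels required).
#' @param cfg A [gan_config()].
#' @param verbose Print per-epoch losses.
#' @return List of class `gan_generator`: `params`, `cfg`, `trace`
#'   (per-epoch mean L1 / adversarial losses, with epoch 0 the
#'   initialization).
#' @export
gan_train <- function(samples, cfg = gan_config(), verbose = FALSE) {
  if (length(samples) == 0) stop("no training samples", call. = FALSE)
  if (is.null(samples[[1]]$label))
    stop("training samples need labels", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  G <- gen_init(cfg)
  D <- disc_init(cfg)
  stG <- adam_init(G); stD <- adam_init(D)
  eps <- 1e-7
  n <- length(samples)
  trace <- data.frame(epoch = 0:cfg$epochs, l1 = NA_real_, adv = NA_real_)

  epoch_l1_at_init <- mean(vapply(samples, function(s) {
    l1_loss(gen_forward(s$input, G, cfg, keep_cache = FALSE)$y, s$label)
  }, numeric(1)))
  trace$l1[1] <- epoch_l1_at_init

  if (cfg$epochs > 0) for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    sum_l1 <- 0; sum_adv <- 0
    starts <- seq(1, n, by = cfg$batch_size)
    for (b in starts) {
      bi <- ord[b:min(b + cfg$batch_size - 1L, n)]
      gD <- NULL; gG <- NULL
      for (i in bi) {
        s <- samples[[i]]
        fw <- gen_forward(s$input, G, cfg)
        y_fake <- fw$y
        # --- discriminator update terms (generator detached) ---
        fr <- disc_forward(s$input, s$label, D)
        ff <- disc_forward(s$input, y_fake, D)
        pr <- .clamp(fr$p, eps, 1 - eps)
        pf <- .clamp(ff$p, eps, 1 - eps)
        npatch <- length(pr)
        # D minimizes -(log D_real + log(1 - D_fake))
        bd_r <- disc_backward(matrix(-1 / pr / npatch, nrow(pr)), D,
                              fr$caches)
        bd_f <- disc_backward(matrix(1 / (1 - pf) / npatch, nrow(pf)), D,
                              ff$caches)
        gD <- grads_add(gD, grads_add(bd_r$grads, bd_f$grads))
        # --- generator update terms (D is fixed within the batch, so the
        # fake forward pass is reused) ---
        dadv_dp <- if (cfg$gan_variant == "log") {
          # d/dp of log(1 - p), descended
          matrix(-1 / (1 - pf) / npatch, nrow(pf))
        } else {
          matrix(-1 / pf / npatch, nrow(pf))
        }
        bd_g <- disc_backward(dadv_dp, D, ff$caches)
        l1v <- l1_loss(y_fake, s$label)
        dl1 <- sign(y_fake - s$label) / length(y_fake)
        dy <- cfg$lambda_gan * bd_g$dy + cfg$lambda_l1 * dl1
        gG <- grads_add(gG, gen_backward(dy, G, cfg, fw$caches))
        sum_l1 <- sum_l1 + l1v
        sum_adv <- sum_adv + gan_loss(pr, pf)
      }
      nb <- length(bi)
      if (!all(vapply(rapply(gD, function(z) all(is.finite(z)), how = "unlist"),
                      isTRUE, logical(1))))
        stop("training diverged (non-finite discriminator gradient); returning no model",
             call. = FALSE)
      upd <- adam_step(D, grads_scale(gD, 1 / nb), stD, cfg$lr, cfg$beta1)
      D <- upd$params; stD <- upd$state
      upg <- adam_step(G, grads_scale(gG, 1 / nb), stG, cfg$lr, cfg$beta1)
      G <- upg$params; stG <- upg$state
    }
    trace$l1[ep + 1] <- sum_l1 / n
    trace$adv[ep + 1] <- sum_adv / n
    if (verbose)
      message(sprintf("epoch %d: L1 %.4f adv %.4f", ep, trace$l1[ep + 1],
                      trace$adv[ep + 1]))
  }
  structure(list(params = G, disc = D, cfg = cfg, trace = trace),
            class = "gan_generator")
}

#' Predict a segmentation mask for a whole volume
#'
#' Runs the generator slice by slice. Interior slices use their true axial
#' neighbours; the first and last slice (excluded from training because
#' they lack one neighbour) are completed with replicated-neighbour
#' padding so every slice of the volume is defined. Sigmoid outputs are
#' thresholded and resized back to the native in-plane grid with
#' nearest-neighbour interpolation.
#'
#' @param volume An [image_volume()].
#' @param generator A [gan_train()] result.
#' @param cfg Optional [gan_config()]; defaults to the generator's own.
#' @return A [binary_mask()] on the input grid.
#' @export
gan_predict <- function(volume, generator, cfg = NULL) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(generator, "gan_generator"))
  if (is.null(cfg)) cfg <- generator$cfg
  d <- dim(volume$voxels)
  nz <- d[3]
  ts <- cfg$train_size
  norm <- lapply(seq_len(nz), function(z) {
    resize2(.normalize_hu(volume$voxels[, , z], cfg$hu_window), ts, ts,
            "bilinear")
  })
  out <- array(FALSE, d)
  for (z in seq_len(nz)) {
    zb <- max(z - 1, 1); za <- min(z + 1, nz)   # replicate at the edges
    inp <- array(0, c(ts, ts, 3))
    inp[, , 1] <- norm[[zb]]
    inp[, , 2] <- norm[[z]]
    inp[, , 3] <- norm[[za]]
    y <- gen_forward(inp, generator$params, cfg, keep_cache = FALSE)$y
    pred <- resize2(y, d[1], d[2], "nearest") >= cfg$threshold
    out[, , z] <- pred
  }
  binary_mask(out, spacing = volume$spacing, case_id = volume$case_id,
              label = "bilateral")
}
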