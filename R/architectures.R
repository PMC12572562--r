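# The five network variants of the ablation: classic U-Net, VGG16 U-Net, and
# the squeeze-and-excitation / attention-gate / dual-attention versions of the
# VGG16 U-Net. One generic encoder-decoder skeleton covers all five; the
# variant toggles widths, batch-norm and the two attention mechanisms.

.VARIANTS <- c("unet", "vgg16_unet", "se_vgg16_unet", "ag_vgg16_unet",
               "se_ag_vgg16_unet")

.variant_arch <- function(variant) {
  variant <- match.arg(variant, .VARIANTS)
  vgg <- variant != "unet"
  enc_widths <- if (vgg) c(64L, 128L, 256L, 512L, 512L) else c(64L, 128L, 256L, 512L, 1024L)
  dec_widths <- c(512L, 256L, 128L, 64L)
  list(variant = variant,
       enc_widths = enc_widths,
       enc_convs = if (vgg) c(2L, 2L, 3L, 3L, 3L) else rep(2L, 5L),
       dec_widths = dec_widths,
       dec_bn = vgg,
       head = if (vgg) "softmax_1x1" else "unet_head",
       se = variant %in% c("se_vgg16_unet", "se_ag_vgg16_unet"),
       ag = variant %in% c("ag_vgg16_unet", "se_ag_vgg16_unet"),
       se_ratio = 64L,
       # decoder level l: skip from encoder block 5-l, gating from the coarser
       # decoder state (the bridge for level 1)
       skip_widths = enc_widths[4:1],
       gate_widths = c(enc_widths[5], dec_widths[1:3]),
       ag_inter = pmax(c(enc_widths[5], dec_widths[1:3]) %/% 4L, 1L))
}

#' Build a segmentation network
#'
#' Constructs one of the five wound-segmentation variants with Glorot-uniform
#' initial weights. `vgg16_unet` uses the standard VGG16 convolutional stack
#' (64,64 | 128,128 | 256,256,256 | 512,512,512 | 512,512,512) as encoder,
#' with skip connections taken before each of the first four poolings and the
#' fifth block acting as the bridge; the decoder mirrors U-Net with 2x2
#' transposed convolutions and widths 512,256,128,64. `se_*` variants insert a
#' squeeze-and-excitation block after every encoder and decoder stage (nine
#' sites); `ag_*` variants gate each of the four skip connections with an
#' additive attention gate; `se_ag_vgg16_unet` (the dual-attention model)
#' applies both. `unet` is the classic 64..1024 double-convolution U-Net.
#' The output head produces a two-channel softmax whose foreground channel is
#' returned as a single wound-probability map.
#'
#' @param variant One of `r paste0('"', .VARIANTS, '"', collapse = ", ")`.
#' @param input_rows,input_cols Input image extents; multiples of 16, >= 16.
#' @param seed Integer seed controlling initialisation; the same seed always
#'   yields identical initial parameters.
#' @return An object of class `wound_network`.
#' @examples
#' net <- build_network("se_ag_vgg16_unet", 32, 32, seed = 1)
#' count_params(net)
#' @export
build_network <- function(variant, input_rows = 480L, input_cols = 640L,
                          seed = 1L) {
  a <- .variant_arch(variant)
  input_rows <- as.integer(input_rows)
  input_cols <- as.integer(input_cols)
  if (input_rows < 16L || input_cols < 16L ||
      input_rows %% 16L != 0L || input_cols %% 16L != 0L) {
    stop("input extents must be multiples of 16 and at least 16")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  P <- list()
  trainable <- character(0)
  frozen <- character(0)
  add <- function(name, val, train = TRUE) {
    P[[name]] <<- val
    if (train) trainable <<- c(trainable, name) else frozen <<- c(frozen, name)
  }
  cin <- 3L
  for (i in 1:5) {
    w <- a$enc_widths[i]
    for (j in seq_len(a$enc_convs[i])) {
      add(sprintf("enc%d_conv%d_w", i, j), .glorot(c(3L, 3L, cin, w)))
      add(sprintf("enc%d_conv%d_b", i, j), numeric(w))
      cin <- w
    }
    if (a$se) {
      bott <- max(w %/% a$se_ratio, 1L)
      add(sprintf("enc%d_se_w1", i), .glorot(c(w, bott)))
      add(sprintf("enc%d_se_w2", i), .glorot(c(bott, w)))
    }
  }
  prev <- a$enc_widths[5]
  for (l in 1:4) {
    w <- a$dec_widths[l]
    s <- a$skip_widths[l]
    add(sprintf("dec%d_up_w", l), .glorot(c(2L, 2L, prev, w)))
    add(sprintf("dec%d_up_b", l), numeric(w))
    if (a$ag) {
      k <- a$ag_inter[l]
      g <- a$gate_widths[l]
      add(sprintf("dec%d_ag_theta_w", l), .glorot(c(1L, 1L, s, k)))
      add(sprintf("dec%d_ag_theta_b", l), numeric(k))
      add(sprintf("dec%d_ag_phi_w", l), .glorot(c(1L, 1L, g, k)))
      add(sprintf("dec%d_ag_phi_b", l), numeric(k))
      add(sprintf("dec%d_ag_psi_w", l), .glorot(c(1L, 1L, k, 1L)))
      add(sprintf("dec%d_ag_psi_b", l), numeric(1))
    }
    cin2 <- w + s
    for (j in 1:2) {
      add(sprintf("dec%d_conv%d_w", l, j), .glorot(c(3L, 3L, cin2, w)))
      add(sprintf("dec%d_conv%d_b", l, j), numeric(w))
      if (a$dec_bn) {
        add(sprintf("dec%d_bn%d_gamma", l, j), rep(1, w))
        add(sprintf("dec%d_bn%d_beta", l, j), numeric(w))
        add(sprintf("dec%d_bn%d_rmean", l, j), numeric(w), train = FALSE)
        add(sprintf("dec%d_bn%d_rvar", l, j), rep(1, w), train = FALSE)
      }
      cin2 <- w
    }
    if (a$se) {
      bott <- max(w %/% a$se_ratio, 1L)
      add(sprintf("dec%d_se_w1", l), .glorot(c(w, bott)))
      add(sprintf("dec%d_se_w2", l), .glorot(c(bott, w)))
    }
    prev <- w
  }
  if (a$head == "softmax_1x1") {
    add("head1_w", .glorot(c(1L, 1L, 64L, 2L)))
    add("head1_b", numeric(2))
  } else {
    add("head1_w", .glorot(c(3L, 3L, 64L, 2L)))
    add("head1_b", numeric(2))
    add("head2_w", .glorot(c(1L, 1L, 2L, 2L)))
    add("head2_b", numeric(2))
  }

  net <- structure(list(variant = a$variant, arch = a,
                        input_rows = input_rows, input_cols = input_cols,
                        seed = as.integer(seed), params = P,
                        trainable = trainable, frozen = frozen),
                   class = "wound_network")
  net
}

#' Total parameter count of a network
#'
#' Sum of the sizes of every parameter tensor, including batch-norm scale,
#' shift and moving statistics (the bookkeeping used by framework model
#' summaries, which the published counts follow).
#'
#' @param net A `wound_network`.
#' @return Integer count.
#' @export
count_params <- function(net) {
  stopifnot(inherits(net, "wound_network"))
  sum(vapply(net$params, length, numeric(1)))
}

#' Per-layer summary table
#'
#' @param net A `wound_network`.
#' @param file Optional path; written as CSV when it ends in `.csv`, plain
#'   text otherwise.
#' @return Data frame with layer name, output shape at the build resolution
#'   and parameter count (invisibly when writing to a file).
#' @export
model_summary <- function(net, file = NULL) {
  stopifnot(inherits(net, "wound_network"))
  a <- net$arch
  H <- net$input_rows
  W <- net$input_cols
  rows <- list()
  addrow <- function(name, h, w, c, prefixes) {
    np <- sum(vapply(prefixes, function(p) length(net$params[[p]]), numeric(1)))
    rows[[length(rows) + 1L]] <<- data.frame(layer = name, out_rows = h,
                                             out_cols = w, out_channels = c,
                                             params = np)
  }
  h <- H; w <- W
  for (i in 1:5) {
    cw <- a$enc_widths[i]
    pre <- unlist(lapply(seq_len(a$enc_convs[i]), function(j)
      sprintf("enc%d_conv%d_%s", i, j, c("w", "b"))))
    addrow(sprintf("encoder%d (%d conv)", i, a$enc_convs[i]), h, w, cw, pre)
    if (a$se) addrow(sprintf("encoder%d_se", i), h, w, cw,
                     sprintf("enc%d_se_w%d", i, 1:2))
    if (i < 5) { h <- h / 2; w <- w / 2 }
  }
  for (l in 1:4) {
    cw <- a$dec_widths[l]
    h <- h * 2; w <- w * 2
    addrow(sprintf("decoder%d_up", l), h, w, cw, sprintf("dec%d_up_%s", l, c("w", "b")))
    if (a$ag) addrow(sprintf("decoder%d_gate", l), h, w, a$skip_widths[l],
                     sprintf("dec%d_ag_%s", l,
                             c("theta_w", "theta_b", "phi_w", "phi_b", "psi_w", "psi_b")))
    pre <- unlist(lapply(1:2, function(j) {
      p <- sprintf("dec%d_conv%d_%s", l, j, c("w", "b"))
      if (a$dec_bn) p <- c(p, sprintf("dec%d_bn%d_%s", l, j,
                                      c("gamma", "beta", "rmean", "rvar")))
      p
    }))
    addrow(sprintf("decoder%d (2 conv%s)", l, if (a$dec_bn) " + bn" else ""),
           h, w, cw, pre)
    if (a$se) addrow(sprintf("decoder%d_se", l), h, w, cw,
                     sprintf("dec%d_se_w%d", l, 1:2))
  }
  if (a$head == "softmax_1x1") {
    addrow("head (1x1, softmax)", h, w, 2L, c("head1_w", "head1_b"))
  } else {
    addrow("head (3x3 + 1x1, softmax)", h, w, 2L,
           c("head1_w", "head1_b", "head2_w", "head2_b"))
  }
  out <- do.call(rbind, rows)
  stopifnot(sum(out$params) == count_params(net))
  if (!is.null(file)) {
    if (grepl("\\.csv$", file)) {
      write.csv(out, file, row.names = FALSE)
    } else {
      writeLines(c(sprintf("%-28s %6s %6s %9s %12s", "layer", "rows", "cols",
                           "channels", "params"),
                   sprintf("%-28s %6d %6d %9d %12d", out$layer, out$out_rows,
                           out$out_cols, out$out_channels, out$params),
                   sprintf("total params: %d", sum(out$params))), file)
    }
    return(invisible(out))
  }
  out
}

#' @export
print.wound_network <- function(x, ...) {
  cat(sprintf("<wound_network> variant=%s  input=%dx%d  params=%s  seed=%d\n",
              x$variant, x$input_rows, x$input_cols,
              format(count_params(x), big.mark = ","), x$seed))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

.forward_net <- function(net, x4, train = FALSE, keep = train) {
  a <- net$arch
  P <- net$params
  .check_fmap(x4)
  if (dim(x4)[4] != 3L) stop("input must have 3 channels (RGB)")
  if (any(dim(x4)[2:3] %% 16L != 0L)) stop("input extents must be multiples of 16")
  cache <- list(enc = vector("list", 5), dec = vector("list", 4))
  bn_upd <- list()
  skips <- vector("list", 4)
  h <- x4
  for (i in 1:5) {
    ec <- list(convs = vector("list", a$enc_convs[i]))
    for (j in seq_len(a$enc_convs[i])) {
      xin <- h
      h <- .relu(.conv_fw(h, P[[sprintf("enc%d_conv%d_w", i, j)]],
                          P[[sprintf("enc%d_conv%d_b", i, j)]]))
      if (keep) ec$convs[[j]] <- list(xin = xin, y = h)
    }
    if (a$se) {
      r <- .se_fw(h, P[[sprintf("enc%d_se_w1", i)]], P[[sprintf("enc%d_se_w2", i)]])
      if (keep) ec$se <- r$cache
      h <- r$y
    }
    if (i < 5) {
      skips[[i]] <- h
      pr <- .pool_fw(h)
      if (keep) ec$pool_idx <- pr$idx
      h <- pr$y
    }
    if (keep) cache$enc[[i]] <- ec
  }
  for (l in 1:4) {
    dc <- list(up_in = if (keep) h)
    up <- .convt_fw(h, P[[sprintf("dec%d_up_w", l)]], P[[sprintf("dec%d_up_b", l)]])
    s <- skips[[5 - l]]
    skips[5 - l] <- list(NULL)
    if (a$ag) {
      agp <- .ag_params(P, l)
      r <- .ag_fw(s, h, agp)
      if (keep) {
        dc$ag <- r$cache
        dc$alpha <- r$alpha
      }
      s <- r$gated
    }
    dc$nup <- dim(up)[4]
    h <- .concat_ch(up, s)
    dc$convs <- vector("list", 2)
    for (j in 1:2) {
      cj <- list(xin = if (keep) h)
      h <- .conv_fw(h, P[[sprintf("dec%d_conv%d_w", l, j)]],
                    P[[sprintf("dec%d_conv%d_b", l, j)]])
      if (a$dec_bn) {
        nm <- sprintf("dec%d_bn%d_", l, j)
        bnr <- .bn_fw(h, P[[paste0(nm, "gamma")]], P[[paste0(nm, "beta")]],
                      P[[paste0(nm, "rmean")]], P[[paste0(nm, "rvar")]], train,
                      keep = keep)
        if (keep) cj$bn <- bnr$cache
        if (train) {
          bn_upd[[paste0(nm, "rmean")]] <- bnr$rmean
          bn_upd[[paste0(nm, "rvar")]] <- bnr$rvar
        }
        h <- bnr$y
      }
      h <- .relu(h)
      if (keep) cj$y <- h
      dc$convs[[j]] <- cj
    }
    if (a$se) {
      r <- .se_fw(h, P[[sprintf("dec%d_se_w1", l)]], P[[sprintf("dec%d_se_w2", l)]])
      if (keep) dc$se <- r$cache
      h <- r$y
    }
    if (keep) cache$dec[[l]] <- dc
  }
  if (keep) cache$head_in <- h
  if (a$head == "softmax_1x1") {
    z <- .conv_fw(h, P$head1_w, P$head1_b)
  } else {
    h1 <- .relu(.conv_fw(h, P$head1_w, P$head1_b))
    if (keep) cache$head_mid <- h1
    z <- .conv_fw(h1, P$head2_w, P$head2_b)
  }
  # two-channel softmax; the foreground probability is the sigmoid of the
  # logit difference
  u <- z[, , , 2, drop = FALSE] - z[, , , 1, drop = FALSE]
  p <- .sigmoid(array(u, c(dim(z)[1:3], 1L)))
  cache$p <- p
  list(prob = p, cache = cache, bn_updates = bn_upd)
}

.ag_params <- function(P, l) {
  list(theta_w = P[[sprintf("dec%d_ag_theta_w", l)]],
       theta_b = P[[sprintf("dec%d_ag_theta_b", l)]],
       phi_w = P[[sprintf("dec%d_ag_phi_w", l)]],
       phi_b = P[[sprintf("dec%d_ag_phi_b", l)]],
       psi_w = P[[sprintf("dec%d_ag_psi_w", l)]],
       psi_b = P[[sprintf("dec%d_ag_psi_b", l)]])
}

# du: gradient of the loss w.r.t. the pre-sigmoid logit difference,
# shape (batch, rows, cols, 1). Returns the named gradient list.
.backward_net <- function(net, cache, du) {
  a <- net$arch
  P <- net$params
  G <- new.env(parent = emptyenv())
  gacc <- function(name, val) {
    cur <- G[[name]]
    G[[name]] <- if (is.null(cur)) val else cur + val
  }
  dz <- .concat_ch(-du, du)
  if (a$head == "softmax_1x1") {
    r <- .conv_bw(cache$head_in, P$head1_w, dz)
    gacc("head1_w", r$dw); gacc("head1_b", r$db)
    dh <- r$dx
  } else {
    r2 <- .conv_bw(cache$head_mid, P$head2_w, dz)
    gacc("head2_w", r2$dw); gacc("head2_b", r2$db)
    dh1 <- .relu_bw(r2$dx, cache$head_mid)
    r1 <- .conv_bw(cache$head_in, P$head1_w, dh1)
    gacc("head1_w", r1$dw); gacc("head1_b", r1$db)
    dh <- r1$dx
  }
  dskips <- vector("list", 4)
  for (l in 4:1) {
    dc <- cache$dec[[l]]
    cache$dec[l] <- list(NULL)
    if (a$se) {
      r <- .se_bw(dc$se, P[[sprintf("dec%d_se_w1", l)]],
                  P[[sprintf("dec%d_se_w2", l)]], dh)
      gacc(sprintf("dec%d_se_w1", l), r$dw1)
      gacc(sprintf("dec%d_se_w2", l), r$dw2)
      dh <- r$dx
    }
    for (j in 2:1) {
      cj <- dc$convs[[j]]
      dh <- .relu_bw(dh, cj$y)
      if (a$dec_bn) {
        nm <- sprintf("dec%d_bn%d_", l, j)
        r <- .bn_bw(cj$bn, P[[paste0(nm, "gamma")]], dh)
        gacc(paste0(nm, "gamma"), r$dgamma)
        gacc(paste0(nm, "beta"), r$dbeta)
        dh <- r$dx
      }
      r <- .conv_bw(cj$xin, P[[sprintf("dec%d_conv%d_w", l, j)]], dh)
      gacc(sprintf("dec%d_conv%d_w", l, j), r$dw)
      gacc(sprintf("dec%d_conv%d_b", l, j), r$db)
      dh <- r$dx
    }
    nup <- dc$nup
    ns <- dim(dh)[4] - nup
    dup <- array(dh[, , , seq_len(nup)], c(dim(dh)[1:3], nup))
    dsk <- array(dh[, , , nup + seq_len(ns)], c(dim(dh)[1:3], ns))
    dg_extra <- NULL
    if (a$ag) {
      agp <- .ag_params(P, l)
      r <- .ag_bw(dc$ag, agp, dsk)
      dsk <- r$dx
      dg_extra <- r$dg
      gacc(sprintf("dec%d_ag_theta_w", l), r$dtheta_w)
      gacc(sprintf("dec%d_ag_theta_b", l), r$dtheta_b)
      gacc(sprintf("dec%d_ag_phi_w", l), r$dphi_w)
      gacc(sprintf("dec%d_ag_phi_b", l), r$dphi_b)
      gacc(sprintf("dec%d_ag_psi_w", l), r$dpsi_w)
      gacc(sprintf("dec%d_ag_psi_b", l), r$dpsi_b)
    }
    dskips[[5 - l]] <- dsk
    r <- .convt_bw(dc$up_in, P[[sprintf("dec%d_up_w", l)]], dup)
    gacc(sprintf("dec%d_up_w", l), r$dw)
    gacc(sprintf("dec%d_up_b", l), r$db)
    dh <- r$dx
    if (!is.null(dg_extra)) dh <- dh + dg_extra
  }
  for (i in 5:1) {
    ec <- cache$enc[[i]]
    cache$enc[i] <- list(NULL)
    if (i < 5) {
      dh <- .pool_bw(dh, ec$pool_idx) + dskips[[i]]
    }
    if (a$se) {
      r <- .se_bw(ec$se, P[[sprintf("enc%d_se_w1", i)]],
                  P[[sprintf("enc%d_se_w2", i)]], dh)
      gacc(sprintf("enc%d_se_w1", i), r$dw1)
      gacc(sprintf("enc%d_se_w2", i), r$dw2)
      dh <- r$dx
    }
    for (j in rev(seq_len(a$enc_convs[i]))) {
      cj <- ec$convs[[j]]
      dh <- .relu_bw(dh, cj$y)
      r <- .conv_bw(cj$xin, P[[sprintf("enc%d_conv%d_w", i, j)]], dh)
      gacc(sprintf("enc%d_conv%d_w", i, j), r$dw)
      gacc(sprintf("enc%d_conv%d_b", i, j), r$db)
      dh <- r$dx
    }
  }
  as.list(G)
}

#' Forward inference
#'
#' Runs the network on a batch of RGB images already scaled to `[0, 1]` and
#' returns the per-pixel wound probability.
#'
#' @param net A `wound_network`.
#' @param x 4-d array `(batch, rows, cols, 3)` with values in `[0, 1]`;
#'   extents must be multiples of 16.
#' @return 4-d array `(batch, rows, cols, 1)` of probabilities in (0,1).
#' @export
network_forward <- function(net, x) {
  stopifnot(inherits(net, "wound_network"))
  .forward_net(net, x, train = FALSE)$prob
}

#' Predict a binary wound mask for one image
#'
#' @param net A `wound_network`.
#' @param image RGB array `rows x cols x 3` with values on the 0..255 scale
#'   (scaled internally by 1/255).
#' @param threshold Probability threshold; a pixel is wound iff its
#'   probability is strictly greater than `threshold`. Default 0.5.
#' @return Integer matrix `rows x cols` of 0/1.
#' @export
predict_mask <- function(net, image, threshold = 0.5) {
  stopifnot(inherits(net, "wound_network"))
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L)) {
    stop("image must be a rows x cols x 3 RGB array")
  }
  d <- dim(image)
  x4 <- array(as.numeric(image) / 255, c(1L, d))
  p <- network_forward(net, x4)
  mask <- matrix(as.integer(p[1, , , 1] > threshold), d[1], d[2])
  mask
}

# ---- checkpoints -----------------------------------------------------------

#' Save network weights
#'
#' Single-file native checkpoint (RDS) holding variant, seed and all
#' parameter tensors.
#'
#' @param net A `wound_network`.
#' @param path Output file; conventionally `<variant>_seed<seed>.rds`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "wound_network"))
  saveRDS(net, path)
  invisible(path)
}

#' Load network weights
#'
#' @param path RDS file written by [save_network()].
#' @return The restored `wound_network`.
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "wound_network")) stop("file does not contain a wound_network")
  net
}

#' Replace the encoder weights with pre-trained VGG16 convolution weights
#'
#' Optional hook for transfer learning: loads an RDS file holding a named
#' list of encoder tensors (`enc<i>_conv<j>_w` / `enc<i>_conv<j>_b`, the
#' 13-layer VGG16 convolutional stack) and swaps them into the network,
#' leaving the decoder untouched.
#'
#' @param net A `wound_network` with the VGG16 encoder (not `"unet"`).
#' @param weights_path RDS file with the named weight list.
#' @return The network with replaced encoder weights.
#' @export
load_pretrained_encoder <- function(net, weights_path) {
  stopifnot(inherits(net, "wound_network"))
  if (net$variant == "unet") {
    stop("pre-trained VGG16 weights require a VGG16-encoder variant, not 'unet'")
  }
  if (!file.exists(weights_path)) stop("weights file not found: ", weights_path)
  w <- readRDS(weights_path)
  if (!is.list(w) || is.null(names(w))) stop("malformed weights file: expected a named list")
  enc_names <- grep("^enc[0-9]_conv[0-9]_(w|b)$", names(net$params), value = TRUE)
  for (nm in enc_names) {
    if (is.null(w[[nm]])) stop("weights file is missing layer '", nm, "'")
    if (!identical(dim(w[[nm]]), dim(net$params[[nm]])) &&
        !(is.null(dim(net$params[[nm]])) && length(w[[nm]]) == length(net$params[[nm]]))) {
      stop("shape mismatch for layer '", nm, "'")
    }
    net$params[[nm]] <- w[[nm]]
  }
  net
}

#' Export the encoder weights of a network
#'
#' Writes the encoder convolution tensors in the format accepted by
#' [load_pretrained_encoder()].
#'
#' @param net A `wound_network`.
#' @param path Output RDS file.
#' @export
save_encoder_weights <- function(net, path) {
  stopifnot(inherits(net, "wound_network"))
  enc_names <- grep("^enc[0-9]_conv[0-9]_(w|b)$", names(net$params), value = TRUE)
  saveRDS(net$params[enc_names], path)
  invisible(path)
}
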