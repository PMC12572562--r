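# Seeded generator of synthetic wound scenes. Each scene is an RGB photograph
# analogue: a skin-tone background (six-tone palette), zero to several
# irregular lesions (thresholded smooth noise inside a random ellipse, filled
# with granulation/slough/necrosis-like colours) and optional photographic
# artifacts (shadow, specular highlight, debris) that perturb the image but
# never the ground-truth mask.

#' Synthetic scene configuration
#'
#' @param rows,cols Image extents; multiples of 16 (default 480 x 640, the
#'   working resolution of the segmentation models).
#' @param wounds_per_image Integer range `c(min, max)` of lesions per image
#'   (default 0-3; zero-wound images are a deliberate part of the corpus).
#' @param area_fraction Range of the per-lesion area fraction (of the image)
#'   enclosing each lesion; upper bound must stay below 0.5.
#' @param skin_tones Number of background skin tones drawn from the built-in
#'   six-tone palette (1-6).
#' @param artifact_prob Probability that each artifact type (shadow, specular
#'   highlight, debris) is applied to a scene.
#' @param noise_sd Standard deviation of additive pixel noise (0-255 scale).
#' @param seed Integer seed; scenes are a deterministic function of
#'   `(seed, index)`.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(rows = 480L, cols = 640L,
                         wounds_per_image = c(0L, 3L),
                         area_fraction = c(0.005, 0.25),
                         skin_tones = 6L, artifact_prob = 0.3,
                         noise_sd = 3, seed = 1L) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows %% 16L != 0L || cols %% 16L != 0L || rows < 16L || cols < 16L) {
    stop("rows and cols must be multiples of 16, >= 16")
  }
  wounds_per_image <- as.integer(wounds_per_image)
  if (length(wounds_per_image) != 2L || wounds_per_image[1] > wounds_per_image[2] ||
      wounds_per_image[1] < 0L) {
    stop("wounds_per_image must be an ordered non-negative range c(min, max)")
  }
  if (length(area_fraction) != 2L || area_fraction[1] > area_fraction[2] ||
      area_fraction[1] <= 0 || area_fraction[2] >= 0.5) {
    stop("area_fraction must be an ordered range inside (0, 0.5)")
  }
  if (skin_tones < 1L || skin_tones > 6L) stop("skin_tones must be 1..6")
  if (artifact_prob < 0 || artifact_prob > 1) stop("artifact_prob must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(rows = rows, cols = cols,
                 wounds_per_image = wounds_per_image,
                 area_fraction = area_fraction,
                 skin_tones = as.integer(skin_tones),
                 artifact_prob = artifact_prob, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Fitzpatrick-like skin palette, light (I) to dark (VI), 0..255 RGB
.SKIN_PALETTE <- matrix(c(244, 222, 204,
                          231, 199, 175,
                          210, 168, 134,
                          180, 134, 90,
                          130, 92, 60,
                          84, 58, 40), ncol = 3, byrow = TRUE)

# smooth random field: coarse Gaussian grid, bilinear upsampling, unit sd
.smooth_noise <- function(rows, cols, grid = 8L) {
  Z <- matrix(rnorm((grid + 1L)^2), grid + 1L, grid + 1L)
  ty <- seq(0, grid, length.out = rows)
  tx <- seq(0, grid, length.out = cols)
  iy <- pmin(floor(ty), grid - 1L)
  ix <- pmin(floor(tx), grid - 1L)
  fy <- ty - iy
  fx <- tx - ix
  A <- Z[cbind(rep(iy + 1L, cols), rep(ix + 1L, each = rows))]
  B <- Z[cbind(rep(iy + 2L, cols), rep(ix + 1L, each = rows))]
  C <- Z[cbind(rep(iy + 1L, cols), rep(ix + 2L, each = rows))]
  D <- Z[cbind(rep(iy + 2L, cols), rep(ix + 2L, each = rows))]
  m <- matrix(A, rows, cols) * outer(1 - fy, 1 - fx) +
    matrix(B, rows, cols) * outer(fy, 1 - fx) +
    matrix(C, rows, cols) * outer(1 - fy, fx) +
    matrix(D, rows, cols) * outer(fy, fx)
  m / stats::sd(m)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic wound scene
#'
#' Deterministic in `(cfg$seed, index)`: the same pair always yields a
#' byte-identical image and mask.
#'
#' @param cfg A [synth_config()].
#' @param index Positive integer scene index.
#' @return List of class `wound_scene`: `image` (rows x cols x 3 integer
#'   array, 0..255), `mask` (rows x cols integer matrix, 0/1), `patient_id`,
#'   `image_id`.
#' @export
generate_scene <- function(cfg, index) {
  stopifnot(inherits(cfg, "synth_config"), index >= 1)
  scene_seed <- as.integer((as.double(cfg$seed) * 1000003 + index) %% 2147483647)
  .with_seed(scene_seed, {
    H <- cfg$rows
    W <- cfg$cols
    tone <- .SKIN_PALETTE[sample.int(cfg$skin_tones, 1L), ]
    shade <- .smooth_noise(H, W, grid = 6L)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- tone[ch] * (1 + 0.04 * shade)
    mask <- matrix(0L, H, W)
    n_wounds <- sample(seq(cfg$wounds_per_image[1], cfg$wounds_per_image[2]), 1L)
    Y <- matrix(seq_len(H), H, W)
    X <- matrix(seq_len(W), H, W, byrow = TRUE)
    if (n_wounds > 0) {
      for (k in seq_len(n_wounds)) {
        af <- runif(1, cfg$area_fraction[1], cfg$area_fraction[2])
        area <- af * H * W
        q <- runif(1, 0.4, 1)                 # minor/major axis ratio
        axa <- sqrt(area / (pi * q))
        axb <- q * axa
        th <- runif(1, 0, pi)
        cy <- runif(1, 0.15 * H, 0.85 * H)
        cx <- runif(1, 0.15 * W, 0.85 * W)
        u <- ((X - cx) * cos(th) + (Y - cy) * sin(th)) / axa
        v <- (-(X - cx) * sin(th) + (Y - cy) * cos(th)) / axb
        r2 <- u * u + v * v
        eta <- .smooth_noise(H, W, grid = 12L)
        # irregular support strictly inside the ellipse, so the per-lesion
        # area never exceeds the drawn fraction
        inside <- (r2 < 1) & (r2 + 0.5 * pmax(eta, 0) < 1)
        if (!any(inside)) next
        tissue <- .smooth_noise(H, W, grid = 10L)
        gran <- c(172, 46, 48)                # granulation red
        slough <- c(196, 172, 92)             # slough yellow
        necro <- c(58, 36, 30)                # necrotic dark
        wmix <- .sigmoid(2 * tissue)
        rim <- pmin(pmax((1 - r2) * 3, 0), 1) # darken toward the boundary
        for (ch in 1:3) {
          base <- gran[ch] * wmix + slough[ch] * (1 - wmix)
          base <- base * (0.55 + 0.45 * rim) + necro[ch] * (1 - rim) * 0.35
          layer <- img[, , ch]
          layer[inside] <- base[inside]
          img[, , ch] <- layer
        }
        mask[inside] <- 1L
      }
    }
    # artifacts: image-only perturbations
    if (runif(1) < cfg$artifact_prob) {       # shadow: multiplicative ramp
      dir <- runif(1, 0, 2 * pi)
      ramp <- ((X / W - 0.5) * cos(dir) + (Y / H - 0.5) * sin(dir))
      fac <- 1 - 0.35 * pmin(pmax(ramp + 0.5, 0), 1)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * fac
    }
    if (runif(1) < cfg$artifact_prob) {       # specular highlight
      cy <- runif(1, 1, H); cx <- runif(1, 1, W)
      rad <- runif(1, 0.02, 0.06) * min(H, W)
      g <- exp(-((Y - cy)^2 + (X - cx)^2) / (2 * rad^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + 90 * g
    }
    if (runif(1) < cfg$artifact_prob) {       # debris: small dark specks
      ns <- sample(8:25, 1)
      for (s in seq_len(ns)) {
        cy <- sample.int(H, 1); cx <- sample.int(W, 1)
        r <- sample(1:3, 1)
        yy <- pmax(1, cy - r):pmin(H, cy + r)
        xx <- pmax(1, cx - r):pmin(W, cx + r)
        for (ch in 1:3) img[yy, xx, ch] <- img[yy, xx, ch] * 0.35
      }
    }
    if (cfg$noise_sd > 0) img <- img + rnorm(length(img), sd = cfg$noise_sd)
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim(img))
    structure(list(image = img, mask = mask,
                   patient_id = sprintf("P%05d", index),
                   image_id = sprintf("img%05d", index)),
              class = "wound_scene")
  })
}

#' Generate a dataset of synthetic scenes
#'
#' @param n Number of scenes.
#' @param cfg A [synth_config()].
#' @param images_per_patient Scenes are assigned pseudo-patient ids in blocks
#'   of this size (default 1, one image per patient).
#' @return List of `wound_scene` objects.
#' @export
generate_dataset <- function(n, cfg, images_per_patient = 1L) {
  stopifnot(n >= 1, images_per_patient >= 1)
  scenes <- lapply(seq_len(n), function(i) {
    sc <- generate_scene(cfg, i)
    sc$patient_id <- sprintf("P%05d", ceiling(i / images_per_patient))
    sc
  })
  scenes
}

#' Write scenes to disk as PNG images plus a CSV manifest
#'
#' Images are RGB PNG; masks are single-channel PNG with values {0, 255}.
#'
#' @param scenes List of `wound_scene` objects.
#' @param directory Output directory (created if missing).
#' @return Path of the manifest CSV (invisibly).
#' @export
write_dataset <- function(scenes, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  rows <- lapply(scenes, function(sc) {
    img_file <- paste0(sc$image_id, ".png")
    mask_file <- paste0(sc$image_id, "_mask.png")
    png::writePNG(sc$image / 255, file.path(directory, img_file))
    png::writePNG(sc$mask + 0, file.path(directory, mask_file))
    data.frame(filename = img_file, mask_filename = mask_file,
               patient_id = sc$patient_id, image_id = sc$image_id,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(directory, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory Dataset directory containing `manifest.csv`.
#' @return List of `wound_scene` objects; masks are reproduced bit-exactly.
#' @export
read_dataset <- function(directory) {
  path <- file.path(directory, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", directory)
  manifest <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(directory, manifest$filename[i]))
    if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
    mask <- png::readPNG(file.path(directory, manifest$mask_filename[i]))
    if (length(dim(mask)) == 3L) mask <- mask[, , 1]
    structure(list(image = array(as.integer(round(img * 255)), dim(img)),
                   mask = matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask)),
                   patient_id = manifest$patient_id[i],
                   image_id = manifest$image_id[i]),
              class = "wound_scene")
  })
}
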