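# Image preprocessing chain: min-max normalization -> CLAHE -> Gaussian
# denoising -> Otsu breast segmentation with morphological refinement,
# plus seeded geometric augmentation. Images are numeric matrices.

#' CLAHE parameters
#'
#' @param tiles Number of tiles per axis (N); 1 means global equalization.
#' @param clip Clip limit C as a multiple of the average histogram bin count;
#'   bins above `clip * n_tile / 256` are clipped and the excess redistributed
#'   uniformly. `Inf` disables clipping (plain adaptive equalization).
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(tiles = 8L, clip = 2.0) {
  check_number(tiles, "tiles", lower = 1, integer = TRUE)
  if (!(is.numeric(clip) && length(clip) == 1L && clip > 0))
    stop_bad_arg("`clip` must be a single positive number (Inf allowed)")
  structure(list(tiles = as.integer(tiles), clip = clip),
            class = "clahe_params")
}

#' Gaussian filter parameters
#'
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @param radius Kernel half-width k; the discrete kernel is (2k+1) x (2k+1)
#'   and renormalized to sum exactly 1, so constant images are fixed points.
#' @return An object of class `gauss_params`.
#' @export
gauss_params <- function(sigma = 1.0, radius = 3L) {
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_number(radius, "radius", lower = 1, integer = TRUE)
  structure(list(sigma = sigma, radius = as.integer(radius)),
            class = "gauss_params")
}

#' Min-max normalization to [0, 1]
#'
#' Affine order-preserving rescaling `(I - min) / (max - min)`.
#'
#' @param img Numeric matrix with at least two distinct values.
#' @return Matrix with min 0 and max 1.
#' @export
minmax_normalize <- function(img) {
  check_image(img)
  rng <- range(img)
  if (rng[1] == rng[2])
    stop_bad_arg("cannot normalize a constant image (max == min)")
  (img - rng[1]) / (rng[2] - rng[1])
}

# 256-bin quantization of a [0,1] image; returns bin indices 0..255.
quantize256 <- function(img) {
  b <- floor(img * 256)
  b[b > 255] <- 255L
  b
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization on a 256-bin quantization with
#' clip-and-redistribute, bilinearly interpolating the per-tile mappings
#' between tile centers. With `tiles = 1` and `clip = Inf` this reduces
#' exactly to global histogram equalization (output = empirical cdf of the
#' pixel's bin).
#'
#' @param img Normalized image ([0, 1]).
#' @param p A [clahe_params()].
#' @return Enhanced image in [0, 1].
#' @export
apply_clahe <- function(img, p = clahe_params()) {
  check_normalized(img)
  if (!inherits(p, "clahe_params")) stop_bad_arg("`p` must be clahe_params")
  nr <- nrow(img); nc <- ncol(img); nt <- p$tiles
  if (nt > min(nr, nc))
    stop_bad_arg("`tiles` (%d) exceeds the smallest image side", nt)
  bins <- quantize256(img)

  # Tile index ranges (contiguous, near-equal).
  row_edges <- round(seq(0, nr, length.out = nt + 1))
  col_edges <- round(seq(0, nc, length.out = nt + 1))

  # Per-tile clipped cdf mappings: 256 x (nt*nt), tile (i,j) in column
  # (j-1)*nt + i.
  maps <- matrix(0, 256L, nt * nt)
  centers_r <- numeric(nt); centers_c <- numeric(nt)
  for (i in seq_len(nt)) {
    ri <- (row_edges[i] + 1L):row_edges[i + 1L]
    centers_r[i] <- (row_edges[i] + row_edges[i + 1L] + 1) / 2
    for (j in seq_len(nt)) {
      ci <- (col_edges[j] + 1L):col_edges[j + 1L]
      if (i == 1L) centers_c[j] <- (col_edges[j] + col_edges[j + 1L] + 1) / 2
      tb <- bins[ri, ci]
      h <- tabulate(tb + 1L, nbins = 256L)
      n_tile <- length(tb)
      if (is.finite(p$clip)) {
        lim <- max(1, p$clip * n_tile / 256)
        excess <- sum(pmax(h - lim, 0))
        h <- pmin(h, lim) + excess / 256
      }
      maps[, (j - 1L) * nt + i] <- cumsum(h) / n_tile
    }
  }

  if (nt == 1L) {
    out <- matrix(maps[bins + 1L, 1L], nr, nc)
    return(out)
  }

  # Bilinear interpolation between the four surrounding tile-center mappings.
  interp_axis <- function(pos, centers) {
    i0 <- findInterval(pos, centers)
    i0c <- pmin(pmax(i0, 1L), length(centers) - 1L)
    w <- (pos - centers[i0c]) / (centers[i0c + 1L] - centers[i0c])
    w[i0 < 1L] <- 0; w[i0 >= length(centers)] <- 1
    list(lo = i0c, w = pmin(pmax(w, 0), 1))
  }
  ra <- interp_axis(seq_len(nr), centers_r)
  ca <- interp_axis(seq_len(nc), centers_c)

  ri_lo <- matrix(ra$lo, nr, nc); rw <- matrix(ra$w, nr, nc)
  ci_lo <- matrix(ca$lo, nr, nc, byrow = TRUE)
  cw <- matrix(ca$w, nr, nc, byrow = TRUE)
  b1 <- bins + 1L
  tile_col <- function(ti, tj) (tj - 1L) * nt + ti
  m00 <- maps[cbind(as.vector(b1), as.vector(tile_col(ri_lo, ci_lo)))]
  m10 <- maps[cbind(as.vector(b1), as.vector(tile_col(ri_lo + 1L, ci_lo)))]
  m01 <- maps[cbind(as.vector(b1), as.vector(tile_col(ri_lo, ci_lo + 1L)))]
  m11 <- maps[cbind(as.vector(b1), as.vector(tile_col(ri_lo + 1L, ci_lo + 1L)))]
  out <- (1 - rw) * (1 - cw) * m00 + rw * (1 - cw) * m10 +
    (1 - rw) * cw * m01 + rw * cw * m11
  matrix(out, nr, nc)
}

# Discrete Gaussian kernel, renormalized to sum exactly 1.
gaussian_kernel <- function(sigma, radius) {
  off <- -radius:radius
  g <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian smoothing filter
#'
#' Convolution with a renormalized discrete Gaussian kernel; image edges are
#' replicate-padded so constant images map to themselves exactly.
#'
#' @param img Numeric matrix (finite values).
#' @param p A [gauss_params()].
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_filter <- function(img, p = gauss_params()) {
  check_image(img)
  if (!inherits(p, "gauss_params")) stop_bad_arg("`p` must be gauss_params")
  k <- gaussian_kernel(p$sigma, p$radius)
  r <- p$radius
  nr <- nrow(img); nc <- ncol(img)
  # Replicate padding.
  pad <- img[c(rep(1L, r), seq_len(nr), rep(nr, r)),
             c(rep(1L, r), seq_len(nc), rep(nc, r))]
  out <- matrix(0, nr, nc)
  for (i in -r:r) for (j in -r:r)
    out <- out + k[i + r + 1L, j + r + 1L] *
      pad[(1L + r - i):(nr + r - i), (1L + r - j):(nc + r - j)]
  out
}

#' Otsu threshold segmentation
#'
#' Quantizes the image to 256 levels and picks the threshold level maximizing
#' the between-class variance `w0 w1 (mu0 - mu1)^2` over all 256 candidates;
#' ties are broken by the lowest level. The mask is `level > t*`.
#'
#' @param img Numeric matrix with at least two distinct values.
#' @return An object of class `breast_mask`: list with `mask` (logical
#'   matrix), `threshold` (on the original intensity scale), `level`
#'   (quantized threshold 0..255), and `between_var` (the attained maximum).
#' @export
otsu_segment <- function(img) {
  check_image(img)
  rng <- range(img)
  if (rng[1] == rng[2])
    stop_bad_arg("cannot threshold a constant image")
  q <- quantize256((img - rng[1]) / (rng[2] - rng[1]))
  h <- tabulate(q + 1L, nbins = 256L)
  n <- length(q)
  w <- h / n
  lv <- 0:255
  cw0 <- cumsum(w)                        # P(level <= t)
  cmu <- cumsum(w * lv)
  mu_tot <- cmu[256L]
  # Candidates t = 0..255; class 0 = levels <= t, class 1 = levels > t.
  w0 <- cw0
  w1 <- 1 - w0
  mu0 <- ifelse(w0 > 0, cmu / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu_tot - cmu) / w1, 0)
  sb <- w0 * w1 * (mu0 - mu1)^2
  t_star <- which.max(sb) - 1L            # first maximum = lowest level
  thr <- rng[1] + (rng[2] - rng[1]) * t_star / 255
  structure(list(mask = q > t_star,
                 threshold = thr,
                 level = t_star,
                 between_var = sb[t_star + 1L]),
            class = "breast_mask")
}

#' Morphological refinement of a binary mask
#'
#' Keeps the largest connected component, then applies dilation and closing
#' with a disk structuring element, removing isolated speckles and filling
#' small interior holes. The result always contains the retained component.
#'
#' @param m A `breast_mask` or a logical matrix.
#' @param radius Disk radius in pixels for the structuring element.
#' @return A `breast_mask` with the refined mask (threshold carried over when
#'   available).
#' @export
refine_mask <- function(m, radius = 5L) {
  mask <- if (inherits(m, "breast_mask")) m$mask else m
  if (!is.matrix(mask)) stop_bad_arg("`m` must be a mask matrix")
  mask <- mask > 0
  if (!any(mask)) stop_bad_arg("cannot refine an empty mask")
  check_number(radius, "radius", lower = 1, integer = TRUE)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- round(EBImage::imageData(lab))
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- (lab == keep) * 1
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  d <- EBImage::dilate(comp, brush)
  cl <- EBImage::closing(d, brush)
  out <- EBImage::imageData(cl) > 0.5
  structure(list(mask = out,
                 threshold = if (inherits(m, "breast_mask")) m$threshold
                             else NA_real_,
                 level = if (inherits(m, "breast_mask")) m$level
                         else NA_integer_),
            class = "breast_mask")
}

#' Augmentation parameters
#'
#' Defaults mirror the classical mammogram augmentation recipe: rotations
#' within +/-15 degrees, horizontal/vertical flips with probability 0.5,
#' zoom-in of 10-15% with center crop back, and a small elastic deformation.
#'
#' @param max_angle Maximum absolute rotation in degrees.
#' @param zoom_range Length-2 zoom factor range (>= 1; 1 disables).
#' @param flip_prob Probability of each of horizontal and vertical flip.
#' @param elastic_alpha Elastic displacement magnitude in pixels (0 disables).
#' @param elastic_sigma Smoothing SD of the elastic displacement field.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(max_angle = 15, zoom_range = c(1.10, 1.15),
                           flip_prob = 0.5, elastic_alpha = 8,
                           elastic_sigma = 4) {
  check_number(max_angle, "max_angle", lower = 0)
  check_number(flip_prob, "flip_prob", lower = 0, upper = 1)
  check_number(elastic_alpha, "elastic_alpha", lower = 0)
  check_number(elastic_sigma, "elastic_sigma", lower = 0,
               strict_lower = TRUE)
  if (length(zoom_range) != 2L || any(zoom_range < 1) ||
      zoom_range[1] > zoom_range[2])
    stop_bad_arg("`zoom_range` must be an increasing pair >= 1")
  structure(list(max_angle = max_angle, zoom_range = as.numeric(zoom_range),
                 flip_prob = flip_prob, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma),
            class = "augment_params")
}

# Bilinear sampling of img at (possibly fractional) coordinates, clamped to
# the image border. xs/ys are matrices of source row/col coordinates.
bilinear_sample <- function(img, xs, ys) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- pmin(pmax(xs, 1), nr); ys <- pmin(pmax(ys, 1), nc)
  x0 <- pmin(floor(xs), nr - 1L); y0 <- pmin(floor(ys), nc - 1L)
  fx <- xs - x0; fy <- ys - y0
  v00 <- img[cbind(as.vector(x0), as.vector(y0))]
  v10 <- img[cbind(as.vector(x0 + 1), as.vector(y0))]
  v01 <- img[cbind(as.vector(x0), as.vector(y0 + 1))]
  v11 <- img[cbind(as.vector(x0 + 1), as.vector(y0 + 1))]
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  matrix(out, nr, nc)
}

#' Seeded random geometric augmentation
#'
#' Draws a rotation angle uniform in `[-max_angle, max_angle]`, a zoom factor
#' uniform in `zoom_range` (zoom-in with center crop back to the original
#' size), horizontal/vertical flips each with `flip_prob`, and an elastic
#' deformation (uniform displacement field smoothed by a Gaussian of SD
#' `elastic_sigma`, scaled to `elastic_alpha` pixels), then resamples the
#' image once through a single bilinear inverse mapping. Deterministic under
#' `seed`; a draw in which every transform is the identity returns the input
#' bit-identically.
#'
#' @param img Normalized image ([0, 1]).
#' @param seed Integer seed for the random draws.
#' @param p An [augment_params()].
#' @return Augmented image of the same shape, with the realized draws in
#'   `attr(, "draws")`.
#' @export
augment <- function(img, seed, p = augment_params()) {
  check_normalized(img)
  if (!inherits(p, "augment_params"))
    stop_bad_arg("`p` must be augment_params")
  with_seed(seed, {
    angle <- if (p$max_angle > 0)
      stats::runif(1, -p$max_angle, p$max_angle) else 0
    flip_h <- stats::runif(1) < p$flip_prob
    flip_v <- stats::runif(1) < p$flip_prob
    zoom <- if (p$zoom_range[2] > 1)
      stats::runif(1, p$zoom_range[1], p$zoom_range[2]) else 1
    draws <- list(angle = angle, flip_h = flip_h, flip_v = flip_v,
                  zoom = zoom)
    identity_draw <- angle == 0 && !flip_h && !flip_v && zoom == 1 &&
      p$elastic_alpha == 0
    if (identity_draw) {
      out <- img
    } else {
      nr <- nrow(img); nc <- ncol(img)
      cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
      gx <- matrix(seq_len(nr), nr, nc) - cr        # rows
      gy <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
      if (flip_h) gy <- -gy
      if (flip_v) gx <- -gx
      th <- -angle * pi / 180                        # inverse rotation
      sx <- (cos(th) * gx - sin(th) * gy) / zoom
      sy <- (sin(th) * gx + cos(th) * gy) / zoom
      if (p$elastic_alpha > 0) {
        sm <- gauss_params(p$elastic_sigma,
                           radius = max(1L, ceiling(2 * p$elastic_sigma)))
        dx <- gaussian_filter(matrix(stats::runif(nr * nc, -1, 1), nr, nc), sm)
        dy <- gaussian_filter(matrix(stats::runif(nr * nc, -1, 1), nr, nc), sm)
        nrm <- max(max(abs(dx)), max(abs(dy)), .Machine$double.eps)
        sx <- sx + dx / nrm * p$elastic_alpha
        sy <- sy + dy / nrm * p$elastic_alpha
      }
      out <- bilinear_sample(img, sx + cr, sy + cc)
      out <- pmin(pmax(out, 0), 1)
    }
    attr(out, "draws") <- draws
    out
  })
}

#' Full preprocessing chain for one image
#'
#' Applies, in order: min-max normalization, CLAHE, Gaussian filtering, and
#' Otsu segmentation with morphological refinement; the final image is the
#' filtered image with the background zeroed by the refined breast mask.
#' Every intermediate stays in [0, 1].
#'
#' @param img Raw grayscale matrix.
#' @param clahe A [clahe_params()].
#' @param gauss A [gauss_params()].
#' @param segment Logical; apply Otsu segmentation and masking.
#' @param mask_radius Disk radius for [refine_mask()].
#' @return List with `norm`, `clahe`, `filtered`, `mask` (or NULL) and
#'   `final`.
#' @export
preprocess_image <- function(img, clahe = clahe_params(),
                             gauss = gauss_params(), segment = TRUE,
                             mask_radius = 5L) {
  x1 <- minmax_normalize(img)
  x2 <- apply_clahe(x1, clahe)
  x3 <- gaussian_filter(x2, gauss)
  x3 <- pmin(pmax(x3, 0), 1)
  if (segment) {
    m <- refine_mask(otsu_segment(x3), radius = mask_radius)
    final <- x3 * m$mask
  } else {
    m <- NULL
    final <- x3
  }
  list(norm = x1, clahe = x2, filtered = x3, mask = m, final = final)
}
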