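# Brute-force oracles, written independently of the package internals
# (plain R loops), used to pin expected values.

# bilinear interpolation at a single 0-based (y, x); zero outside
oracle_bilinear_at <- function(img, y, x) {
  h <- nrow(img)
  w <- ncol(img)
  y0 <- floor(y)
  x0 <- floor(x)
  v <- 0
  for (dy in 0:1) {
    for (dx in 0:1) {
      yy <- y0 + dy
      xx <- x0 + dx
      wt <- (if (dy == 1) y - y0 else 1 - (y - y0)) *
        (if (dx == 1) x - x0 else 1 - (x - x0))
      if (yy >= 0 && yy < h && xx >= 0 && xx < w && wt > 0) {
        v <- v + wt * img[yy + 1, xx + 1]
      }
    }
  }
  v
}

# line-integral projection by direct sampling along each ray
oracle_radon <- function(img, angles_deg, substeps = 2) {
  h <- nrow(img)
  w <- ncol(img)
  ndet <- ceiling(sqrt(h^2 + w^2))
  if (ndet %% 2 == 0) ndet <- ndet + 1
  cc <- (ndet - 1) / 2
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  out <- matrix(0, ndet, length(angles_deg))
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    for (i in seq_len(ndet)) {
      t <- i - 1 - cc
      acc <- 0
      svals <- seq(-cc, cc, by = 1 / substeps)
      for (s in svals) {
        acc <- acc + oracle_bilinear_at(img, cy + t * sin(th) + s * cos(th),
                                        cx + t * cos(th) - s * sin(th))
      }
      out[i, a] <- acc / substeps
    }
  }
  out
}

oracle_dice <- function(P, G, eps = 1e-5) {
  i <- 0
  p <- 0
  g <- 0
  for (k in seq_along(P)) {
    i <- i + (P[k] == 1 && G[k] == 1)
    p <- p + (P[k] == 1)
    g <- g + (G[k] == 1)
  }
  (2 * i + eps) / (p + g + eps)
}

oracle_iou <- function(P, G) {
  i <- 0
  u <- 0
  for (k in seq_along(P)) {
    i <- i + (P[k] == 1 && G[k] == 1)
    u <- u + (P[k] == 1 || G[k] == 1)
  }
  if (u == 0) 1 else i / u
}

oracle_centroid <- function(M) {
  sy <- 0
  sx <- 0
  n <- 0
  for (y in seq_len(nrow(M))) {
    for (x in seq_len(ncol(M))) {
      if (M[y, x] == 1) {
        sy <- sy + (y - 1)
        sx <- sx + (x - 1)
        n <- n + 1
      }
    }
  }
  list(y_bar = sy / n, x_bar = sx / n, n_pixels = n)
}

# pixel-center-in-disk rasterization count
oracle_disk_count <- function(cy, cx, r, h, w) {
  n <- 0
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      if ((y - 1 - cy)^2 + (x - 1 - cx)^2 <= r^2) n <- n + 1
    }
  }
  n
}

# mean squared 5-point Laplacian (high-frequency energy)
oracle_laplacian_energy <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  lap <- img[2:(h - 1), 2:(w - 1)] * -4 +
    img[1:(h - 2), 2:(w - 1)] + img[3:h, 2:(w - 1)] +
    img[2:(h - 1), 1:(w - 2)] + img[2:(h - 1), 3:w]
  mean(lap^2)
}

# marching-squares perimeter at the 0.5 level of a binary mask
oracle_marching_perimeter <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  len <- 0
  half_diag <- sqrt(0.5)
  for (y in seq_len(nrow(pad) - 1)) {
    for (x in seq_len(ncol(pad) - 1)) {
      code <- pad[y, x] + 2 * pad[y, x + 1] + 4 * pad[y + 1, x + 1] +
        8 * pad[y + 1, x]
      n1 <- sum(c(pad[y, x], pad[y, x + 1], pad[y + 1, x + 1], pad[y + 1, x]))
      if (n1 == 1 || n1 == 3) {
        len <- len + half_diag
      } else if (n1 == 2) {
        len <- len + if (code %in% c(5, 10)) 2 * half_diag else 1
      }
    }
  }
  len
}

# small deterministic test phantom with one centered-ish lesion
make_lesion_sample <- function(size = 128, seed = 5, modality = "mammography",
                               center_off = c(0, 0), semi = c(8, 6),
                               irregularity = 0) {
  smp <- generate_phantom(size, modality, seed)
  ctr <- c(smp$support$cy + center_off[1], smp$support$cx + center_off[2])
  add_lesion(smp, lesion_spec(ctr, semi, rotation_deg = 20, contrast = 0.4,
                              boundary_irregularity = irregularity))
}
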