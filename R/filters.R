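#' Image filter bank for radiomic extraction
#'
#' Computes the 11 image types the intensity feature classes are extracted
#' from: the original image, the 8 sub-bands of an undecimated (stationary)
#' 3-D Haar wavelet transform (LLL..HHH), and Laplacian-of-Gaussian responses
#' at the configured sigmas. All filters are separable and use nearest-edge
#' padding.
#'
#' @param vol a [volume()].
#' @param log_sigmas_mm LoG scales in mm (default `c(2, 3)`).
#' @return Named list of 3-D arrays, names matching the feature-name filter
#'   tags (`original`, `wavelet-LLL`, ..., `log-sigma-2-mm`, ...).
#' @export
filter_bank <- function(vol, log_sigmas_mm = c(2, 3)) {
  arr <- vol$array
  d <- dim(arr)
  out <- list(original = arr)

  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  # pad kernels to odd length for conv_axis_cpp (center on first tap)
  lo3 <- c(0, lo)
  hi3 <- c(0, hi)
  bands_x <- list(L = array(conv_axis_cpp(as.numeric(arr), d, lo3, 0L), d),
                  H = array(conv_axis_cpp(as.numeric(arr), d, hi3, 0L), d))
  for (nx in names(bands_x)) {
    bx <- bands_x[[nx]]
    bands_y <- list(L = array(conv_axis_cpp(as.numeric(bx), d, lo3, 1L), d),
                    H = array(conv_axis_cpp(as.numeric(bx), d, hi3, 1L), d))
    for (ny in names(bands_y)) {
      by <- bands_y[[ny]]
      for (nz in c("L", "H")) {
        k <- if (nz == "L") lo3 else hi3
        out[[paste0("wavelet-", nx, ny, nz)]] <-
          array(conv_axis_cpp(as.numeric(by), d, k, 2L), d)
      }
    }
  }

  for (s in log_sigmas_mm) {
    out[[sprintf("log-sigma-%g-mm", s)]] <- log_filter(arr, vol$spacing, s)
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

gaussian_smooth <- function(arr, spacing, sigma_mm) {
  d <- dim(arr)
  out <- as.numeric(arr)
  for (ax in 0:2) {
    k <- gaussian_kernel(sigma_mm / spacing[ax + 1])
    out <- conv_axis_cpp(out, d, k, ax)
  }
  array(out, d)
}

# Laplacian of Gaussian: Gaussian smoothing followed by the 7-point discrete
# Laplacian on the physical grid, scale-normalized by sigma^2.
log_filter <- function(arr, spacing, sigma_mm) {
  sm <- gaussian_smooth(arr, spacing, sigma_mm)
  d <- dim(sm)
  lap <- array(0, d)
  for (ax in 1:3) {
    k <- c(1, -2, 1) / spacing[ax]^2
    lap <- lap + array(conv_axis_cpp(as.numeric(sm), d, k, ax - 1L), d)
  }
  sigma_mm^2 * lap
}
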