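# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Salt-and-pepper noise
#'
#' Each pixel is independently replaced, with probability `p` (the
#' corruption density), by the minimum (0) or maximum intensity with equal
#' chance. Density 0 returns the input unchanged; density 1 leaves only
#' extreme intensities.
#'
#' @param image numeric matrix.
#' @param p corruption density in \[0, 1\].
#' @param seed integer seed; the same seed reproduces the same corruption.
#' @param max_val intensity used for "salt" (default 255, the 8-bit
#'   convention).
#' @return corrupted image matrix.
#' @export
add_salt_pepper <- function(image, p, seed = 1L, max_val = 255) {
  image <- as_gray_matrix(image)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("density p must be a single value in [0, 1]")
  }
  if (p == 0) return(image)
  with_seed(seed, {
    hit <- runif(length(image)) < p
    salt <- runif(length(image)) < 0.5
    out <- image
    out[hit & salt] <- max_val
    out[hit & !salt] <- 0
    out
  })
}

#' Additive white Gaussian noise at a given SNR
#'
#' Adds zero-mean Gaussian noise whose variance is the image's mean square
#' intensity (signal power) divided by `10^(snr_db/10)`, then clips to the
#' valid intensity range. Lower SNR means stronger noise; at very high SNR
#' the image is essentially unchanged.
#'
#' @param image numeric matrix with nonzero power.
#' @param snr_db signal-to-noise ratio in decibels.
#' @param seed integer seed.
#' @param max_val clipping ceiling (default 255).
#' @return noisy image matrix, clipped to \[0, max_val\].
#' @export
add_awgn <- function(image, snr_db, seed = 1L, max_val = 255) {
  image <- as_gray_matrix(image)
  if (!is.finite(snr_db)) stop("snr_db must be finite")
  power <- mean(image^2)
  if (power == 0) stop("image has zero power; SNR is undefined")
  sigma <- sqrt(power / 10^(snr_db / 10))
  noisy <- with_seed(seed, image + rnorm(length(image), 0, sigma))
  noisy[noisy < 0] <- 0
  noisy[noisy > max_val] <- max_val
  matrix(noisy, nrow(image), ncol(image))
}

#' Noise specification grid point
#'
#' @param kind `"salt_pepper"` or `"awgn"`.
#' @param level corruption density for salt_pepper, SNR in dB for awgn.
#' @param seed integer seed for the corruption draw.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("salt_pepper", "awgn"), level, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "salt_pepper" && (level < 0 || level > 1)) {
    stop("salt_pepper level is a density in [0, 1]")
  }
  if (kind == "awgn" && !is.finite(level)) stop("awgn level must be finite dB")
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

apply_noise <- function(image, spec) {
  switch(spec$kind,
    salt_pepper = add_salt_pepper(image, spec$level, spec$seed),
    awgn = add_awgn(image, spec$level, spec$seed))
}

#' Descriptor accuracy across a noise grid
#'
#' For each noise specification, corrupts every image of the dataset
#' (per-image seeds derived from the grid point's seed), extracts features with each
#' requested descriptor, runs leave-one-sample-out KNN, and records the
#' accuracy. The zero-noise grid point reproduces the clean-data accuracy
#' exactly.
#'
#' @param dataset labeled dataset ([make_dataset()] / [load_dataset()]).
#' @param descriptors character vector of descriptor names
#'   (see [extract_feature()]).
#' @param grid list of [noise_spec()] objects.
#' @param k,metric KNN settings for [loso_knn_evaluate()].
#' @return data.frame with columns noise_kind, level, seed, descriptor,
#'   accuracy — one row per grid point x descriptor.
#' @export
noise_sweep <- function(dataset, descriptors = c("lddscp", "lbp"),
                        grid, k = 1L, metric = "euclidean") {
  if (length(grid) == 0L) stop("noise grid is empty")
  if (inherits(grid, "noise_spec")) grid <- list(grid)
  rows <- list()
  for (spec in grid) {
    noisy <- dataset
    noisy$images <- lapply(seq_along(dataset$images), function(i) {
      apply_noise(dataset$images[[i]], noise_spec(
        spec$kind, spec$level, seed = spec$seed + i))
    })
    for (desc in descriptors) {
      feats <- dataset_features(noisy, desc)
      ev <- loso_knn_evaluate(feats, k = k, metric = metric)
      rows[[length(rows) + 1L]] <- data.frame(
        noise_kind = spec$kind, level = spec$level, seed = spec$seed,
        descriptor = desc, accuracy = ev$accuracy,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plot a noise sweep as accuracy-vs-level curves
#'
#' One line per descriptor; accuracies from repeated seeds at the same level
#' are averaged.
#'
#' @param sweep data.frame from [noise_sweep()].
#' @return a ggplot object.
#' @export
plot_noise_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  agg <- aggregate(accuracy ~ noise_kind + level + descriptor, sweep, mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$level, y = .data$accuracy,
                                    colour = .data$descriptor)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~noise_kind, scales = "free_x") +
    ggplot2::labs(x = "noise level", y = "LOSO accuracy") +
    ggplot2::theme_minimal()
}
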