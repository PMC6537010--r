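#' Synthetic oriented texture
#'
#' Generates a grayscale texture whose intensity gradient points along one
#' of the eight compass directions: a linear ramp (one step-edge cycle, the
#' default) or a sawtooth grating (`cycles > 1`), plus optional Gaussian
#' intensity jitter. With no jitter and `cycles = 1`, every interior pixel's
#' strongest group response comes from the mask of the requested direction —
#' exactly the structure the dominant-direction encoder is built to detect.
#'
#' @param direction_deg one of 0, 45, ..., 315 (0 = East, counter-clockwise;
#'   intensity increases toward this direction).
#' @param size image side length in pixels (>= 16).
#' @param contrast peak-to-peak intensity range of the ramp (> 0).
#' @param noise_sigma standard deviation of additive Gaussian jitter
#'   (0 = none).
#' @param seed integer seed for the jitter.
#' @param cycles number of ramp cycles across the image (1 = single ramp;
#'   more cycles give a sawtooth grating with stronger local step edges).
#' @param phase phase offset of the grating in cycles (0..1); only
#'   meaningful with `cycles > 1`.
#' @return numeric `size x size` matrix with intensities centered on 128 and
#'   clipped to \[0, 255\].
#' @export
make_oriented_texture <- function(direction_deg, size = 128L, contrast = 140,
                                  noise_sigma = 0, seed = 1L, cycles = 1L,
                                  phase = 0) {
  if (!direction_deg %in% seq(0, 315, by = 45)) {
    stop("direction_deg must be one of 0, 45, ..., 315")
  }
  size <- as.integer(size)
  if (size < 16L) stop("size must be >= 16")
  if (contrast <= 0) stop("contrast must be positive")
  theta <- direction_deg * pi / 180
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  # projection onto the gradient direction; row index grows downward, so the
  # screen-up component enters with a minus sign
  t <- x * cos(theta) - y * sin(theta)
  t <- (t - min(t)) / (max(t) - min(t))                      # 0..1 across image
  if (cycles > 1L || phase != 0) t <- (t * cycles + phase) %% 1
  img <- 128 - contrast / 2 + contrast * t
  if (noise_sigma > 0) {
    img <- with_seed(seed, img + rnorm(length(img), 0, noise_sigma))
  }
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

#' Labeled synthetic oriented-texture dataset
#'
#' Classes are sawtooth gratings at distinct (orientation, frequency)
#' combinations: orientations advance by `separation` degrees modulo 180 and
#' the grating frequency doubles with every full 180-degree lap, so up to 8
#' classes are available at the default 45-degree separation. Orientations
#' are taken modulo 180 because the stacked descriptor is blind to gradient
#' polarity by construction — the two group code maps swap roles under a
#' 180-degree gradient flip, leaving their per-block sums unchanged — so
#' opposite-polarity "classes" would be inherently confusable.
#'
#' Within a class, samples differ by Gaussian intensity jitter, a random
#' grating phase (which shifts texture relative to the block grid) and a
#' random contrast gain; the jitter default is deliberately non-trivial
#' relative to the gratings' local step size so that per-pixel codes are
#' noisy while the block histograms remain class-discriminative — the regime
#' in which descriptor robustness can actually be compared. The manifest
#' records every generator parameter, so a dataset can be regenerated
#' bit-identically.
#'
#' @param n_classes number of texture classes (2..8).
#' @param n_per_class samples per class.
#' @param size image side length.
#' @param separation orientation gap between consecutive classes, a multiple
#'   of 45 degrees (default 45).
#' @param noise_sigma per-sample Gaussian jitter level (default 8).
#' @param contrast base peak-to-peak intensity range per grating cycle
#'   (default 60).
#' @param base_cycles grating frequency of the first orientation lap
#'   (default 4 cycles across the image).
#' @param seed master seed; per-image seeds are derived from it.
#' @return list with `images` (list of matrices), `labels` (character,
#'   `o<orientation>c<cycles>`), `ids`, `manifest` (data.frame of per-image
#'   generator parameters) and `params` (the call parameters, sufficient for
#'   [replay_dataset()]).
#' @examples
#' ds <- make_dataset(n_classes = 3, n_per_class = 2, size = 32)
#' table(ds$labels)
#' @export
make_dataset <- function(n_classes = 6L, n_per_class = 10L, size = 128L,
                         separation = 45, noise_sigma = 8, contrast = 60,
                         base_cycles = 4L, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 8L) stop("n_classes must be in 2..8")
  if (!separation %in% seq(45, 315, by = 45)) {
    stop("separation must be a positive multiple of 45 degrees")
  }
  ang <- (seq_len(n_classes) - 1L) * separation
  dirs <- ang %% 180
  cycles <- base_cycles * 2^(ang %/% 180)
  if (anyDuplicated(paste(dirs, cycles))) {
    stop("orientation/frequency classes collide; reduce n_classes or change separation")
  }
  images <- list(); labels <- character(0); ids <- character(0)
  manifest <- list()
  idx <- 0L
  for (ci in seq_len(n_classes)) {
    for (si in seq_len(n_per_class)) {
      idx <- idx + 1L
      img_seed <- as.integer(seed) + idx * 1009L
      draw <- with_seed(img_seed, runif(2))
      gain <- 0.8 + 0.4 * draw[1]          # mild affine gain variation
      phase <- draw[2]                     # shifts grating vs block grid
      images[[idx]] <- make_oriented_texture(
        dirs[ci], size = size, contrast = contrast * gain,
        noise_sigma = noise_sigma, seed = img_seed + 1L,
        cycles = cycles[ci], phase = phase)
      labels[idx] <- sprintf("o%03dc%02d", dirs[ci], cycles[ci])
      ids[idx] <- sprintf("o%03dc%02d_s%02d", dirs[ci], cycles[ci], si)
      manifest[[idx]] <- data.frame(
        id = ids[idx], label = labels[idx], direction_deg = dirs[ci],
        cycles = cycles[ci], size = size, contrast = contrast, gain = gain,
        phase = phase, noise_sigma = noise_sigma, img_seed = img_seed,
        stringsAsFactors = FALSE)
    }
  }
  list(images = images, labels = labels, ids = ids,
       manifest = do.call(rbind, manifest),
       params = list(n_classes = n_classes, n_per_class = n_per_class,
                     size = size, separation = separation,
                     noise_sigma = noise_sigma, contrast = contrast,
                     base_cycles = as.integer(base_cycles),
                     seed = as.integer(seed)))
}

#' Regenerate a dataset from its recorded parameters
#'
#' @param params the `params` element of a [make_dataset()] result.
#' @return the bit-identical dataset.
#' @export
replay_dataset <- function(params) do.call(make_dataset, params)

#' Find a noise perturbation that flips LBP but not LDDSCP
#'
#' Searches random small-integer 3x3 patches for a witness of the coding
#' robustness claim: perturbing a single neighbor pixel changes the center
#' pixel's 8-bit LBP code while both 4-bit dominant-direction codes are
#' unchanged. The LBP bit flips as soon as one neighbor crosses the center
#' intensity, whereas the group codes depend on each Kirsch response only
#' relative to its group mean, which small perturbations rarely reorder.
#'
#' @param search_budget maximum number of candidate (patch, perturbation)
#'   draws.
#' @param seed RNG seed for the search.
#' @param value_range intensity range of candidate patches.
#' @param max_delta largest perturbation magnitude tried.
#' @return list with `patch`, `perturbed` (3x3 matrices), `lbp`
#'   (the two differing LBP codes) and `codes` (the shared LDDSCP pair);
#'   errors if the budget is exhausted without a witness.
#' @export
find_lbp_flip_patch <- function(search_budget = 1e5, seed = 0L,
                                value_range = 0:40, max_delta = 5L) {
  if (search_budget < 1) stop("search budget must be >= 1")
  with_seed(seed, {
    for (trial in seq_len(search_budget)) {
      patch <- matrix(sample(value_range, 9, replace = TRUE), 3, 3)
      pos <- sample(setdiff(1:9, 5), 1)           # any neighbor, not center
      delta <- sample(c(-max_delta:-1, 1:max_delta), 1)
      pert <- patch
      pert[pos] <- pert[pos] + delta
      if (pert[pos] < 0) next
      l0 <- lbp_codes(patch)[1, 1]; l1 <- lbp_codes(pert)[1, 1]
      if (l0 == l1) next
      c0 <- lddscp_codes(patch); c1 <- lddscp_codes(pert)
      if (c0$code1[1, 1] == c1$code1[1, 1] &&
          c0$code2[1, 1] == c1$code2[1, 1]) {
        return(list(patch = patch, perturbed = pert,
                    lbp = c(original = l0, perturbed = l1),
                    codes = c(code1 = c0$code1[1, 1],
                              code2 = c0$code2[1, 1])))
      }
    }
    stop("no LBP-flip witness found within the search budget")
  })
}
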