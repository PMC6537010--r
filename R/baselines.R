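#' Baseline descriptor configuration
#'
#' Parameters for the block-histogram comparison descriptors. All three
#' share the LDDSCP block grid and concatenate one histogram per block:
#' \describe{
#'   \item{lbp}{8-bit code comparing each of the 8 neighbors to the center
#'     (neighbor >= center sets the bit); 256 bins/block. On a 128x128 image
#'     with 16x16 blocks the feature has 16384 dimensions.}
#'   \item{cslbp}{4-bit code from the 4 center-symmetric neighbor pairs
#'     (difference > threshold sets the bit); 16 bins/block, 1024 dims.}
#'   \item{ldp}{8-bit code setting the `k_ldp` bits with largest absolute
#'     Kirsch response; 256-bin histograms (only choose(8, k_ldp) codes are
#'     attainable), 16384 dims.}
#' }
#' Neighbors are ordered on the 8-connected ring starting East and moving
#' counter-clockwise, matching the Kirsch mask direction order.
#'
#' @param descriptor one of `"lbp"`, `"cslbp"`, `"ldp"`.
#' @param blocks_per_side blocks per image side (default 8: 16x16-pixel
#'   blocks on 128x128 inputs).
#' @param k_ldp number of prominent directions for LDP (default 3).
#' @param threshold CS-LBP pair-difference threshold (default 0; the bit
#'   requires a strictly positive excess, so ties stay 0).
#' @param border border policy as in [directional_responses()].
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(descriptor = c("lbp", "cslbp", "ldp"),
                            blocks_per_side = 8L, k_ldp = 3L,
                            threshold = 0, border = c("crop", "pad")) {
  descriptor <- match.arg(descriptor)
  border <- match.arg(border)
  stopifnot(blocks_per_side >= 1L, k_ldp >= 1L, k_ldp <= 8L)
  structure(list(descriptor = descriptor,
                 blocks_per_side = as.integer(blocks_per_side),
                 k_ldp = as.integer(k_ldp), threshold = threshold,
                 border = border),
            class = "baseline_config")
}

baseline_bins <- function(config) {
  switch(config$descriptor, lbp = 256L, ldp = 256L, cslbp = 16L)
}

# Neighbor offsets (dy, dx) on the 8-ring, counter-clockwise from East.
# Row 1 of the image is the top row, so "up" is dy = -1.
ring_offsets <- function() {
  rbind(E = c(0, 1), NE = c(-1, 1), N = c(-1, 0), NW = c(-1, -1),
        W = c(0, -1), SW = c(1, -1), S = c(1, 0), SE = c(1, 1))
}

# Shifted neighbor view: value of the neighbor at (dy, dx) for every coded
# (interior) pixel of `image`.
shift_view <- function(image, dy, dx) {
  h <- nrow(image); w <- ncol(image)
  image[(2L + dy):(h - 1L + dy), (2L + dx):(w - 1L + dx), drop = FALSE]
}

#' Per-pixel LBP codes
#'
#' 8-bit local binary pattern: bit i is 1 when neighbor i (ring order,
#' starting East, counter-clockwise) is greater than or equal to the center.
#' A constant image codes 255 everywhere.
#'
#' @param image numeric matrix, at least 3x3.
#' @param border `"crop"` or `"pad"`.
#' @return integer matrix of codes in 0..255.
#' @export
lbp_codes <- function(image, border = c("crop", "pad")) {
  border <- match.arg(border)
  image <- as_gray_matrix(image)
  if (nrow(image) < 3L || ncol(image) < 3L) stop("image must be >= 3x3")
  if (border == "pad") image <- replicate_pad(image)
  center <- shift_view(image, 0L, 0L)
  off <- ring_offsets()
  code <- matrix(0, nrow(center), ncol(center))
  for (i in 1:8) {
    code <- code + 2^(i - 1) * (shift_view(image, off[i, 1], off[i, 2]) >= center)
  }
  storage.mode(code) <- "integer"
  code
}

#' Per-pixel CS-LBP codes
#'
#' 4-bit center-symmetric LBP: bit i is 1 when neighbor i minus its
#' diametrically opposite neighbor exceeds the threshold (strictly).
#' Pairs, in bit order: E-W, NE-SW, N-S, NW-SE.
#'
#' @inheritParams lbp_codes
#' @param threshold pair-difference threshold (default 0).
#' @return integer matrix of codes in 0..15.
#' @export
cslbp_codes <- function(image, threshold = 0, border = c("crop", "pad")) {
  border <- match.arg(border)
  image <- as_gray_matrix(image)
  if (nrow(image) < 3L || ncol(image) < 3L) stop("image must be >= 3x3")
  if (border == "pad") image <- replicate_pad(image)
  off <- ring_offsets()
  code <- NULL
  for (i in 1:4) {
    d <- shift_view(image, off[i, 1], off[i, 2]) -
      shift_view(image, off[i + 4, 1], off[i + 4, 2])
    bit <- 2^(i - 1) * (d > threshold)
    code <- if (is.null(code)) bit else code + bit
  }
  storage.mode(code) <- "integer"
  code
}

#' Per-pixel LDP codes
#'
#' 8-bit local directional pattern: the image is correlated with all eight
#' Kirsch masks and the bits of the `k` masks with largest absolute response
#' are set (bit i = mask of direction 45*i degrees). Ties at the k-th rank
#' are broken toward the lower mask index. Every code has exactly `k` set
#' bits, so only choose(8, k) of the 256 values are attainable.
#'
#' @inheritParams lbp_codes
#' @param k number of prominent directions (default 3).
#' @return integer matrix of codes in 0..255.
#' @export
ldp_codes <- function(image, k = 3L, border = c("crop", "pad")) {
  border <- match.arg(border)
  stack <- directional_responses(image, kirsch_masks(), border)
  absresp <- lapply(stack$responses, abs)
  h <- nrow(absresp[[1]]); w <- ncol(absresp[[1]])
  flat <- do.call(cbind, lapply(absresp, as.numeric))   # (h*w) x 8
  code <- integer(h * w)
  # rank per pixel: order by (-|response|, mask index); take top k
  for (px in seq_len(h * w)) {
    top <- order(-flat[px, ], seq_len(8L))[seq_len(k)]
    code[px] <- as.integer(sum(2^(top - 1L)))
  }
  matrix(code, h, w)
}

#' Extract a baseline block-histogram feature
#'
#' Computes the per-pixel code map of the configured descriptor, partitions
#' it into the block grid, and concatenates per-block histograms (256 bins
#' for lbp/ldp, 16 for cslbp; all code values are binned, there are no
#' degenerate exclusions for the baselines).
#'
#' @param image numeric matrix.
#' @param config a [baseline_config()].
#' @return named numeric feature vector of length
#'   `blocks_per_side^2 * bins`.
#' @examples
#' img <- matrix(runif(128 * 128, 0, 255), 128, 128)
#' length(extract_baseline(img, baseline_config("cslbp")))  # 1024
#' @export
extract_baseline <- function(image, config = baseline_config()) {
  codes <- switch(config$descriptor,
    lbp = lbp_codes(image, config$border),
    cslbp = cslbp_codes(image, config$threshold, config$border),
    ldp = ldp_codes(image, config$k_ldp, config$border))
  bins <- baseline_bins(config)
  blocks <- partition_blocks(codes, config$blocks_per_side)
  segs <- lapply(seq_along(blocks), function(b) {
    seg <- tabulate(blocks[[b]] + 1L, nbins = bins)  # codes 0..bins-1
    names(seg) <- sprintf("b%d.%d", b, seq_len(bins) - 1L)
    seg
  })
  unlist(segs, use.names = TRUE)
}

#' Extract features by descriptor name
#'
#' Dispatcher used by the dataset-level helpers and the command line:
#' `"lddscp"` goes through [extract_lddscp()], the baselines through
#' [extract_baseline()].
#'
#' @param image numeric matrix.
#' @param descriptor `"lddscp"`, `"lbp"`, `"cslbp"` or `"ldp"`.
#' @param config optional pre-built [lddscp_config()]/[baseline_config()];
#'   built from defaults when `NULL`.
#' @return named numeric feature vector.
#' @export
extract_feature <- function(image,
                            descriptor = c("lddscp", "lbp", "cslbp", "ldp"),
                            config = NULL) {
  descriptor <- match.arg(descriptor)
  if (descriptor == "lddscp") {
    extract_lddscp(image, config %||% lddscp_config())
  } else {
    extract_baseline(image, config %||% baseline_config(descriptor))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature matrix of a labeled dataset
#'
#' Applies [extract_feature()] to every image of a dataset (as produced by
#' [make_dataset()] or [load_dataset()]).
#'
#' @param dataset list with `images` (list of matrices) and `labels`.
#' @inheritParams extract_feature
#' @return list with `features` (matrix, rows = samples), `labels`, `ids`.
#' @export
dataset_features <- function(dataset,
                             descriptor = c("lddscp", "lbp", "cslbp", "ldp"),
                             config = NULL) {
  descriptor <- match.arg(descriptor)
  rows <- lapply(dataset$images, extract_feature, descriptor = descriptor,
                 config = config)
  features <- do.call(rbind, rows)
  ids <- dataset$ids %||% sprintf("img%03d", seq_along(dataset$images))
  rownames(features) <- ids
  list(features = features, labels = dataset$labels, ids = ids)
}
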