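#' Descriptor configuration
#'
#' Collects the parameters of the block-histogram feature pipeline. With the
#' defaults (128x128 inputs, an 8x8 block grid, 4-bit codes, stacking) each
#' block is 16x16 pixels and contributes 14 bins, so the whole-image feature
#' has 8 * 8 * 14 = 896 dimensions. Concatenating the two group histograms
#' instead of stacking doubles the per-block dimensionality to 28.
#'
#' @param blocks_per_side number of blocks along each image side (N of the
#'   N x N grid); the grid sweep of interest is N in 2, 4, 8, 16.
#' @param strategy `"stack"` (element-wise sum of the LDDSCP-1 and LDDSCP-2
#'   block histograms; 14 dims/block, default) or `"concatenate"` (side by
#'   side; 28 dims/block).
#' @param border border policy passed to [directional_responses()].
#' @param bits_per_code code width; fixed at 4 for LDDSCP.
#' @param normalize if `TRUE`, L1-normalize each block histogram segment.
#'   Off by default: raw counts are the canonical feature.
#' @return an object of class `lddscp_config`.
#' @export
lddscp_config <- function(blocks_per_side = 8L,
                          strategy = c("stack", "concatenate"),
                          border = c("crop", "pad"),
                          bits_per_code = 4L,
                          normalize = FALSE) {
  strategy <- match.arg(strategy)
  border <- match.arg(border)
  blocks_per_side <- as.integer(blocks_per_side)
  stopifnot(blocks_per_side >= 1L, bits_per_code == 4L)
  structure(list(blocks_per_side = blocks_per_side, strategy = strategy,
                 border = border, bits_per_code = 4L, normalize = normalize),
            class = "lddscp_config")
}

#' @export
print.lddscp_config <- function(x, ...) {
  cat(sprintf(
    "LDDSCP config: %d x %d blocks, %s strategy, %s border, %d bins/block\n",
    x$blocks_per_side, x$blocks_per_side, x$strategy, x$border,
    feature_bins_per_block(x)), ...)
  invisible(x)
}

#' Number of informative code bins
#'
#' A k-bit group code can take `2^k` values, of which the all-zero and
#' all-one patterns express no dominant direction; `2^k - 2` informative
#' bins remain (14 for the 4-bit LDDSCP codes).
#'
#' @param bits code width in bits.
#' @return integer bin count.
#' @export
n_code_bins <- function(bits = 4L) as.integer(2^bits - 2)

feature_bins_per_block <- function(config) {
  b <- n_code_bins(config$bits_per_code)
  if (config$strategy == "stack") b else 2L * b
}

#' Expected feature length for a configuration
#'
#' `N^2 * 14` for stacking, `N^2 * 28` for concatenation, independent of the
#' image size (histogram counts, not densities, are used, so unequal block
#' support never changes dimensionality).
#'
#' @param config an [lddscp_config()].
#' @return integer feature length.
#' @export
lddscp_feature_length <- function(config = lddscp_config()) {
  config$blocks_per_side^2L * feature_bins_per_block(config)
}

#' Partition a code map into an N x N block grid
#'
#' Splits each side into N contiguous runs, as evenly as possible; when the
#' side is not divisible by N the shortfall (or surplus) is absorbed by the
#' outermost runs first. A 126x126 code map (a 128x128 image coded under the
#' crop border policy) with N = 8 therefore yields 16-pixel interior runs
#' and 15-pixel edge runs. Blocks are returned in row-major order.
#'
#' @param codes integer matrix (a code map) or any matrix to partition.
#' @param n blocks per side.
#' @return list of `n^2` matrices covering `codes` disjointly, row-major.
#' @export
partition_blocks <- function(codes, n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n > nrow(codes) || n > ncol(codes)) {
    stop(sprintf("cannot split a %dx%d map into %dx%d blocks",
                 nrow(codes), ncol(codes), n, n))
  }
  rr <- side_runs(nrow(codes), n)
  cc <- side_runs(ncol(codes), n)
  blocks <- vector("list", n * n)
  idx <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      blocks[[idx]] <- codes[rr[[i]], cc[[j]], drop = FALSE]
      idx <- idx + 1L
    }
  }
  blocks
}

# Split 1..len into n runs of near-equal size; deviation from the rounded
# target is pushed to the outermost runs (alternating first/last), so a
# cropped border shrinks edge blocks rather than shifting interior ones.
side_runs <- function(len, n) {
  m <- max(1L, as.integer(round(len / n)))
  sizes <- rep(m, n)
  excess <- n * m - len           # >0: runs too long, shave edges
  edge_order <- as.integer(rbind(seq_len(n), rev(seq_len(n))))[seq_len(n)]
  k <- 1L
  while (excess != 0L) {
    step <- if (excess > 0L) -1L else 1L
    i <- edge_order[(k - 1L) %% n + 1L]
    if (sizes[i] + step >= 1L) {
      sizes[i] <- sizes[i] + step
      excess <- excess + step
    }
    k <- k + 1L
  }
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n] + 1L)
  Map(seq.int, starts, ends)
}

#' Per-block histogram pair of the two LDDSCP code maps
#'
#' Counts, for each informative code value 1..14, the pixels of the block
#' whose LDDSCP-1 (resp. LDDSCP-2) code equals it. The degenerate codes 0
#' and 15 are counted in neither histogram, so each histogram sums to at
#' most the block pixel count.
#'
#' @param block1,block2 integer matrices of group-1 and group-2 codes for
#'   the same block.
#' @return list with integer count vectors `h1` and `h2`, each of length 14
#'   (bin i = code value i).
#' @export
block_histogram_pair <- function(block1, block2) {
  list(h1 = code_histogram(block1, 4L), h2 = code_histogram(block2, 4L))
}

# 14-bin (or 2^bits-2) histogram of codes 1 .. 2^bits-2; 0 and the all-ones
# code fall outside tabulate's range and are dropped.
code_histogram <- function(codes, bits = 4L) {
  tabulate(codes[codes >= 1L & codes <= n_code_bins(bits)],
           nbins = n_code_bins(bits))
}

#' Assemble the whole-image feature vector from block histogram pairs
#'
#' Under `"stack"` each block emits the element-wise sum `h1 + h2`
#' (14 values); under `"concatenate"` it emits `h1` followed by `h2`
#' (28 values). Blocks appear in row-major order.
#'
#' @param pairs list of [block_histogram_pair()] results, length `N^2`.
#' @param config an [lddscp_config()].
#' @return numeric feature vector of length [lddscp_feature_length()],
#'   named `b<block>.<bin>` (stack) or `b<block>.h<g>.<bin>` (concatenate).
#' @export
assemble_feature <- function(pairs, config = lddscp_config()) {
  n2 <- config$blocks_per_side^2L
  if (length(pairs) != n2) {
    stop(sprintf("expected %d histogram pairs, got %d", n2, length(pairs)))
  }
  bins <- n_code_bins(config$bits_per_code)
  segs <- lapply(seq_along(pairs), function(b) {
    p <- pairs[[b]]
    if (config$strategy == "stack") {
      seg <- p$h1 + p$h2
      names(seg) <- sprintf("b%d.%d", b, seq_len(bins))
    } else {
      seg <- c(p$h1, p$h2)
      names(seg) <- c(sprintf("b%d.h1.%d", b, seq_len(bins)),
                      sprintf("b%d.h2.%d", b, seq_len(bins)))
    }
    if (config$normalize && sum(seg) > 0) seg <- seg / sum(seg)
    seg
  })
  unlist(segs, use.names = TRUE)
}

#' Extract the LDDSCP feature vector of an image
#'
#' Full pipeline: Kirsch responses, group coding, N x N block partition,
#' per-block 14-bin histogram pair, and stacking (or concatenation) into the
#' final descriptor. With the defaults a 128x128 image yields an 896-dim
#' vector of raw counts.
#'
#' @param image numeric matrix, at least 3x3.
#' @param config an [lddscp_config()].
#' @return named numeric feature vector.
#' @examples
#' img <- matrix(runif(128 * 128, 0, 255), 128, 128)
#' length(extract_lddscp(img))   # 896
#' @export
extract_lddscp <- function(image, config = lddscp_config()) {
  codes <- lddscp_codes(image, config$border)
  b1 <- partition_blocks(codes$code1, config$blocks_per_side)
  b2 <- partition_blocks(codes$code2, config$blocks_per_side)
  pairs <- Map(block_histogram_pair, b1, b2)
  assemble_feature(pairs, config)
}
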