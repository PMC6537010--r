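#' Directional Kirsch responses of an image
#'
#' Correlates a grayscale image with the eight Kirsch masks and returns the
#' eight response maps together with the per-pixel mean response of each
#' symmetric group. Under the default `"crop"` border policy only pixels
#' with full 3x3 support are coded, so the response maps are
#' `(h-2) x (w-2)`; under `"pad"` the image border is replicated first and
#' the maps keep the input size.
#'
#' @param image numeric matrix (single-channel intensities; any real values,
#'   8-bit 0..255 by convention), at least 3x3.
#' @param masks mask set from [kirsch_masks()].
#' @param border `"crop"` (code interior pixels only, default) or `"pad"`
#'   (replicate-pad the border).
#' @return list with `responses` (named list of 8 response matrices, names
#'   the direction labels), `average1`, `average2` (per-pixel group means),
#'   and `border`.
#' @examples
#' patch <- matrix(c(0, 0, 100, 0, 0, 100, 0, 0, 100), 3, byrow = TRUE)
#' r <- directional_responses(patch)
#' sapply(r$responses, as.numeric)  # 1500 700 -100 -900 | -900 -900 -100 700
#' @export
directional_responses <- function(image, masks = kirsch_masks(),
                                  border = c("crop", "pad")) {
  border <- match.arg(border)
  image <- as_gray_matrix(image)
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("image must be at least 3x3 to code any pixel")
  }
  if (border == "pad") image <- replicate_pad(image)
  all_masks <- c(masks$group1, masks$group2)
  responses <- lapply(all_masks, function(m) correlate3x3(image, m))
  avg1 <- Reduce(`+`, responses[1:4]) / 4
  avg2 <- Reduce(`+`, responses[5:8]) / 4
  list(responses = responses, average1 = avg1, average2 = avg2,
       border = border)
}

# 3x3 correlation restricted to pixels with full support, via shifted
# submatrices (exact arithmetic, no FFT).
correlate3x3 <- function(image, mask) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h - 2L, w - 2L)
  for (dy in -1:1) {
    for (dx in -1:1) {
      wgt <- mask[dy + 2L, dx + 2L]
      if (wgt != 0) {
        out <- out + wgt * image[(2L + dy):(h - 1L + dy),
                                 (2L + dx):(w - 1L + dx), drop = FALSE]
      }
    }
  }
  out
}

replicate_pad <- function(image) {
  image <- image[c(1L, seq_len(nrow(image)), nrow(image)), , drop = FALSE]
  image[, c(1L, seq_len(ncol(image)), ncol(image)), drop = FALSE]
}

#' Encode LDDSCP code pairs from directional responses
#'
#' At each pixel the four responses of a group are compared with the group's
#' mean response: bit i (weight `2^i`) of the group's code is 1 when
#' response of mask i+1 is greater than or equal to the mean (the sign
#' function takes value 1 at 0, so ties set the bit). Group 1 yields the
#' LDDSCP-1 code, group 2 the LDDSCP-2 code; both live in 0..15 and the
#' degenerate values 0 ("0000") and 15 ("1111"), which express no dominant
#' direction, are excluded later when histograms are built.
#'
#' Because each bit depends only on the sign of a response minus the group
#' mean, the codes are invariant under affine intensity maps `a*I + b`
#' with `a > 0`.
#'
#' @param stack output of [directional_responses()].
#' @return list with integer matrices `code1` and `code2`.
#' @export
encode_patterns <- function(stack) {
  enc <- function(resps, avg) {
    code <- (resps[[1L]] >= avg) + 2 * (resps[[2L]] >= avg) +
      4 * (resps[[3L]] >= avg) + 8 * (resps[[4L]] >= avg)
    storage.mode(code) <- "integer"
    code
  }
  list(code1 = enc(stack$responses[1:4], stack$average1),
       code2 = enc(stack$responses[5:8], stack$average2))
}

#' LDDSCP code maps of an image
#'
#' Convenience composition of [directional_responses()] and
#' [encode_patterns()].
#'
#' @inheritParams directional_responses
#' @return list with integer code matrices `code1` (LDDSCP-1) and `code2`
#'   (LDDSCP-2), values in 0..15.
#' @examples
#' img <- matrix(rep(0:127, 128), 128, 128)   # eastward ramp
#' codes <- lddscp_codes(img)
#' table(codes$code1)[1]                       # dominated by code 3 ("0011")
#' @export
lddscp_codes <- function(image, border = c("crop", "pad")) {
  encode_patterns(directional_responses(image, kirsch_masks(), border))
}

# Coerce to a plain numeric matrix; reject non-2D input.
as_gray_matrix <- function(image) {
  if (is.data.frame(image)) image <- as.matrix(image)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix (single channel)")
  }
  image
}
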