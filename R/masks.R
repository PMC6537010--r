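#' Kirsch compass masks in two symmetric direction groups
#'
#' Builds the eight 3x3 Kirsch masks (three weights of +5 on one side, five
#' of -3, center 0; every mask sums to zero) and partitions them into two
#' symmetric groups: group 1 covers directions 0, 45, 90, 135 degrees and
#' group 2 the opposite directions 180, 225, 270, 315. The direction of a
#' mask is the direction of the intensity gradient it responds to most
#' strongly, with 0 degrees = East (the +5 column on the right) and angles
#' increasing counter-clockwise. Mask `i+1` of group 2 is mask `i+1` of
#' group 1 rotated by 180 degrees, so the full set is closed under 45-degree
#' rotation of the weight pattern.
#'
#' Matrices follow image convention: row 1 is the top image row, columns
#' increase eastward. Masks are applied as correlation stencils (no flip).
#'
#' @return A list with elements `group1` and `group2`, each a named list of
#'   four 3x3 integer matrices; names are the direction labels in degrees
#'   (`"0"`, `"45"`, ... ). Mask index i within a group is the bit position
#'   i-1 used by [encode_patterns()].
#' @examples
#' m <- kirsch_masks()
#' m$group1[["0"]]                  # East mask: +5 column on the right
#' sapply(m$group1, sum)            # all zero-sum
#' @export
kirsch_masks <- function() {
  east <- matrix(c(
    -3, -3, 5,
    -3,  0, 5,
    -3, -3, 5
  ), nrow = 3, byrow = TRUE)
  dirs <- seq(0L, 315L, by = 45L)
  masks <- vector("list", 8L)
  masks[[1L]] <- east
  for (i in 2:8) masks[[i]] <- rotate45(masks[[i - 1L]])
  names(masks) <- as.character(dirs)
  list(group1 = masks[1:4], group2 = masks[5:8])
}

# Rotate a 3x3 stencil counter-clockwise by 45 degrees: the 8 ring cells
# advance one position along the ring (in image coordinates, with row 1 on
# top, counter-clockwise on screen).
rotate45 <- function(m) {
  stopifnot(identical(dim(m), c(3L, 3L)) || identical(dim(m), c(3, 3)))
  # ring positions (row, col) in counter-clockwise order starting East
  ring <- rbind(
    c(2, 3), c(1, 3), c(1, 2), c(1, 1),
    c(2, 1), c(3, 1), c(3, 2), c(3, 3)
  )
  out <- m
  vals <- m[ring]
  out[ring[c(2:8, 1), , drop = FALSE]] <- vals
  out
}

#' Format a code value as a binary string
#'
#' Most-significant bit first, so the 4-bit code 3 prints as `"0011"`
#' (bits 0 and 1 set, i.e. the first two masks of the group dominate).
#'
#' @param code integer vector of code values.
#' @param bits code width (4 for LDDSCP and CS-LBP, 8 for LBP/LDP).
#' @return character vector of `bits`-character binary strings.
#' @export
code_to_binary <- function(code, bits = 4L) {
  stopifnot(all(code >= 0), all(code < 2^bits))
  vapply(code, function(x) {
    paste(rev(as.integer(intToBits(x))[seq_len(bits)]), collapse = "")
  }, character(1))
}
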