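test_that("block partition splits sides evenly with the shortfall on edge runs", {
  # 128x128 image coded under crop -> 126x126 map; 8x8 grid
  map <- matrix(0L, 126, 126)
  blocks <- partition_blocks(map, 8)
  expect_length(blocks, 64)
  sizes <- t(vapply(blocks, dim, integer(2)))
  expect_true(all(sizes %in% c(15L, 16L)))
  expect_identical(dim(blocks[[1]]), c(15L, 15L))    # corner block
  expect_identical(dim(blocks[[10]]), c(16L, 16L))   # interior block
  expect_equal(sum(sizes[seq(1, 64, by = 8), 1]), 126)

  expect_length(partition_blocks(map, 1), 1)
  expect_identical(partition_blocks(map, 1)[[1]], map)

  small <- matrix(1:64, 8, 8)
  quads <- partition_blocks(small, 2)
  expect_identical(quads[[1]], small[1:4, 1:4])
  expect_identical(quads[[2]], small[1:4, 5:8])      # row-major order
  expect_identical(quads[[3]], small[5:8, 1:4])
  expect_identical(quads[[4]], small[5:8, 5:8])

  expect_error(partition_blocks(small, 9), "blocks")
})

test_that("block partition covers the map disjointly for the sweep grid", {
  for (n in c(2, 4, 8, 16)) {
    map <- matrix(seq_len(126 * 126), 126, 126)
    blocks <- partition_blocks(map, n)
    expect_length(blocks, n^2)
    vals <- sort(unlist(lapply(blocks, as.vector)))
    expect_identical(vals, seq_len(126 * 126))       # partition, no overlap
  }
})

test_that("block histograms count informative codes and drop degenerate ones", {
  # constant image: all codes 15 -> empty histograms
  codes <- lddscp_codes(matrix(5, 18, 18))
  hp <- block_histogram_pair(codes$code1, codes$code2)
  expect_identical(hp$h1, rep(0L, 14))
  expect_identical(hp$h2, rep(0L, 14))

  # forced counting: every pixel codes (3, 12)
  b1 <- matrix(3L, 16, 16); b2 <- matrix(12L, 16, 16)
  hp <- block_histogram_pair(b1, b2)
  expect_equal(hp$h1[3], 256)
  expect_equal(sum(hp$h1), 256)
  expect_equal(hp$h2[12], 256)

  # random codes match a brute-force tally, including 0/15 exclusion
  set.seed(11)
  blk <- matrix(sample(0:15, 400, replace = TRUE), 20, 20)
  expect_equal(lddscp:::code_histogram(blk), oracle_hist(blk, 1, 14))
})

test_that("feature assembly follows the stack / concatenate dimension laws", {
  cfg_stack <- lddscp_config()
  cfg_cat <- lddscp_config(strategy = "concatenate")
  expect_equal(lddscp_feature_length(cfg_stack), 896)
  expect_equal(lddscp_feature_length(cfg_cat), 64 * 28)

  for (n in c(2, 4, 8, 16)) {
    expect_equal(lddscp_feature_length(lddscp_config(n)), n^2 * 14)
    expect_equal(
      lddscp_feature_length(lddscp_config(n, strategy = "concatenate")),
      n^2 * 2 * 14)
  }

  set.seed(21)
  pairs <- replicate(64, list(h1 = sample(0:9, 14, TRUE),
                              h2 = sample(0:9, 14, TRUE)),
                     simplify = FALSE)
  stacked <- assemble_feature(pairs, cfg_stack)
  concatenated <- assemble_feature(pairs, cfg_cat)
  expect_length(stacked, 896)
  expect_length(concatenated, 1792)
  for (b in c(1, 30, 64)) {
    seg <- stacked[(b - 1) * 14 + 1:14]
    expect_equal(unname(seg), pairs[[b]]$h1 + pairs[[b]]$h2)
    expect_equal(sum(seg), sum(pairs[[b]]$h1) + sum(pairs[[b]]$h2))
    seg2 <- concatenated[(b - 1) * 28 + 1:28]
    expect_equal(unname(seg2), c(pairs[[b]]$h1, pairs[[b]]$h2))
  }
  expect_error(assemble_feature(pairs[1:10], cfg_stack), "expected")
})

test_that("end-to-end extraction matches the chained naive oracle", {
  set.seed(31)
  for (trial in 1:5) {
    img <- random_image(2 * sample(12:16, 1))   # even coded-map side
    cfg <- lddscp_config(blocks_per_side = 2)
    got <- extract_lddscp(img, cfg)
    codes <- oracle_lddscp(img)
    want <- numeric(0)
    n <- nrow(codes$code1)          # even, so the 2x2 split is exact halves
    half <- list(seq_len(n / 2), (n / 2 + 1):n)
    for (i in 1:2) for (j in 1:2) {
      h1 <- oracle_hist(codes$code1[half[[i]], half[[j]]], 1, 14)
      h2 <- oracle_hist(codes$code2[half[[i]], half[[j]]], 1, 14)
      want <- c(want, h1 + h2)
    }
    expect_equal(unname(got), want)
  }
})

test_that("constant and affine-transformed images behave as the theory says", {
  img <- matrix(123, 128, 128)
  f <- extract_lddscp(img)
  expect_length(f, 896)
  expect_true(all(f == 0))                           # all codes degenerate

  set.seed(41)
  img <- random_image(64)
  expect_equal(extract_lddscp(2.5 * img + 17), extract_lddscp(img))
})

test_that("stacked feature mass is conserved and bounded by twice the coded pixels", {
  set.seed(51)
  for (trial in 1:5) {
    img <- random_image(sample(30:60, 1))
    codes <- lddscp_codes(img)
    f <- extract_lddscp(img, lddscp_config(blocks_per_side = 3))
    informative <- sum(codes$code1 %in% 1:14) + sum(codes$code2 %in% 1:14)
    expect_equal(sum(f), informative)
    expect_lte(sum(f), 2 * length(codes$code1))
  }
})

test_that("swapping two context-isolated image blocks swaps exactly their feature segments", {
  # 66x66 image, N = 4 grid, crop border: the coded map is 64x64 with
  # uniform 16-pixel runs. Blocks (2,2) and (3,4) carry random content kept
  # 2 pixels inside their boundaries (the 3x3 stencil support then never
  # leaks the content into neighboring blocks' code pixels), so swapping the
  # content must swap exactly the two feature segments.
  set.seed(61)
  a <- random_image(12)
  b <- random_image(12)
  img1 <- matrix(50, 66, 66)
  img1[20:31, 20:31] <- a
  img1[36:47, 52:63] <- b
  img2 <- matrix(50, 66, 66)
  img2[20:31, 20:31] <- b
  img2[36:47, 52:63] <- a
  cfg <- lddscp_config(blocks_per_side = 4)
  f1 <- extract_lddscp(img1, cfg)
  f2 <- extract_lddscp(img2, cfg)
  seg <- function(f, blk) f[(blk - 1) * 14 + 1:14]
  bA <- (2 - 1) * 4 + 2   # row-major block index of (2,2)
  bB <- (3 - 1) * 4 + 4   # block (3,4)
  expect_equal(unname(seg(f1, bA)), unname(seg(f2, bB)))
  expect_equal(unname(seg(f1, bB)), unname(seg(f2, bA)))
  other <- setdiff(1:16, c(bA, bB))
  for (blk in other) expect_equal(seg(f1, blk), seg(f2, blk))
})

test_that("optional L1 normalization rescales block segments", {
  set.seed(71)
  img <- random_image(32)
  f <- extract_lddscp(img, lddscp_config(2, normalize = TRUE))
  for (b in 1:4) {
    s <- sum(f[(b - 1) * 14 + 1:14])
    expect_true(abs(s - 1) < 1e-12 || s == 0)
  }
})
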