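#' Read a grayscale image
#'
#' Reads PNG (via the png package), TIFF (via the tiff package) or NetPBM
#' PGM (plain P2 or binary P5, parsed directly). Multichannel images are
#' converted to luminance (Rec. 601 weights). Intensities are returned on
#' the 0..255 scale as a numeric matrix, row 1 = top image row.
#'
#' @param path image file; format inferred from the extension.
#' @return numeric matrix of intensities.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    to_gray_255(arr)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
    to_gray_255(arr)
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop("unsupported image format: .", ext, " (", path, ")")
  }
}

# png/tiff readers return [0,1] arrays, possibly with channels; collapse to
# a 0..255 luminance matrix.
to_gray_255 <- function(arr) {
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    arr <- if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  arr * 255
}

#' Read a PGM image (plain P2 or binary P5)
#'
#' @param path file path.
#' @return numeric matrix on the file's own intensity scale.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval; '#' starts a comment to EOL
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L) {
    stop("malformed PGM header in ", path)
  }
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE,
                 comment.char = "#")
  } else {
    if (maxval > 255L) stop("16-bit P5 PGM not supported")
    vals <- as.integer(readBin(con, "raw", n = w * h))
  }
  if (length(vals) != w * h) stop("truncated PGM pixel data in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a plain-text PGM (P2) image
#'
#' Intensities are rounded and clipped to 0..maxval.
#'
#' @param image numeric matrix.
#' @param path output file.
#' @param maxval maximum intensity (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  image <- as_gray_matrix(image)
  v <- pmin(pmax(round(image), 0), maxval)
  header <- sprintf("P2\n%d %d\n%d", ncol(image), nrow(image), maxval)
  body <- apply(v, 1L, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Bilinear resize of a grayscale image
#'
#' @param image numeric matrix.
#' @param height,width target dimensions.
#' @return resized numeric matrix.
#' @export
resize_bilinear <- function(image, height, width) {
  image <- as_gray_matrix(image)
  h <- nrow(image); w <- ncol(image)
  if (h == height && w == width) return(image)
  # map target pixel centers into source coordinates
  ys <- (seq_len(height) - 0.5) * h / height + 0.5
  xs <- (seq_len(width) - 0.5) * w / width + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- image[y0, x0, drop = FALSE]; b <- image[y0, x1, drop = FALSE]
  c_ <- image[y1, x0, drop = FALSE]; d <- image[y1, x1, drop = FALSE]
  wy <- matrix(fy, height, width); wx <- matrix(fx, height, width,
                                                byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    c_ * wy * (1 - wx) + d * wy * wx
}

#' Center-crop a fraction of an image
#'
#' @param image numeric matrix.
#' @param fraction side fraction kept, in (0, 1].
#' @return cropped matrix.
#' @export
center_crop <- function(image, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(image)
  h <- nrow(image); w <- ncol(image)
  ch <- max(3L, round(h * fraction)); cw <- max(3L, round(w * fraction))
  y0 <- floor((h - ch) / 2); x0 <- floor((w - cw) / 2)
  image[(y0 + 1):(y0 + ch), (x0 + 1):(x0 + cw), drop = FALSE]
}

#' Write a labeled dataset as a directory tree
#'
#' One subdirectory per class, PGM files inside, plus a `manifest.tsv`
#' recording per-image generator parameters (when present) so a synthetic
#' dataset can be regenerated exactly. This is the same layout
#' [load_dataset()] consumes for real data.
#'
#' @param dataset a dataset from [make_dataset()] (or the same shape).
#' @param root output directory (created).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    cls_dir <- file.path(root, dataset$labels[i])
    dir.create(cls_dir, showWarnings = FALSE)
    write_pgm(dataset$images[[i]],
              file.path(cls_dir, paste0(dataset$ids[i], ".pgm")))
  }
  if (!is.null(dataset$manifest)) {
    write.table(dataset$manifest, file.path(root, "manifest.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(root)
}

#' Load a labeled image dataset from a directory tree
#'
#' Labels are the class subdirectory names; files are read in lexicographic
#' order within each class so sample identity (and hence leave-one-out fold
#' identity) is reproducible. Images may optionally be center-cropped and
#' resized to a common side length.
#'
#' @param root dataset root containing one subdirectory per class.
#' @param extensions accepted file extensions.
#' @param crop_fraction optional center-crop fraction in (0, 1].
#' @param resize_to optional target side length (e.g. 128); `NULL` keeps
#'   native sizes.
#' @return list with `images`, `labels`, `ids`.
#' @export
load_dataset <- function(root, extensions = c("png", "pgm", "tif", "tiff"),
                         crop_fraction = 1, resize_to = NULL) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  classes <- classes[nzchar(classes)]
  if (length(classes) < 2L) {
    stop("need at least 2 class subdirectories under ", root)
  }
  images <- list(); labels <- character(0); ids <- character(0)
  for (cl in classes) {
    files <- sort(list.files(file.path(root, cl), full.names = TRUE,
                             pattern = paste0("\\.(",
                                              paste(extensions, collapse = "|"),
                                              ")$"), ignore.case = TRUE))
    if (length(files) == 0L) stop("class directory has no images: ", cl)
    for (f in files) {
      img <- tryCatch(read_gray_image(f), error = function(e) {
        stop("failed to load ", f, ": ", conditionMessage(e))
      })
      if (crop_fraction < 1) img <- center_crop(img, crop_fraction)
      if (!is.null(resize_to)) img <- resize_bilinear(img, resize_to, resize_to)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      ids <- c(ids, tools::file_path_sans_ext(basename(f)))
    }
  }
  list(images = images, labels = labels, ids = ids)
}

#' Write a feature matrix with a self-describing header
#'
#' Tab-delimited text: comment lines (`#key: value`) record the descriptor
#' and its configuration, then a header row and one row per image with its
#' id, label and feature values.
#'
#' @param data list with `features`, `labels`, `ids`
#'   (from [dataset_features()]).
#' @param path output file.
#' @param meta named list of configuration values to record.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(data, path, meta = list()) {
  hdr <- vapply(names(meta), function(k) sprintf("#%s: %s", k, meta[[k]]),
                character(1))
  df <- data.frame(id = data$ids, label = data$labels,
                   data$features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(unname(hdr), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path input file.
#' @return list with `features` (matrix), `labels`, `ids`, and `meta`
#'   (named character vector of header key-values).
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- NULL
  if (length(meta_lines)) {
    kv <- sub("^#", "", meta_lines)
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- stats::setNames(vals, keys)
  }
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  features <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(features) <- df$id
  list(features = features, labels = as.character(df$label), ids = df$id,
       meta = meta)
}
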