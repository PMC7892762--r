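# Synthetic toy images and labelled datasets, plus IDX/PGM readers, so the
# whole encode -> reservoir -> readout pipeline can be exercised without any
# external download.

#' Draw a toy stroke image
#'
#' Renders a single geometric stroke — the kind of line or circular component
#' the Hough input layers are built to detect — into a grayscale image with
#' intensities in `[0, 1]`. Coordinates are 0-based with `x` the column index
#' and `y` the row index, origin at the top-left corner.
#'
#' @param shape One of `"vline"` (vertical line at column `x`), `"hline"`
#'   (horizontal line at row `y`), `"diag"` (diagonal `y = x + offset`),
#'   `"circle"` (lattice circle of radius `r` about `center`), or
#'   `"composite"` (a vline plus a circle).
#' @param x,y Column / row index for line shapes (0-based).
#' @param offset Diagonal offset for `"diag"`.
#' @param center Length-2 vector `c(x, y)` for `"circle"`/`"composite"`.
#' @param r Circle radius in pixels.
#' @param intensity Stroke intensity in `(0, 1]`.
#' @param width Stroke width in pixels: the 1-pixel stroke is dilated by the
#'   `width x width` square (clipped at the borders). Width 2 approximates the
#'   thickness of handwritten digit strokes.
#' @param jitter Fraction of stroke pixels whose position is perturbed by one
#'   pixel (uniformly among the 8 neighbours); `0` gives a deterministic image.
#' @param dims Image dimensions `c(rows, cols)`.
#' @param seed Optional integer seed controlling the jitter.
#'
#' @return A `dims[1] x dims[2]` numeric matrix with values in `[0, 1]`.
#' @examples
#' img <- make_shape_image("vline", x = 5)
#' sum(img > 0)  # 28 pixels, all in column 5
#' @export
make_shape_image <- function(shape = c("vline", "hline", "diag", "circle", "composite"),
                             x = 13, y = 13, offset = 0, center = c(13, 13), r = 5,
                             intensity = 1, width = 1, jitter = 0, dims = c(28, 28),
                             seed = NULL) {
  shape <- match.arg(shape)
  check_scalar_number(intensity, "intensity", lower = 0, upper = 1)
  check_scalar_number(width, "width", lower = 1)
  check_scalar_number(jitter, "jitter", lower = 0, upper = 1)
  h <- dims[1]; w <- dims[2]
  stroke <- switch(shape,
    vline = {
      if (x < 0 || x >= w) abort("`x` outside image bounds.")
      cbind(x = rep(x, h), y = 0:(h - 1))
    },
    hline = {
      if (y < 0 || y >= h) abort("`y` outside image bounds.")
      cbind(x = 0:(w - 1), y = rep(y, w))
    },
    diag = {
      xs <- 0:(w - 1); ys <- xs + offset
      keep <- ys >= 0 & ys < h
      if (!any(keep)) abort("diagonal falls outside image bounds.")
      cbind(x = xs[keep], y = ys[keep])
    },
    circle = circle_points(center[1], center[2], r, w, h),
    composite = rbind(cbind(x = rep(x, h), y = 0:(h - 1)),
                      circle_points(center[1], center[2], r, w, h))
  )
  stroke <- unique(stroke)
  if (width > 1) {
    dil <- expand.grid(dx = 0:(width - 1), dy = 0:(width - 1))
    stroke <- unique(do.call(rbind, lapply(seq_len(nrow(dil)), function(k) {
      cbind(x = pmin(stroke[, "x"] + dil$dx[k], w - 1),
            y = pmin(stroke[, "y"] + dil$dy[k], h - 1))
    })))
  }
  if (jitter > 0) {
    stroke <- with_seed_(seed, jitter_points(stroke, jitter, w, h))
  }
  img <- matrix(0, h, w)
  img[cbind(stroke[, "y"] + 1L, stroke[, "x"] + 1L)] <- intensity
  img
}

# Integer lattice points at exact squared distance r^2 from (a, b), the same
# enumeration the strict circle-Hough mode matches. For r = 5 about a centred
# point this yields the 12 Pythagorean lattice solutions.
circle_points <- function(a, b, r, w, h) {
  if (r == 0) return(cbind(x = a, y = b))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 == r^2, , drop = FALSE]
  pts <- cbind(x = a + off$dx, y = b + off$dy)
  pts <- pts[pts[, 1] >= 0 & pts[, 1] < w & pts[, 2] >= 0 & pts[, 2] < h, , drop = FALSE]
  if (nrow(pts) == 0) abort("circle falls entirely outside image bounds.")
  pts
}

jitter_points <- function(pts, jitter, w, h) {
  n <- nrow(pts)
  move <- which(stats::runif(n) < jitter)
  if (length(move)) {
    nb <- expand.grid(dx = -1:1, dy = -1:1)
    nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
    pick <- sample(nrow(nb), length(move), replace = TRUE)
    pts[move, "x"] <- pmin(pmax(pts[move, "x"] + nb$dx[pick], 0), w - 1)
    pts[move, "y"] <- pmin(pmax(pts[move, "y"] + nb$dy[pick], 0), h - 1)
  }
  unique(pts)
}

#' Generate a balanced labelled toy dataset
#'
#' Produces a balanced dataset of jittered stroke images whose classes differ
#' in their Hough signature: vertical lines (random column), horizontal lines
#' (random row), diagonals (random offset) and circles (random centre, fixed
#' radius). Line classes are separated by orientation in the line-Hough
#' parameter space and the circle class by its radius in the circle-Hough
#' space, so the modular reservoir with Hough input synapses is exercised
#' end to end. Because the stroke position varies within each class, the
#' classes are deliberately hard for a linear classifier on raw pixels.
#'
#' @param n_classes Number of classes, at most 4.
#' @param n_per_class Images per class.
#' @param jitter Per-image pixel jitter fraction (see [make_shape_image()]).
#' @param stroke_width Stroke width in pixels (default 2, the approximate
#'   thickness of handwritten digit strokes).
#' @param seed Integer seed; the dataset is a deterministic function of
#'   `(n_classes, n_per_class, jitter, seed)`.
#' @param dims Image dimensions.
#'
#' @return A list with `images` (list of matrices) and `labels`
#'   (integer vector, classes `0:(n_classes - 1)`).
#' @export
make_toy_dataset <- function(n_classes = 4, n_per_class = 10, jitter = 0,
                             seed = NULL, dims = c(28, 28), stroke_width = 2) {
  if (n_classes < 1 || n_classes > 4) abort("`n_classes` must be between 1 and 4.")
  families <- c("vline", "hline", "diag", "circle")
  with_seed_(seed, {
    images <- list(); labels <- integer(0)
    for (k in seq_len(n_classes)) {
      for (i in seq_len(n_per_class)) {
        img <- switch(families[k],
          vline  = make_shape_image("vline", x = sample(3:(dims[2] - 4), 1),
                                    width = stroke_width, jitter = jitter, dims = dims),
          hline  = make_shape_image("hline", y = sample(3:(dims[1] - 4), 1),
                                    width = stroke_width, jitter = jitter, dims = dims),
          diag   = make_shape_image("diag", offset = sample(-8:8, 1),
                                    width = stroke_width, jitter = jitter, dims = dims),
          circle = make_shape_image("circle",
                                    center = c(sample(7:(dims[2] - 8), 1),
                                               sample(7:(dims[1] - 8), 1)),
                                    r = 5, width = stroke_width, jitter = jitter,
                                    dims = dims)
        )
        images <- c(images, list(img)); labels <- c(labels, k - 1L)
      }
    }
    list(images = images, labels = labels)
  })
}

#' Read an IDX-format image or label file
#'
#' Reads the big-endian IDX container (magic `0x00000803` for
#' image tensors, `0x00000801` for label vectors) used by the MNIST
#' distribution. Image intensities are scaled from 0–255 to `[0, 1]`.
#'
#' @param images_path Path to an `idx3-ubyte` image file.
#' @param labels_path Optional path to the matching `idx1-ubyte` label file.
#' @return A list with `images` (list of numeric matrices) and `labels`
#'   (integer vector, or `NULL` when no label file is given).
#' @export
load_idx <- function(images_path, labels_path = NULL) {
  imgs <- read_idx_images(images_path)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read_idx_labels(labels_path)
    if (length(labels) != length(imgs)) {
      abort(sprintf("IDX mismatch: %d images but %d labels.",
                    length(imgs), length(labels)))
    }
  }
  list(images = imgs, labels = labels)
}

read_be_int <- function(con) readBin(con, "integer", 1, size = 4, endian = "big")

read_idx_images <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- read_be_int(con)
  if (length(magic) != 1 || magic != 2051L) {
    abort(sprintf("not an idx3-ubyte image file (magic %s at offset 0, expected 2051).",
                  if (length(magic)) magic else "<EOF>"))
  }
  n <- read_be_int(con); h <- read_be_int(con); w <- read_be_int(con)
  raw <- readBin(con, "raw", n * h * w)
  if (length(raw) != n * h * w) {
    abort(sprintf("truncated IDX image file: expected %d pixel bytes, found %d.",
                  n * h * w, length(raw)))
  }
  vals <- as.integer(raw) / 255
  lapply(seq_len(n), function(i) {
    # IDX stores each image row-major
    matrix(vals[((i - 1) * h * w + 1):(i * h * w)], h, w, byrow = TRUE)
  })
}

read_idx_labels <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- read_be_int(con)
  if (length(magic) != 1 || magic != 2049L) {
    abort(sprintf("not an idx1-ubyte label file (magic %s at offset 0, expected 2049).",
                  if (length(magic)) magic else "<EOF>"))
  }
  n <- read_be_int(con)
  raw <- readBin(con, "raw", n)
  if (length(raw) != n) {
    abort(sprintf("truncated IDX label file: expected %d labels, found %d.",
                  n, length(raw)))
  }
  as.integer(raw)
}

#' Read or write a PGM image
#'
#' Supports both the ASCII (`P2`) and binary (`P5`) portable graymap formats.
#' Intensities are normalized to `[0, 1]` on read and scaled to the stated
#' maximum value on write.
#'
#' @param path File path.
#' @return For `read_pgm()`, a numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) abort("not a P2/P5 PGM file.")
  toks <- integer(0)
  # header: width, height, maxval; '#' comments allowed
  while (length(toks) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (!length(ch) || ch == "") abort("truncated PGM header.")
    if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1)); if (c2 %in% c("\n", "")) break } ; next }
    if (grepl("[0-9]", ch)) {
      num <- ch
      repeat {
        c2 <- rawToChar(readBin(con, "raw", 1))
        if (grepl("[0-9]", c2)) num <- paste0(num, c2) else break
      }
      toks <- c(toks, as.integer(num))
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  if (magic == "P5") {
    raw <- readBin(con, "raw", w * h)
    if (length(raw) != w * h) abort("truncated P5 pixel data.")
    vals <- as.integer(raw)
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
    if (length(vals) != w * h) abort("truncated P2 pixel data.")
  }
  matrix(vals / maxval, h, w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param image Numeric matrix in `[0, 1]`.
#' @param maxval Maximum gray value written to the header.
#' @param ascii Write ASCII `P2` (default) or binary `P5`.
#' @export
write_pgm <- function(image, path, maxval = 255, ascii = TRUE) {
  check_image(image)
  vals <- round(pmin(pmax(image, 0), 1) * maxval)
  if (ascii) {
    lines <- c("P2", paste(ncol(image), nrow(image)), as.character(maxval),
               apply(vals, 1, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), maxval)), con)
    writeBin(as.raw(t(vals)), con)
  }
  invisible(path)
}
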