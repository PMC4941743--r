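#' Default box-size ladder for box counting
#'
#' Box edge lengths of 2 to 64 pixels, spaced roughly geometrically:
#' \{2, 3, 4, 6, 8, 12, 16, 32, 64\}. This matches the documented
#' defaults of the classical binary box-counting implementation in
#' common image-analysis software.
#'
#' @return integer vector of box edge lengths in pixels.
#' @export
default_box_sizes <- function() c(2L, 3L, 4L, 6L, 8L, 12L, 16L, 32L, 64L)

#' Extract the one-pixel-wide border of a binary trace
#'
#' Returns the foreground pixels that touch the background: a foreground
#' pixel is kept iff at least one of its 8 neighbours (4 with
#' \code{connectivity = 4}) is background, the image boundary counting
#' as background. Filled regions reduce to their one-pixel outline;
#' already-thin curves pass through unchanged. Box counting is run on
#' this border so that the thickness of the drawn band cannot influence
#' the estimated dimension.
#'
#' @param trace a [raster_trace()].
#' @param connectivity 8 (default) or 4.
#' @return a [raster_trace()] containing only border pixels.
#' @export
extract_border <- function(trace, connectivity = 8) {
  stopifnot(inherits(trace, "raster_trace"))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  px <- trace$pixels
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  any_bg <- matrix(FALSE, nr, nc)
  for (s in shifts) {
    nb <- pad[(2L + s[1]):(nr + 1L + s[1]), (2L + s[2]):(nc + 1L + s[2])]
    any_bg <- any_bg | (nb == 0L)
  }
  raster_trace(matrix(as.integer(px == 1L & any_bg), nr, nc),
               specimen_id = trace$specimen_id)
}

#' Count covering boxes of one size
#'
#' Partitions the image into an axis-aligned grid of size x size cells
#' anchored at \code{origin} (row/col offsets in \code{[0, size)});
#' partial cells at the image edges count as cells. Returns the number
#' of cells containing at least one foreground pixel. A size exceeding
#' both image dimensions yields 1 whenever any foreground exists.
#'
#' @param trace a [raster_trace()].
#' @param size box edge length in pixels, >= 1.
#' @param origin integer (row, col) grid offset, each in \code{[0, size)}.
#' @return integer count of occupied boxes.
#' @export
count_boxes <- function(trace, size, origin = c(0L, 0L)) {
  stopifnot(inherits(trace, "raster_trace"))
  size <- as.integer(size)
  if (size < 1L) stop("'size' must be >= 1")
  if (any(origin < 0L) || any(origin >= size))
    stop("'origin' components must be in [0, size)")
  idx <- which(trace$pixels == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  cr <- (idx[, 1] - 1L - origin[1]) %/% size
  cc <- (idx[, 2] - 1L - origin[2]) %/% size
  # cells left/above the origin (index -1) are partial cells, counted too
  length(unique(cr * (max(cc) - min(cc) + 2L) + (cc - min(cc))))
}

#' Box-count series over a ladder of box sizes
#'
#' Applies [count_boxes()] at each size in \code{sizes} on a single grid
#' anchored at \code{origin}, or, when \code{n_origins > 1}, averages
#' counts over that many uniformly drawn origins per size (a seeded
#' robustness mode; the default single-grid mode is the classical
#' procedure).
#'
#' @param trace a [raster_trace()].
#' @param sizes box edge lengths in pixels, all >= 2.
#' @param origin grid offset used for every size (single-grid mode).
#' @param n_origins if > 1, number of random grid origins to average over.
#' @param seed RNG seed for the random origins.
#' @return object of class \code{boxcount_series}: list with
#'   \code{sizes}, \code{counts}, \code{grid_origin}.
#' @export
box_count_series <- function(trace, sizes = default_box_sizes(),
                             origin = c(0L, 0L), n_origins = 1L,
                             seed = NULL) {
  stopifnot(inherits(trace, "raster_trace"))
  if (length(sizes) == 0L) stop("'sizes' must be non-empty")
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L)) stop("all box sizes must be >= 2")
  if (n_origins > 1L && !is.null(seed)) set.seed(seed)
  counts <- vapply(sizes, function(s) {
    if (n_origins <= 1L) as.numeric(count_boxes(trace, s, origin))
    else {
      ors <- cbind(sample.int(s, n_origins, replace = TRUE) - 1L,
                   sample.int(s, n_origins, replace = TRUE) - 1L)
      mean(vapply(seq_len(n_origins),
                  function(i) count_boxes(trace, s, ors[i, ]), numeric(1)))
    }
  }, numeric(1))
  structure(list(sizes = sizes, counts = counts,
                 grid_origin = as.integer(origin)),
            class = "boxcount_series")
}

#' @export
print.boxcount_series <- function(x, ...) {
  cat("box-count series (origin",
      paste(x$grid_origin, collapse = ","), "):\n")
  print(data.frame(size_px = x$sizes, n_boxes = x$counts))
  invisible(x)
}

#' Fit the fractal dimension from a box-count series
#'
#' Ordinary least squares of log N(s) on log s. The fitted slope is
#' negative (fewer, larger boxes are needed as s grows) and the fractal
#' dimension is its sign inverse, D = -slope. The log base is
#' immaterial; natural logs are used.
#'
#' @param series a \code{boxcount_series} with at least 3 distinct sizes
#'   and positive counts.
#' @return object of class \code{D_estimate}: list with \code{D},
#'   \code{intercept} (log-space), \code{fit_r2} and the input
#'   \code{series}.
#' @export
fit_dimension <- function(series) {
  stopifnot(inherits(series, "boxcount_series"))
  ok <- series$counts > 0
  s <- series$sizes[ok]; n <- series$counts[ok]
  if (length(s) < 3L) stop("need >= 3 sizes with positive counts")
  if (length(unique(n)) == 1L) {
    warning("all box counts equal; D = 0 (degenerate series)")
    return(structure(list(D = 0, intercept = log(n[1]), fit_r2 = NA_real_,
                          series = series), class = "D_estimate"))
  }
  fit <- stats::lm(log(n) ~ log(s))
  D <- -unname(stats::coef(fit)[2])
  if (D < 0.9 || D > 2.1)
    warning(sprintf("D = %.3f outside [0.9, 2.1]: not a planar curve?", D))
  structure(list(D = D, intercept = unname(stats::coef(fit)[1]),
                 fit_r2 = summary(fit)$r.squared, series = series),
            class = "D_estimate")
}

#' @export
print.D_estimate <- function(x, ...) {
  cat(sprintf("D = %.4f (log-log R^2 = %.4f, %d box sizes)\n",
              x$D, x$fit_r2, length(x$series$sizes)))
  invisible(x)
}

#' Estimate the fractal dimension of a binary trace
#'
#' The full box-counting estimator: the one-pixel border of the trace is
#' extracted (skipped in the diagnostic \code{border = FALSE} mode, e.g.
#' to confirm that a filled region approaches D = 2), covered by grids
#' of each box size, and D fitted as minus the slope of log N(s) on
#' log s. Deterministic for a fixed configuration.
#'
#' @param trace a [raster_trace()] with at least one foreground pixel.
#' @param sizes box-size ladder, default [default_box_sizes()].
#' @param border apply [extract_border()] first (default TRUE).
#' @param connectivity neighbourhood for border extraction.
#' @param origin grid origin, default (0, 0).
#' @return a \code{D_estimate}.
#' @export
estimate_D <- function(trace, sizes = default_box_sizes(), border = TRUE,
                       connectivity = 8, origin = c(0L, 0L)) {
  stopifnot(inherits(trace, "raster_trace"))
  if (sum(trace$pixels) == 0L) stop("empty trace")
  if (border) trace <- extract_border(trace, connectivity = connectivity)
  fit_dimension(box_count_series(trace, sizes = sizes, origin = origin))
}

#' Estimate D for a directory of trace images
#'
#' Runs [read_trace()] and [estimate_D()] over every PNG/TIFF in a
#' directory. Unreadable or empty images are skipped with a warning
#' rather than aborting the batch.
#'
#' @param dir directory of .png/.tif/.tiff images.
#' @param threshold,invert passed to [read_trace()].
#' @param ... passed to [estimate_D()].
#' @return data.frame with columns \code{specimen_id}, \code{D},
#'   \code{fit_r2}, \code{n_sizes}.
#' @export
estimate_D_dir <- function(dir, threshold = 0.5, invert = FALSE, ...) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  rows <- lapply(files, function(f) {
    est <- tryCatch(
      estimate_D(read_trace(f, threshold = threshold, invert = invert), ...),
      error = function(e) {
        warning("skipping ", basename(f), ": ", conditionMessage(e))
        NULL
      })
    if (is.null(est)) return(NULL)
    data.frame(specimen_id = tools::file_path_sans_ext(basename(f)),
               D = est$D, fit_r2 = est$fit_r2,
               n_sizes = length(est$series$sizes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(specimen_id = character(), D = numeric(),
                      fit_r2 = numeric(), n_sizes = integer())
  out
}
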