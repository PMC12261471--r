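#' Tent (triangle) function of a single persistence pair
#'
#' Piecewise-linear function supported on `(b, d)`: rises with slope 1 from
#' the birth, falls with slope -1 to the death, peaking at `(d - b) / 2` at
#' the midpoint `(b + d) / 2`.
#'
#' @param pair Numeric length-2 vector `c(birth, death)` with `birth <= death`.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of tent values, zero outside `(b, d)`.
#' @export
#' @examples
#' triangle_function(c(100, 200), 150)  # peak: 50
triangle_function <- function(pair, x) {
  b <- pair[1]; d <- pair[2]
  if (!is.finite(b) || !is.finite(d) || b > d) {
    stop("invalid persistence pair: need finite birth <= death", call. = FALSE)
  }
  pmax(0, pmin(x - b, d - x))
}

# bars alive at threshold t: born at or before t, not yet dead; essential
# bars additionally count at the top of the range
bars_alive_at <- function(diagram, t, dim) {
  d <- diagram[diagram$dim == dim, , drop = FALSE]
  sum(d$birth <= t & (t < d$death | (d$essential & t >= d$death)))
}

#' Betti curve of a persistence diagram
#'
#' Entry m counts the bars of the requested dimension alive at threshold
#' `tm`: a bar (b, d) is alive at t when `b <= t < d`; the essential class is
#' also alive at the final threshold 255.
#'
#' @param diagram A `persistence_diagram`.
#' @param grid Threshold grid the diagram was computed over.
#' @param dim Homology dimension, 0 (components) or 1 (loops).
#' @return Integer vector with one entry per threshold.
#' @export
betti_curve <- function(diagram, grid = attr(diagram, "grid"), dim = 0L) {
  if (is.null(grid)) grid <- threshold_grid()
  validate_grid(grid)
  if (!dim %in% c(0L, 1L)) stop("dim must be 0 or 1", call. = FALSE)
  vapply(grid, function(t) as.integer(bars_alive_at(diagram, t, dim)),
         integer(1))
}

#' First persistence landscape sampled on a fixed domain
#'
#' The level-1 landscape is the pointwise maximum of the tent functions of
#' all pairs of the requested dimension. It is sampled at `bins` evenly
#' spaced points placed at the centers of the equal subintervals of
#' \[0, 255\], giving features comparable across images.
#'
#' @param diagram A `persistence_diagram`.
#' @param dim Homology dimension, 0 or 1.
#' @param bins Number of sampling bins (default 100).
#' @return Numeric vector of length `bins`; all zeros for an empty diagram.
#' @export
landscape_level1 <- function(diagram, dim = 0L, bins = 100L) {
  if (!dim %in% c(0L, 1L)) stop("dim must be 0 or 1", call. = FALSE)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  x <- landscape_bins(bins)
  d <- diagram[diagram$dim == dim, , drop = FALSE]
  if (nrow(d) == 0L) return(numeric(bins))
  vals <- vapply(seq_len(nrow(d)),
                 function(i) triangle_function(c(d$birth[i], d$death[i]), x),
                 numeric(length(x)))
  apply(matrix(vals, nrow = length(x)), 1, max)
}

#' Landscape sampling points
#'
#' Centers of the `bins` equal subintervals of \[0, 255\].
#'
#' @param bins Number of bins.
#' @return Numeric vector of length `bins`.
#' @export
landscape_bins <- function(bins = 100L) {
  (seq_len(bins) - 0.5) * (255 / bins)
}

#' Per-channel topological feature block
#'
#' Concatenates Betti H0, Betti H1 (length N each) and first-landscape H0,
#' H1 (length B each) of one channel's diagram: with the defaults N = 50 and
#' B = 100 this is the 300-dimensional per-channel block.
#'
#' @param diagram A `persistence_diagram`.
#' @param grid Threshold grid.
#' @param bins Landscape bins.
#' @return Named numeric vector of length `2 * length(grid) + 2 * bins`.
#' @export
channel_vector <- function(diagram, grid = attr(diagram, "grid"),
                           bins = 100L) {
  if (is.null(grid)) grid <- threshold_grid()
  v <- c(betti_curve(diagram, grid, 0L),
         betti_curve(diagram, grid, 1L),
         landscape_level1(diagram, 0L, bins),
         landscape_level1(diagram, 1L, bins))
  names(v) <- c(sprintf("betti0_%02d", seq_along(grid)),
                sprintf("betti1_%02d", seq_along(grid)),
                sprintf("land0_%03d", seq_len(bins)),
                sprintf("land1_%03d", seq_len(bins)))
  v
}

#' Split an RGB raster into the four filtration channels
#'
#' @param rgb Numeric array `r x s x 3` with values in \[0, 255\].
#' @return Named list of integer matrices: `gray` (ITU-R 601 luminance
#'   0.299 R + 0.587 G + 0.114 B, rounded), `red`, `green`, `blue`.
#' @export
split_channels <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("expected an r x s x 3 RGB array", call. = FALSE)
  }
  gray <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  list(gray  = as_channel_image(gray, "gray"),
       red   = as_channel_image(rgb[, , 1], "red"),
       green = as_channel_image(rgb[, , 2], "green"),
       blue  = as_channel_image(rgb[, , 3], "blue"))
}

#' Full topological feature vector of an RGB image
#'
#' Runs the sublevel cubical persistence pipeline on the grayscale, red,
#' green and blue channels and concatenates the four per-channel blocks
#' (Betti H0 | Betti H1 | landscape H0 | landscape H1 within each channel).
#' With the default 50-threshold grid and 100 landscape bins the result has
#' 4 x (2x50 + 2x100) = 1200 entries.
#'
#' @param rgb Numeric array `r x s x 3`, values in \[0, 255\].
#' @param grid Threshold grid.
#' @param bins Landscape bins.
#' @return Named numeric vector (length 1200 at the defaults) with a
#'   `layout` attribute recording the block order.
#' @export
image_vector <- function(rgb, grid = threshold_grid(), bins = 100L) {
  chans <- split_channels(rgb)
  blocks <- lapply(names(chans), function(ch) {
    v <- channel_vector(cubical_persistence(chans[[ch]], grid), grid, bins)
    names(v) <- paste(ch, names(v), sep = "_")
    v
  })
  out <- unlist(blocks, use.names = TRUE)
  attr(out, "layout") <- paste(rep(names(chans),
                                   each = 2L * length(grid) + 2L * bins),
                               collapse = NULL)
  out
}

#' Restrict a topological feature vector to Betti or landscape blocks
#'
#' Used by the ablation fusion variants that feed only Betti curves or only
#' persistence landscapes into the projection head.
#'
#' @param v Vector from [image_vector()] (named entries).
#' @param blocks `"betti"`, `"landscape"` or `"all"`.
#' @return The selected sub-vector.
#' @export
topo_blocks <- function(v, blocks = c("all", "betti", "landscape")) {
  blocks <- match.arg(blocks)
  if (blocks == "all") return(v)
  pat <- if (blocks == "betti") "_betti" else "_land"
  v[grepl(pat, names(v), fixed = TRUE)]
}

#' Write a per-entity feature table as TSV
#'
#' One row per entity id; the first column is `id`, remaining columns the
#' feature entries (layout documented in the header comment line).
#'
#' @param mat Numeric matrix with rownames = entity ids.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# feature table: %d entities x %d features",
                     nrow(mat), ncol(mat)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-entity feature table written by [write_feature_table()]
#'
#' @param path TSV file.
#' @return Numeric matrix with rownames = entity ids.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
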