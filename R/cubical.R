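#' Threshold grid for sublevel-set filtrations
#'
#' Builds the increasing sequence of pixel-value thresholds
#' `0 = t1 < t2 < ... < tN = 255` at which binary sublevel images are taken.
#' The default is 50 evenly spaced values spanning the full 8-bit range.
#'
#' @param n Number of thresholds (>= 2).
#' @return Numeric vector of length `n`, strictly increasing, with first
#'   element 0 and last element 255.
#' @export
#' @examples
#' g <- threshold_grid(10)
#' range(g)
threshold_grid <- function(n = 50) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("`n` must be a single number >= 2", call. = FALSE)
  }
  seq(0, 255, length.out = as.integer(n))
}

validate_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2) {
    stop("threshold grid must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("threshold grid must be strictly increasing", call. = FALSE)
  }
  if (grid[1] != 0 || grid[length(grid)] != 255) {
    stop("threshold grid must start at 0 and end at 255; otherwise some ",
         "pixels would never activate", call. = FALSE)
  }
  invisible(grid)
}

#' Coerce a numeric matrix to a single-channel 8-bit image
#'
#' Values are rounded half-up to integers and must land in \[0, 255\].
#'
#' @param values Numeric matrix (at least 2x2).
#' @param channel Channel tag, one of `"gray"`, `"red"`, `"green"`, `"blue"`.
#' @return Integer matrix with a `channel` attribute.
#' @export
as_channel_image <- function(values, channel = c("gray", "red", "green", "blue")) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("image must be at least 2x2", call. = FALSE)
  }
  v <- floor(values + 0.5)  # round half up
  if (any(!is.finite(v)) || any(v < 0) || any(v > 255)) {
    stop("pixel values must be finite and in [0, 255]", call. = FALSE)
  }
  storage.mode(v) <- "integer"
  attr(v, "channel") <- channel
  v
}

# Index of the smallest grid value >= v, for each pixel value v.
snap_index <- function(values, grid) {
  idx <- findInterval(values, grid)
  hit <- idx >= 1 & abs(grid[pmax(idx, 1L)] - values) < 1e-9
  idx[!hit] <- idx[!hit] + 1L
  idx
}

#' Sublevel-set filtration of an image
#'
#' At each threshold `tm` of the grid, the binary image contains exactly the
#' pixels whose value is `<= tm`, giving a nested sequence of cubical
#' complexes (mask m is a subset of mask m+1).
#'
#' @param image Integer matrix as returned by [as_channel_image()].
#' @param grid Threshold grid from [threshold_grid()].
#' @return List of logical matrices, one per threshold.
#' @export
sublevel_filtration <- function(image, grid = threshold_grid()) {
  image <- as_channel_image(image, channel = attr(image, "channel") %||% "gray")
  validate_grid(grid)
  lapply(grid, function(t) image <= t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euler characteristic of a binary cubical complex
#'
#' Counts vertices, edges and faces of the closure cubical complex whose
#' 2-cells are the active pixels (each pixel contributes its 4 corner
#' vertices and 4 boundary edges; shared cells are counted once) and returns
#' V - E + F. For sublevel complexes of 2D images this equals beta0 - beta1.
#'
#' @param mask Logical matrix of active pixels.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  r <- nrow(mask); s <- ncol(mask)
  p <- matrix(FALSE, r + 2L, s + 2L)
  p[2:(r + 1L), 2:(s + 1L)] <- mask
  faces <- sum(mask)
  verts <- sum(p[1:(r + 1L), 1:(s + 1L)] | p[1:(r + 1L), 2:(s + 2L)] |
               p[2:(r + 2L), 1:(s + 1L)] | p[2:(r + 2L), 2:(s + 2L)])
  e_horiz <- sum(p[1:(r + 1L), 2:(s + 1L)] | p[2:(r + 2L), 2:(s + 1L)])
  e_vert  <- sum(p[2:(r + 1L), 1:(s + 1L)] | p[2:(r + 1L), 2:(s + 2L)])
  as.integer(verts - (e_horiz + e_vert) + faces)
}

#' H0/H1 persistence diagram of an image sublevel filtration
#'
#' Computes the persistence diagram of the sublevel-set cubical filtration of
#' a single-channel image over a threshold grid. H0 bars track connected
#' components (closure T-construction, so components are vertex-adjacent);
#' merges follow the elder rule with ties broken by the smallest linearized
#' pixel index of the component root. H1 bars track holes, computed by
#' duality as components of the 4-connected complement scanned in decreasing
#' threshold order. The single essential H0 class of the full image is closed
#' at death 255 and flagged `essential`. Zero-persistence pairs (birth equal
#' to death after snapping values to the grid) are dropped.
#'
#' @param image Numeric/integer matrix (coerced via [as_channel_image()]).
#' @param grid Threshold grid.
#' @return A `persistence_diagram`: data.frame with columns `birth`, `death`,
#'   `dim` (0 or 1) and `essential` (logical), plus the grid as an attribute.
#' @export
cubical_persistence <- function(image, grid = threshold_grid()) {
  image <- as_channel_image(image, channel = attr(image, "channel") %||% "gray")
  validate_grid(grid)
  r <- nrow(image); s <- ncol(image)
  n <- r * s
  lev <- matrix(snap_index(as.numeric(image), grid), r, s)

  ## ---- H0: union-find over pixels in increasing (level, index) order ----
  ord <- order(as.vector(lev), seq_len(n))
  parent <- seq_len(n)
  birth <- integer(n)        # level index at component birth (at root)
  rootpix <- integer(n)      # smallest linearized pixel index in component
  active <- logical(n)
  b0_births <- integer(0); b0_deaths <- integer(0)

  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # 8-neighbourhood offsets as (drow, dcol)
  off8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L,  0L,  1L, -1L, 1L, -1L, 0L, 1L))
  for (p in ord) {
    i <- ((p - 1L) %% r) + 1L
    j <- ((p - 1L) %/% r) + 1L
    lv <- lev[p]
    birth[p] <- lv
    rootpix[p] <- p
    active[p] <- TRUE
    for (k in 1:8) {
      ii <- i + off8[k, 1L]; jj <- j + off8[k, 2L]
      if (ii < 1L || ii > r || jj < 1L || jj > s) next
      q <- ii + (jj - 1L) * r
      if (!active[q]) next
      ra <- find(p); rb <- find(q)
      if (ra == rb) next
      # elder rule: smaller birth survives; tie -> smaller root pixel index
      if (birth[ra] < birth[rb] ||
          (birth[ra] == birth[rb] && rootpix[ra] < rootpix[rb])) {
        elder <- ra; young <- rb
      } else {
        elder <- rb; young <- ra
      }
      if (birth[young] < lv) {           # drop zero-persistence merges
        b0_births <- c(b0_births, birth[young])
        b0_deaths <- c(b0_deaths, lv)
      }
      parent[young] <- elder
    }
  }
  # exactly one essential component: the full rectangle
  ess_root <- find(1L)
  ess_birth <- birth[ess_root]

  ## ---- H1 by duality: complement (4-connected) in decreasing order ----
  # pixel p is in the complement at thresholds strictly below grid[lev[p]];
  # pixels snapped to the first grid value are never in the complement.
  comp <- which(as.vector(lev) > 1L)
  b1_births <- integer(0); b1_deaths <- integer(0)
  if (length(comp)) {
    cord <- comp[order(-lev[comp], comp)]
    # node n+1 is the unbounded outside region (reverse-birth = +Inf)
    parent2 <- seq_len(n + 1L)
    rbirth <- integer(n + 1L)  # reverse birth level (max level in component)
    rbirth[n + 1L] <- .Machine$integer.max
    active2 <- logical(n + 1L)
    active2[n + 1L] <- TRUE
    find2 <- function(i) {
      while (parent2[i] != i) {
        parent2[i] <<- parent2[parent2[i]]
        i <- parent2[i]
      }
      i
    }
    off4 <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
    for (p in cord) {
      i <- ((p - 1L) %% r) + 1L
      j <- ((p - 1L) %/% r) + 1L
      lv <- lev[p]
      rbirth[p] <- lv
      active2[p] <- TRUE
      nbrs <- integer(0)
      for (k in 1:4) {
        ii <- i + off4[k, 1L]; jj <- j + off4[k, 2L]
        if (ii < 1L || ii > r || jj < 1L || jj > s) {
          nbrs <- c(nbrs, n + 1L)       # image border touches the outside
        } else {
          q <- ii + (jj - 1L) * r
          if (active2[q]) nbrs <- c(nbrs, q)
        }
      }
      for (q in nbrs) {
        ra <- find2(p); rb <- find2(q)
        if (ra == rb) next
        if (rbirth[ra] >= rbirth[rb]) { old <- ra; young <- rb } else { old <- rb; young <- ra }
        # the hole corresponding to `young` exists at grid levels [lv, rbirth-1]
        if (rbirth[young] > lv) {
          b1_births <- c(b1_births, lv)
          b1_deaths <- c(b1_deaths, rbirth[young])
        }
        parent2[young] <- old
      }
    }
    # bounded complement components never linked to the outside: holes already
    # enclosed at the lowest threshold
    roots <- unique(vapply(cord, find2, integer(1)))
    out_root <- find2(n + 1L)
    for (rt in setdiff(roots, out_root)) {
      if (rbirth[rt] > 1L) {
        b1_births <- c(b1_births, 1L)
        b1_deaths <- c(b1_deaths, rbirth[rt])
      }
    }
  }

  pairs <- data.frame(
    birth = c(grid[b0_births], grid[ess_birth], grid[b1_births]),
    death = c(grid[b0_deaths], 255, grid[b1_deaths]),
    dim = c(rep(0L, length(b0_births)), 0L, rep(1L, length(b1_births))),
    essential = c(rep(FALSE, length(b0_births)), TRUE,
                  rep(FALSE, length(b1_births)))
  )
  pairs <- pairs[order(pairs$dim, pairs$birth, pairs$death), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, grid = grid, class = c("persistence_diagram", "data.frame"))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram: %d H0 bar(s), %d H1 bar(s)\n",
              sum(x$dim == 0L), sum(x$dim == 1L)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Serialize persistence diagrams to TSV
#'
#' @param diagrams Named list of `persistence_diagram` objects (names are
#'   channel tags), or a single diagram.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagrams, path) {
  if (inherits(diagrams, "persistence_diagram")) {
    diagrams <- list(gray = diagrams)
  }
  rows <- do.call(rbind, lapply(names(diagrams), function(ch) {
    d <- diagrams[[ch]]
    data.frame(birth = d$birth, death = d$death, dim = d$dim,
               channel = ch, essential = d$essential)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read persistence diagrams from TSV
#'
#' @param path File written by [write_diagram()].
#' @return Named list of `persistence_diagram` objects, one per channel.
#' @export
read_diagram <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("birth", "death", "dim", "channel", "essential")
  if (!all(need %in% names(rows))) {
    stop("diagram file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(rows, rows$channel), function(d) {
    structure(data.frame(birth = d$birth, death = d$death,
                         dim = as.integer(d$dim), essential = d$essential),
              class = c("persistence_diagram", "data.frame"))
  })
}
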