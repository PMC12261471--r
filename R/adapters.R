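#' Render a molecule image from a SMILES string
#'
#' Produces a square RGB raster depicting the molecular skeleton as dark
#' strokes on a white background, the form the sublevel filtration expects
#' (low values activate first, so bonds appear before the background and
#' rings show up as H1 classes). The built-in renderer parses a restricted
#' SMILES subset (organic-subset atoms, aromatic lowercase atoms, bonds
#' `-=#`, branches, ring-closure digits), lays the molecular graph out with a
#' fixed-iteration deterministic force-directed embedding initialized on a
#' circle, and rasterizes bonds as anti-aliasing-free strokes. The same
#' SMILES always yields identical bytes. A different backend (e.g. a
#' chemistry toolkit) can be plugged in via `renderer`.
#'
#' @param smiles SMILES string.
#' @param size Canvas edge in pixels (default 256).
#' @param id Optional entity id, echoed in error messages.
#' @param renderer Optional function `(smiles, size)` returning an
#'   `size x size x 3` array in \[0, 255\]; overrides the built-in drawing.
#' @return Numeric array `size x size x 3` with values in \[0, 255\].
#' @export
#' @examples
#' img <- render_molecule("c1ccccc1", size = 64)
#' dim(img)
render_molecule <- function(smiles, size = 256L, id = NULL,
                            renderer = NULL) {
  if (!is.null(renderer)) {
    out <- renderer(smiles, size)
    stopifnot(is.array(out), all(dim(out) == c(size, size, 3)))
    return(out)
  }
  mol <- tryCatch(parse_smiles(smiles), error = function(e) {
    stop(sprintf("cannot render SMILES%s: %s",
                 if (is.null(id)) "" else paste0(" for id '", id, "'"),
                 conditionMessage(e)), call. = FALSE)
  })
  xy <- layout_molecule(mol)
  draw_skeleton(xy, mol$bonds, size)
}

# --- restricted SMILES parser -----------------------------------------------
# atoms: B C N O P S F I Cl Br (+ aromatic lowercase b c n o p s),
# bonds - = #, branches ( ), ring-closure digits 1-9.
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("empty or non-character SMILES", call. = FALSE)
  }
  chars <- strsplit(smiles, "")[[1]]
  n_atoms <- 0L
  bonds <- matrix(0L, 0, 2)
  prev <- 0L
  stack <- integer(0)
  ring_open <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#")) {
      i <- i + 1L
      next                                  # bond order ignored in skeleton
    }
    if (ch == "(") {
      if (prev == 0L) stop("branch before any atom", call. = FALSE)
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')'", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (grepl("^[1-9]$", ch)) {
      if (prev == 0L) stop("ring digit before any atom", call. = FALSE)
      key <- ch
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- prev
      } else {
        bonds <- rbind(bonds, c(ring_open[[key]], prev))
        ring_open[[key]] <- NULL
      }
      i <- i + 1L; next
    }
    two <- if (i < length(chars)) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      i <- i + 1L; ch <- two
    } else if (!ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                          "b", "c", "n", "o", "p", "s")) {
      stop(sprintf("unsupported SMILES token '%s'", ch), call. = FALSE)
    }
    n_atoms <- n_atoms + 1L
    if (prev > 0L) bonds <- rbind(bonds, c(prev, n_atoms))
    prev <- n_atoms
    i <- i + 1L
  }
  if (length(stack)) stop("unbalanced '('", call. = FALSE)
  if (length(ring_open)) stop("unclosed ring bond", call. = FALSE)
  if (n_atoms == 0L) stop("no atoms", call. = FALSE)
  list(n_atoms = n_atoms, bonds = bonds)
}

# deterministic force-directed layout: circle initialization, fixed number of
# Fruchterman-Reingold-style updates, no randomness
layout_molecule <- function(mol, iters = 250L) {
  n <- mol$n_atoms
  theta <- 2 * pi * (seq_len(n) - 1L) / max(n, 3L)
  xy <- cbind(cos(theta), sin(theta))
  if (n == 1L) return(matrix(0, 1, 2))
  k <- sqrt(4 / n)                   # ideal edge length in layout units
  bonds <- mol$bonds
  step0 <- 0.1
  for (it in seq_len(iters)) {
    disp <- matrix(0, n, 2)
    dx <- outer(xy[, 1], xy[, 1], "-")
    dy <- outer(xy[, 2], xy[, 2], "-")
    d2 <- dx * dx + dy * dy + 1e-9
    rep_f <- k * k / d2
    disp[, 1] <- rowSums(dx * rep_f) ; disp[, 2] <- rowSums(dy * rep_f)
    if (nrow(bonds)) {
      bx <- xy[bonds[, 1], 1] - xy[bonds[, 2], 1]
      by <- xy[bonds[, 1], 2] - xy[bonds[, 2], 2]
      bd <- sqrt(bx * bx + by * by) + 1e-9
      fx <- bx * bd / k; fy <- by * bd / k
      for (e in seq_len(nrow(bonds))) {
        a <- bonds[e, 1]; b <- bonds[e, 2]
        disp[a, ] <- disp[a, ] - c(fx[e], fy[e])
        disp[b, ] <- disp[b, ] + c(fx[e], fy[e])
      }
    }
    dl <- sqrt(rowSums(disp^2)) + 1e-9
    step <- step0 * (1 - it / (iters + 1L))
    xy <- xy + disp / dl * pmin(dl, step)
  }
  xy
}

# rasterize line segments as value-0 strokes on a 255 background
draw_skeleton <- function(xy, bonds, size) {
  size <- as.integer(size)
  rng <- apply(xy, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-6)
  margin <- 0.12 * size
  scale <- (size - 2 * margin) / span
  px <- margin + (xy[, 1] - rng[1, 1]) * scale
  py <- margin + (xy[, 2] - rng[1, 2]) * scale
  canvas <- matrix(255, size, size)
  halfw <- max(1.2, size / 120)
  gx <- matrix(rep(seq_len(size) - 0.5, size), size, size)       # row coord
  gy <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
  paint <- function(mask) canvas[mask] <<- 0
  if (nrow(bonds)) {
    for (e in seq_len(nrow(bonds))) {
      a <- bonds[e, 1]; b <- bonds[e, 2]
      x1 <- px[a]; y1 <- py[a]; x2 <- px[b]; y2 <- py[b]
      vx <- x2 - x1; vy <- y2 - y1
      L2 <- vx * vx + vy * vy
      t <- if (L2 < 1e-12) 0 else pmin(1, pmax(0, ((gx - x1) * vx + (gy - y1) * vy) / L2))
      ddx <- gx - (x1 + t * vx); ddy <- gy - (y1 + t * vy)
      paint(ddx * ddx + ddy * ddy <= halfw^2)
    }
  } else {
    ddx <- gx - px[1]; ddy <- gy - py[1]
    paint(ddx * ddx + ddy * ddy <= (2 * halfw)^2)
  }
  array(rep(canvas, 3), c(size, size, 3))
}

#' Convert a protein contact map to an RGB image
#'
#' Scales a square matrix of contact probabilities in \[0, 1\] to the 8-bit
#' range, resamples it to `size x size` by nearest-neighbor interpolation
#' (order-preserving, so the sublevel filtration order is unchanged) and
#' replicates the single channel to the three color planes.
#'
#' @param mat Square numeric matrix with entries in \[0, 1\].
#' @param size Output edge in pixels (default 300).
#' @return Numeric array `size x size x 3` with integer values in \[0, 255\].
#' @export
contact_map_to_image <- function(mat, size = 300L) {
  if (!is.matrix(mat) || !is.numeric(mat) || nrow(mat) != ncol(mat)) {
    stop("contact map must be a square numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(mat)) || any(mat < 0) || any(mat > 1)) {
    stop("contact map entries must be finite and in [0, 1]", call. = FALSE)
  }
  size <- as.integer(size)
  n <- nrow(mat)
  scaled <- floor(mat * 255 + 0.5)                 # round half up
  idx <- floor((seq_len(size) - 0.5) * n / size) + 1L
  idx <- pmin(pmax(idx, 1L), n)
  out <- scaled[idx, idx, drop = FALSE]
  array(rep(out, 3), c(size, size, 3))
}

#' Read a protein contact map from a text matrix file
#'
#' @param path Whitespace- or comma-delimited numeric matrix file.
#' @return Numeric matrix.
#' @export
read_contact_map <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  as.matrix(utils::read.table(path, sep = sep, header = FALSE))
}

#' Read protein records from a FASTA file
#'
#' Parses sequences with `Biostrings` and returns them as target entity
#' records (id from the FASTA header up to the first whitespace).
#'
#' @param path FASTA file.
#' @return Data frame with columns `id`, `kind` (`"target"`), `sequence`.
#' @export
records_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("records_from_fasta requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, call. = FALSE)
  }
  data.frame(id = ids, kind = "target",
             sequence = as.character(seqs), row.names = NULL)
}

expected_embedding_length <- function(kind) {
  switch(match.arg(kind, c("drug", "target")), drug = 768L, target = 1024L)
}

#' Load a precomputed embedding table
#'
#' Reads a TSV/CSV with an `id` column followed by numeric feature columns,
#' such as exported molecule- or protein-language-model embeddings (768
#' columns for drugs, 1024 for targets).
#'
#' @param path TSV or CSV file.
#' @param kind `"drug"` or `"target"`.
#' @return Numeric matrix with rownames = ids.
#' @export
load_embedding_table <- function(path, kind = c("drug", "target")) {
  kind <- match.arg(kind)
  want <- expected_embedding_length(kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("embedding table needs an 'id' column",
                                 call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (!is.numeric(m)) stop("embedding columns must be numeric", call. = FALSE)
  rownames(m) <- df$id
  bad <- rowSums(!is.finite(m)) > 0
  if (ncol(m) != want) {
    stop(sprintf("%s embeddings must have %d columns, found %d (ids: %s)",
                 kind, want, ncol(m),
                 paste(utils::head(df$id, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(bad)) {
    stop("non-finite embedding rows for ids: ",
         paste(utils::head(rownames(m)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Write an embedding table as TSV
#'
#' @param mat Numeric matrix with rownames = ids.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stable 31-bit string hash for per-id reproducibility independent of order
string_seed <- function(id, seed) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(id)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Deterministic mock sequence embeddings
#'
#' Generates standard-normal embedding vectors of the kind's nominal width
#' (768 for drugs, 1024 for targets) as a stand-in for exported language-
#' model embeddings. Each id's vector depends only on `(id, seed)`, so
#' tables are reproducible and independent of id ordering.
#'
#' @param ids Character vector of entity ids.
#' @param kind `"drug"` or `"target"`.
#' @param seed Integer seed.
#' @return Numeric matrix `length(ids) x width` with rownames = ids.
#' @export
mock_embeddings <- function(ids, kind = c("drug", "target"), seed = 1L) {
  kind <- match.arg(kind)
  len <- expected_embedding_length(kind)
  out <- matrix(0, length(ids), len,
                dimnames = list(ids, paste0("e", seq_len(len))))
  for (i in seq_along(ids)) {
    rs <- string_seed(ids[i], seed)
    out[i, ] <- withr::with_seed(rs, stats::rnorm(len))
  }
  out
}

#' Create a two-layer projection head
#'
#' Initializes the fully connected `input -> hidden -> out` head (ReLU after
#' both layers) that maps raw sequence embeddings or topological feature
#' vectors into the shared latent space (512-D by default).
#'
#' @param input_len Input width.
#' @param out Output width (default 512).
#' @param hidden Hidden width (default `out`).
#' @param seed Integer seed for He-scaled normal initialization.
#' @return List with weight matrices `W1`, `W2` and biases `b1`, `b2`.
#' @export
projection_head <- function(input_len, out = 512L, hidden = out, seed = 1L) {
  withr::with_seed(seed, {
    list(W1 = matrix(stats::rnorm(input_len * hidden, sd = sqrt(2 / input_len)),
                     input_len, hidden),
         b1 = numeric(hidden),
         W2 = matrix(stats::rnorm(hidden * out, sd = sqrt(2 / hidden)),
                     hidden, out),
         b2 = numeric(out))
  })
}

relu <- function(x) pmax(x, 0)

#' Project embeddings into the shared latent space
#'
#' Applies the two-layer ReLU head: `relu(relu(X W1 + b1) W2 + b2)`.
#'
#' @param x Numeric vector or matrix (rows = entities).
#' @param head Head from [projection_head()].
#' @return Matrix of projected rows (or vector if `x` was a vector).
#' @export
project <- function(x, head) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(m) != nrow(head$W1)) {
    stop(sprintf("projection head expects input width %d, got %d",
                 nrow(head$W1), ncol(m)), call. = FALSE)
  }
  h <- relu(sweep(m %*% head$W1, 2, head$b1, "+"))
  o <- relu(sweep(h %*% head$W2, 2, head$b2, "+"))
  if (vec) drop(o) else o
}

#' Read an RGB image from PNG or a text matrix
#'
#' PNG files are read with the `png` package and rescaled to \[0, 255\];
#' grayscale PNGs are replicated to three channels. Text files are parsed as
#' numeric matrices already on the 0-255 scale.
#'
#' @param path Input file (`.png`, or delimited text).
#' @return Numeric array `r x s x 3` in \[0, 255\].
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    return(a * 255)
  }
  m <- as.matrix(utils::read.table(path, header = FALSE))
  array(rep(m, 3), c(dim(m), 3))
}

#' Write an RGB array to PNG
#'
#' @param img Array `r x s x 3` in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
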