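# Independent oracle: persistence of the sublevel cubical filtration by
# textbook boundary-matrix reduction over Z/2 on the closure complex
# (vertices, edges, pixel faces; lower cells enter with the min of their
# incident pixels). Deliberately slow and simple; used on small images only.

oracle_persistence <- function(values, grid) {
  r <- nrow(values); s <- ncol(values)
  lev <- matrix(topofuse:::snap_index(as.numeric(values), grid), r, s)

  # cell tables ---------------------------------------------------------
  # vertices: (r+1) x (s+1), id = vi + (vj-1)*(r+1)
  vlev <- matrix(Inf, r + 1L, s + 1L)
  for (i in 1:r) for (j in 1:s) {
    for (di in 0:1) for (dj in 0:1) {
      vlev[i + di, j + dj] <- min(vlev[i + di, j + dj], lev[i, j])
    }
  }
  nV <- (r + 1L) * (s + 1L)
  # vertical edges between vertices (vi,vj)-(vi+1,vj): r x (s+1)
  # horizontal edges between vertices (vi,vj)-(vi,vj+1): (r+1) x s
  edges <- list(); elev <- numeric(0)
  eid <- function(k) nV + k
  ev <- matrix(0L, 0, 2)  # endpoint vertex ids
  add_edge <- function(v1, v2, lv) {
    ev <<- rbind(ev, c(v1, v2)); elev <<- c(elev, lv)
  }
  vid <- function(vi, vj) vi + (vj - 1L) * (r + 1L)
  vedge_idx <- matrix(0L, r, s + 1L)
  for (vj in 1:(s + 1L)) for (vi in 1:r) {
    lv <- Inf
    if (vj >= 2)      lv <- min(lv, lev[vi, vj - 1L])
    if (vj <= s)      lv <- min(lv, lev[vi, vj])
    add_edge(vid(vi, vj), vid(vi + 1L, vj), lv)
    vedge_idx[vi, vj] <- length(elev)
  }
  hedge_idx <- matrix(0L, r + 1L, s)
  for (vj in 1:s) for (vi in 1:(r + 1L)) {
    lv <- Inf
    if (vi >= 2)      lv <- min(lv, lev[vi - 1L, vj])
    if (vi <= r)      lv <- min(lv, lev[vi, vj])
    add_edge(vid(vi, vj), vid(vi, vj + 1L), lv)
    hedge_idx[vi, vj] <- length(elev)
  }
  nE <- length(elev)
  # faces: pixel (i,j) bounded by edges top/bottom (horizontal) + left/right
  flev <- as.numeric(lev)
  fedges <- matrix(0L, r * s, 4)
  for (j in 1:s) for (i in 1:r) {
    fedges[i + (j - 1L) * r, ] <- c(hedge_idx[i, j], hedge_idx[i + 1L, j],
                                    vedge_idx[i, j], vedge_idx[i, j + 1L])
  }

  dim_all <- c(rep(0L, nV), rep(1L, nE), rep(2L, r * s))
  lev_all <- c(as.numeric(vlev), elev, flev)
  ord <- order(lev_all, dim_all, seq_along(lev_all))
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)

  # boundary columns in filtration positions ----------------------------
  cols <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    cell <- ord[k]
    if (dim_all[cell] == 0L) {
      cols[[k]] <- integer(0)
    } else if (dim_all[cell] == 1L) {
      e <- cell - nV
      cols[[k]] <- sort(pos[ev[e, ]])
    } else {
      f <- cell - nV - nE
      cols[[k]] <- sort(pos[nV + fedges[f, ]])
    }
  }

  symdiff <- function(a, b) {
    x <- c(a, b)
    sort(x[!(duplicated(x) | duplicated(x, fromLast = TRUE))])
  }
  low_owner <- integer(length(ord))  # column that has this row as its low
  pairs_b <- integer(0); pairs_d <- integer(0); pairs_dim <- integer(0)
  for (k in seq_along(ord)) {
    col <- cols[[k]]
    while (length(col)) {
      lw <- col[length(col)]
      if (low_owner[lw] == 0L) break
      col <- symdiff(col, cols[[low_owner[lw]]])
    }
    cols[[k]] <- col
    if (length(col)) {
      lw <- col[length(col)]
      low_owner[lw] <- k
      pairs_b <- c(pairs_b, lw); pairs_d <- c(pairs_d, k)
      pairs_dim <- c(pairs_dim, dim_all[ord[lw]])
    }
  }
  paired <- c(pairs_b, pairs_d)
  res <- data.frame(birth = lev_all[ord[pairs_b]], death = lev_all[ord[pairs_d]],
                    dim = pairs_dim, essential = FALSE)
  # essential classes: unpaired cells (positive, never a death)
  unpaired <- setdiff(seq_along(ord), paired)
  unpaired <- unpaired[lengths(cols[unpaired]) == 0L]
  for (k in unpaired) {
    d <- dim_all[ord[k]]
    if (d <= 1L) {
      res <- rbind(res, data.frame(birth = lev_all[ord[k]], death = Inf,
                                   dim = d, essential = TRUE))
    }
  }
  res <- res[res$essential | res$birth < res$death, , drop = FALSE]
  res$birth <- grid[res$birth]
  res$death <- ifelse(is.finite(res$death), grid[res$death], 255)
  res <- res[order(res$dim, res$birth, res$death), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-threshold component count of a mask, vertex-adjacent (8-connected) BFS
count_components8 <- function(mask) {
  r <- nrow(mask); s <- ncol(mask)
  seen <- matrix(FALSE, r, s)
  ncomp <- 0L
  for (j in 1:s) for (i in 1:r) {
    if (!mask[i, j] || seen[i, j]) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- cur[1] + di; jj <- cur[2] + dj
        if (ii >= 1 && ii <= r && jj >= 1 && jj <= s &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
  }
  ncomp
}

rand_image <- function(r, s, levels = 0:255) {
  matrix(sample(levels, r * s, replace = TRUE), r, s)
}

diagram_key <- function(d) {
  d <- d[order(d$dim, d$birth, d$death), c("birth", "death", "dim")]
  paste(sprintf("%.6f|%.6f|%d", d$birth, d$death, d$dim), collapse = ";")
}
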