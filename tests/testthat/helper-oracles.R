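# Independent brute-force oracles used across the suite. These are
# deliberately naive (queue-based flood fill, per-pixel loops) and
# share no code with the implementations they check.

# Flood-fill connected-component labeling, 2D.
oracle_label_2d <- function(cells, connectivity = 8L) {
  nr <- nrow(cells); nc <- ncol(cells)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  nbrs <- as.matrix(nbrs)
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (cells[r, c] == 0L || lab[r, c] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(r, c)); lab[r, c] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nbrs))) {
          rr <- p[1] + nbrs[k, 1]; cc <- p[2] + nbrs[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              cells[rr, cc] != 0L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Flood fill on a stacked volume, 26-connectivity.
oracle_label_3d <- function(vox) {
  dm <- dim(vox)
  lab <- array(0L, dm)
  nxt <- 0L
  for (s in seq_len(dm[3])) for (r in seq_len(dm[1])) for (c in seq_len(dm[2])) {
    if (vox[r, c, s] == 0L || lab[r, c, s] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c, s)); lab[r, c, s] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
        if (dr == 0 && dc == 0 && ds == 0) next
        rr <- p[1] + dr; cc <- p[2] + dc; ss <- p[3] + ds
        if (rr >= 1 && rr <= dm[1] && cc >= 1 && cc <= dm[2] &&
            ss >= 1 && ss <= dm[3] &&
            vox[rr, cc, ss] != 0L && lab[rr, cc, ss] == 0L) {
          lab[rr, cc, ss] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc, ss)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff the label pairing is
# a bijection on the foreground.
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  fg <- a != 0L
  if (!identical(fg, b != 0L)) return(FALSE)
  if (!any(fg)) return(TRUE)
  pairs <- unique(cbind(a[fg], b[fg]))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# Per-pixel binary median with edge replication (clamped coordinates,
# duplicates counted).
oracle_median <- function(cells, kernel) {
  nr <- nrow(cells); nc <- ncol(cells); h <- kernel %/% 2
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- integer(0)
    for (dr in -h:h) for (dc in -h:h) {
      rr <- min(max(r + dr, 1), nr); cc <- min(max(c + dc, 1), nc)
      vals <- c(vals, cells[rr, cc])
    }
    out[r, c] <- as.integer(median(vals))
  }
  out
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

random_labelmap <- function(nr, nc) {
  label_map(matrix(sample(0:3, nr * nc, TRUE), nr, nc))
}

# Small phantom used by unit tests (full-size runs live in the
# acceptance suite).
tiny_spec <- function(size = 64) phantom_spec(image_size = size)

# Ring (cranium) pixel mask implied by a spec, from the deterministic
# geometry.
ring_mask_of <- function(spec) {
  geo <- phantom_geometry(spec)
  sz <- spec$image_size
  rr <- matrix(seq_len(sz), sz, sz) - geo$center[1]
  cc <- matrix(seq_len(sz), sz, sz, byrow = TRUE) - geo$center[2]
  d <- sqrt(rr^2 + cc^2)
  d <= geo$r_outer & d > geo$r_inner
}
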