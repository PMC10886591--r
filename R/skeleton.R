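# Binary-image skeleton utilities: Zhang-Suen thinning, 8-connected
# labeling, and skeleton-path lengths. Written in-package because no
# installed R package provides 2-D skeletonization; all operations are on
# logical matrices (TRUE = foreground).

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Eight neighbors in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW).
zs_neighbors <- function(m) {
  list(p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1))
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until an 8-connected, one-pixel-wide
#' skeleton remains.
#'
#' @param mask logical matrix, TRUE = foreground.
#' @return logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- zs_neighbors(m)
      b <- Reduce(`+`, nb)
      seqd <- with(nb, list(p2, p3, p4, p5, p6, p7, p8, p9, p2))
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (seqd[[i]] == 0L & seqd[[i + 1L]] == 1L)
      if (step == 1) {
        c1 <- nb$p2 * nb$p4 * nb$p6
        c2 <- nb$p4 * nb$p6 * nb$p8
      } else {
        c1 <- nb$p2 * nb$p4 * nb$p8
        c2 <- nb$p2 * nb$p6 * nb$p8
      }
      kill <- m == 1L & b >= 2L & b <= 6L & a == 1L & c1 == 0L & c2 == 0L
      if (any(kill)) { m[kill] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Number of 8-neighbors of each pixel that are foreground.
neighbor_count <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  Reduce(`+`, zs_neighbors(m))
}

# 8-connected component labeling by flood fill; returns an integer matrix
# (0 = background). Masks here are sparse skeletons, so a queue in R is fine.
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && lab[q] == 0L) { lab[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# Path length of a labeled skeleton component in pixels: each orthogonal
# adjacency contributes 1, each diagonal adjacency sqrt(2); one pixel is
# added so that an n-pixel simple path measures ~n, compensating the
# endpoint erosion of thinning.
component_lengths_px <- function(lab) {
  ortho <- diag_ <- integer(max(lab))
  count_pairs <- function(dr, dc) {
    a <- lab
    b <- shift_mat(lab, dr, dc)
    same <- a > 0L & b > 0L & a == b
    tabulate(a[same], nbins = max(lab))
  }
  ortho <- count_pairs(0, 1) + count_pairs(1, 0)
  diag_ <- count_pairs(1, 1) + count_pairs(1, -1)
  ortho + sqrt(2) * diag_ + 1
}
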