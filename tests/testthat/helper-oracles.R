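# Independent oracles used across the suite.

# Membership-count IoU on a regular point lattice of spacing d. Counts
# lattice points (cell centers) inside each box with a pointwise predicate;
# exact when box edges lie on the d-grid, since no point falls on an edge.
raster_iou <- function(a, b, d = 0.1) {
  x0 <- min(a$x, b$x); x1 <- max(a$x + a$w, b$x + b$w)
  y0 <- min(a$y, b$y); y1 <- max(a$y + a$h, b$y + b$h)
  xs <- seq(x0 + d / 2, x1, by = d)
  ys <- seq(y0 + d / 2, y1, by = d)
  in_ax <- xs >= a$x & xs < a$x + a$w
  in_ay <- ys >= a$y & ys < a$y + a$h
  in_bx <- xs >= b$x & xs < b$x + b$w
  in_by <- ys >= b$y & ys < b$y + b$h
  na <- sum(in_ax) * sum(in_ay)
  nb <- sum(in_bx) * sum(in_by)
  ni <- sum(in_ax & in_bx) * sum(in_ay & in_by)
  ni / (na + nb - ni)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], all_perms(v[-i]))))
}

# Best achievable total IoU over all one-to-one matchings where pairs below
# iou_min are disallowed, by exhaustive enumeration of permutations of the
# zero-padded square matrix.
brute_best_total <- function(score, iou_min) {
  n <- nrow(score); m <- ncol(score)
  k <- max(n, m)
  sq <- matrix(0, k, k)
  sq[seq_len(n), seq_len(m)] <- ifelse(score >= iou_min, score, 0)
  p <- all_perms(seq_len(k))
  max(apply(p, 1, function(perm) sum(sq[cbind(seq_len(k), perm)])))
}

assoc_total <- function(iou_mat, assoc) {
  if (nrow(assoc$matches) == 0L) return(0)
  sum(iou_mat[assoc$matches])
}

# A random box on the 0.1-px grid inside a 1280x720 frame, and a perturbed
# partner likely to overlap it.
random_box_pair <- function() {
  w <- round(runif(1, 10, 200), 1); h <- round(runif(1, 10, 200), 1)
  x <- round(runif(1, 0, 1280 - w), 1); y <- round(runif(1, 0, 720 - h), 1)
  a <- list(x = x, y = y, w = w, h = h)
  b <- list(x = round(x + runif(1, -60, 60), 1),
            y = round(y + runif(1, -60, 60), 1),
            w = round(pmax(10, w + runif(1, -30, 30)), 1),
            h = round(pmax(10, h + runif(1, -30, 30)), 1))
  list(a = a, b = b)
}
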