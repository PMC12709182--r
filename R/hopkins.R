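#' Hopkins clustering-tendency statistic
#'
#' Measures whether contact positions are clustered or spatially uniform
#' over the admissible region of the map, the triangle
#' \eqn{\{(i, j) : 1 \le i,\ i + \mathrm{min\_sep} \le j \le L\}}.  Per
#' repetition, `m = max(1, ceiling(frac * n))` probe positions are drawn
#' uniformly from that triangle and `m` real contacts are drawn without
#' replacement; with `u` the nearest-contact distances of the probes and
#' `w` the nearest-other-contact distances of the sampled contacts,
#' \deqn{H = \frac{\sum u}{\sum u + \sum w}.}
#' The returned value is the mean over `reps` repetitions.  Uniform point
#' sets give \eqn{H \approx 0.5}; strongly clustered sets approach 1.
#'
#' @param x A [contact_map()], a `contact_selection`, or a 2-column matrix
#'   of `(i, j)` positions (then `L` is required).
#' @param L,min_sep Domain geometry; taken from `x` when it is a map or a
#'   selection.
#' @param reps Number of repetitions averaged (default 100).
#' @param frac Probe sample fraction of the point count (default 0.1).
#' @param seed Integer seed.
#' @return Mean Hopkins statistic in `[0, 1]`.
#' @examples
#' cm <- generate_synthetic_contact_map(60, stems = list(c(5, 50, 6)), seed = 1)
#' hopkins_statistic(cm, seed = 1)
#' @export
hopkins_statistic <- function(x, L = NULL, min_sep = NULL, reps = 100L,
                              frac = 0.1, seed) {
  if (inherits(x, "contact_selection")) {
    pts <- x$chosen
    L <- x$parent$L
    min_sep <- x$parent$definition$min_sep
  } else if (inherits(x, "contact_map")) {
    pts <- x$contacts
    L <- x$L
    min_sep <- x$definition$min_sep
  } else {
    pts <- as.matrix(x)
    if (is.null(L)) stop("L is required for a bare point matrix")
    if (is.null(min_sep)) min_sep <- 4L
  }
  n <- nrow(pts)
  if (n < 2L) stop("Hopkins statistic needs at least 2 points")
  stopifnot(reps >= 1L, frac > 0, frac <= 1)
  m <- max(1L, as.integer(ceiling(frac * n)))
  rng <- local_rng(seed)
  pts <- matrix(as.numeric(pts), n, 2L)
  H <- numeric(reps)
  for (r in seq_len(reps)) {
    probes <- sample_triangle(rng, m, L, min_sep)
    ridx <- rng$sample(n, m)
    u <- nn_dist(probes, pts)
    w <- vapply(ridx, function(k) {
      d2 <- (pts[, 1L] - pts[k, 1L])^2 + (pts[, 2L] - pts[k, 2L])^2
      d2[k] <- Inf
      sqrt(min(d2))
    }, numeric(1))
    H[r] <- sum(u) / (sum(u) + sum(w))
  }
  mean(H)
}

# uniform points in the triangle {1 <= x, x + min_sep <= y <= L}
sample_triangle <- function(rng, m, L, min_sep) {
  a <- c(1, 1 + min_sep)
  b <- c(L - min_sep, L)
  cc <- c(1, L)
  u1 <- rng$runif(m)
  u2 <- rng$runif(m)
  refl <- u1 + u2 > 1
  u1[refl] <- 1 - u1[refl]
  u2[refl] <- 1 - u2[refl]
  cbind(a[1] + u1 * (b[1] - a[1]) + u2 * (cc[1] - a[1]),
        a[2] + u1 * (b[2] - a[2]) + u2 * (cc[2] - a[2]))
}

# nearest-neighbour distance from each row of q to the set p
nn_dist <- function(q, p) {
  vapply(seq_len(nrow(q)), function(k) {
    sqrt(min((p[, 1L] - q[k, 1L])^2 + (p[, 2L] - q[k, 2L])^2))
  }, numeric(1))
}
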