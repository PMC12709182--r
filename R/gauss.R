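#' Gaussian contact weights
#'
#' The dispersion weighting at the heart of the Gauss score.  Each contact
#' occupies a position \eqn{r_i = (i, j)} in the upper triangle of the
#' contact map.  A Gaussian kernel density is accumulated at each contact
#' from every contact in the set (including itself),
#' \deqn{\nu_i = \sum_{j \in C} \exp\!\left[-\|r_i - r_j\|^2 / \sigma^2\right],}
#' and inverted to give the weight \eqn{\omega_i = \nu_i^{-1} \in (0, 1]}.
#' Isolated contacts keep weight 1; contacts inside a dense cluster are
#' devalued.  The self-term \eqn{\exp(0) = 1} guarantees \eqn{\nu_i \ge 1}.
#'
#' @param cmap A [contact_map()] with at least one contact.
#' @param sigma2 Kernel variance \eqn{\sigma^2} in squared index units
#'   (default 4).
#' @return An object of class `contact_weights`: list with `nu`, `omega`
#'   (per contact, in the row order of `cmap$contacts`), `omega_total`
#'   (their sum, the Gauss score) and `sigma2`.
#' @examples
#' cm <- contact_map(20, rbind(c(2, 10), c(2, 12)))
#' gauss_weights(cm)$omega  # each ~0.731
#' @export
gauss_weights <- function(cmap, sigma2 = 4) {
  stopifnot(inherits(cmap, "contact_map"))
  if (!nrow(cmap$contacts)) stop("empty contact map: Gauss weights undefined")
  w <- gauss_weights_points(cmap$contacts, sigma2)
  structure(list(nu = w$nu, omega = w$omega, omega_total = w$omega_total,
                 sigma2 = sigma2), class = "contact_weights")
}

#' Gaussian weights of arbitrary points
#'
#' Kernel-sum/inverse weighting on real-valued positions; the integer-grid
#' version used for contact maps is the special case of integer `(i, j)`
#' cells.  Exposed so the closed forms (e.g. two points at distance d give
#' a total of \eqn{2/(1 + e^{-d^2/\sigma^2})}) can be evaluated off-grid.
#'
#' @param points Numeric matrix with one row per point (any dimension).
#' @param sigma2 Kernel variance.
#' @return List with `nu`, `omega` and `omega_total`.
#' @export
gauss_weights_points <- function(points, sigma2 = 4) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(nrow(points) >= 1L, is.numeric(sigma2), sigma2 > 0)
  K <- gauss_kernel_matrix(points, sigma2)
  nu <- rowSums(K)
  omega <- 1 / nu
  list(nu = nu, omega = omega, omega_total = sum(omega))
}

# pairwise kernel matrix exp(-||r_i - r_j||^2 / sigma2), unit diagonal
gauss_kernel_matrix <- function(points, sigma2) {
  sq <- rowSums(points^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(points)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' Gauss score of a contact map
#'
#' The Gauss score \eqn{\Omega = \sum_i \omega_i} summarizes how dispersed
#' a set of contacts is over the map: \eqn{\Omega} approaches the number of
#' contacts when all contacts are far apart (every \eqn{\omega_i \to 1})
#' and shrinks towards 1 as contacts collapse into a single tight cluster.
#' It always satisfies \eqn{1 \le \Omega \le |C|}.  The normalized variant
#' \eqn{\Omega / L} makes molecules of different size comparable.
#'
#' @inheritParams gauss_weights
#' @param normalized If `TRUE`, return \eqn{\Omega / L}.
#' @return A single numeric value.
#' @examples
#' cm <- contact_map(20, rbind(c(2, 10), c(2, 12)))
#' gauss_score(cm)            # 2 / (1 + exp(-1)) ~ 1.462
#' gauss_score(cm, normalized = TRUE)
#' @export
gauss_score <- function(cmap, sigma2 = 4, normalized = FALSE) {
  om <- gauss_weights(cmap, sigma2)$omega_total
  if (normalized) om / cmap$L else om
}

#' Soft Gauss score of a weighted contact map
#'
#' Continuous relaxation of [gauss_score()] for real-valued contact
#' probabilities in \eqn{[0, 1]}, as needed when the score enters the loss
#' function of a contact-prediction model.  Each upper-triangle cell
#' \eqn{p} with weight \eqn{w_p > 0} accumulates
#' \eqn{\nu(p) = \sum_q w_q \exp(-\|r_p - r_q\|^2/\sigma^2)} and the score
#' is \eqn{\sum_p w_p / \nu(p)}.  For a binary weight matrix this reduces
#' exactly to the Gauss score of the corresponding contact map.
#'
#' @param wmap Either an `L x L` numeric matrix (upper triangle used;
#'   entries in `[0, 1]`) or a data frame / 3-column matrix of
#'   `(i, j, w)` triplets.
#' @param sigma2 Kernel variance (default 4).
#' @param min_sep Cells with `j - i < min_sep` are ignored (set to 1 to
#'   keep everything above the diagonal).
#' @param format `"dense"` for an `L x L` matrix, `"triplets"` for
#'   `(i, j, w)` rows, or `"auto"` (dense iff square and not 3-column).
#' @return A single numeric value; 0 for an all-zero map.
#' @export
soft_gauss_score <- function(wmap, sigma2 = 4, min_sep = 1L,
                             format = c("auto", "dense", "triplets")) {
  format <- match.arg(format)
  if (is.data.frame(wmap)) wmap <- as.matrix(wmap)
  if (format == "auto")
    format <- if (nrow(wmap) == ncol(wmap) && ncol(wmap) != 3L)
      "dense" else "triplets"
  if (format == "dense") {
    if (nrow(wmap) != ncol(wmap)) stop("dense wmap must be square")
    idx <- which(upper.tri(wmap), arr.ind = TRUE)
    trip <- cbind(idx, w = wmap[idx])
  } else {
    trip <- wmap
    if (ncol(trip) != 3L) stop("triplet wmap needs columns (i, j, w)")
  }
  colnames(trip) <- c("i", "j", "w")
  trip <- trip[trip[, "j"] - trip[, "i"] >= min_sep, , drop = FALSE]
  w <- trip[, "w"]
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("weights must lie in [0, 1]")
  pos <- trip[w > 0, c("i", "j"), drop = FALSE]
  w <- w[w > 0]
  if (!length(w)) return(0)
  K <- gauss_kernel_matrix(pos, sigma2)
  nu <- as.vector(K %*% w)
  sum(w / nu)
}
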