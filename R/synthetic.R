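#' Generate a toy RNA-like structure
#'
#' Builds an idealized hairpin-and-loop geometry for testing: each helix
#' is a pair of antiparallel strands whose reference atoms sit 8.6 A
#' apart across the helix (inside the 9.5 A nitrogen contact threshold),
#' with a 5.9 A step between consecutive residues along a strand and
#' hairpin/linker loops connecting the strands.  Successive helices are
#' laid out far apart so no unintended inter-helix contacts arise.  Each
#' residue carries its N1/N9 reference atom, a C1' atom and a backbone P.
#' The designed base pairs are attached as the `pairing` attribute.  The
#' geometry is idealized, not physically realistic.
#'
#' @param n_helices Number of helices (0 gives an extended chain).
#' @param helix_len Base pairs per helix (recycled; each >= 1).
#' @param loop_len Residues in each hairpin loop (recycled; each >= 3 so
#'   designed pairs respect a minimum separation of 4).
#' @param linker_len Residues between consecutive helices.
#' @param n_loose Extra unpaired residues when `n_helices = 0`.
#' @param jitter Gaussian coordinate noise (A) added to every atom.
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return An [rna_structure()] with attribute `pairing` (2-column matrix
#'   of designed pairs, 1-based residue indices).
#' @examples
#' s <- generate_toy_structure(n_helices = 1, helix_len = 5, seed = 7)
#' attr(s, "pairing")
#' @export
generate_toy_structure <- function(n_helices = 1L, helix_len = 5L,
                                   loop_len = 3L, linker_len = 6L,
                                   n_loose = 20L, jitter = 0.05, seed) {
  n_helices <- as.integer(n_helices)
  if (n_helices < 0L) stop("n_helices must be >= 0")
  helix_len <- rep_len(as.integer(helix_len), max(1L, n_helices))
  loop_len <- rep_len(as.integer(loop_len), max(1L, n_helices))
  if (n_helices > 0L && any(helix_len < 1L)) stop("helix_len must be >= 1")
  if (n_helices > 0L && any(loop_len < 3L))
    stop("loop_len must be >= 3 so designed pairs clear the near-diagonal band")
  step <- 5.9   # along-strand reference-atom spacing
  width <- 8.6  # cross-strand reference-atom distance (< 9.5)
  rng <- local_rng(seed)
  coords <- NULL
  resname <- character()
  pairing <- matrix(integer(), ncol = 2L)
  x0 <- 0
  if (n_helices == 0L) {
    n <- max(2L, as.integer(n_loose))
    coords <- cbind(seq_len(n) * step, 0, 0)
    resname <- rep_len(c("A", "U", "G", "C"), n)
  } else {
    for (h in seq_len(n_helices)) {
      hl <- helix_len[h]
      ll <- loop_len[h]
      strand1 <- cbind(x0 + seq_len(hl) * step, 0, 0)
      # hairpin loop: arc from strand1 end to strand2 start across the helix
      theta <- seq(-pi / 2, pi / 2, length.out = ll + 2L)[2:(ll + 1L)]
      arc <- cbind(x0 + hl * step + (width / 2) * cos(theta),
                   width / 2 + (width / 2) * sin(theta), 0)
      strand2 <- cbind(x0 + rev(seq_len(hl)) * step, width, 0)
      i1 <- nrow_or0(coords) + seq_len(hl)
      i2 <- nrow_or0(coords) + hl + ll + rev(seq_len(hl))
      pairing <- rbind(pairing, cbind(i1, i2))
      seg <- rbind(strand1, arc, strand2)
      coords <- rbind(coords, seg)
      resname <- c(resname, rep_len(c("G", "C"), hl),
                   rep_len("U", ll), rep_len(c("C", "G"), hl))
      if (h < n_helices) { # linker to a far-away start for the next helix
        lk <- max(1L, as.integer(linker_len))
        coords <- rbind(coords, cbind(x0 + hl * step + width +
                                        seq_len(lk) * step, width, 0))
        resname <- c(resname, rep_len("A", lk))
        x0 <- max(coords[, 1L]) + 3 * step
      }
    }
  }
  n <- nrow(coords)
  if (jitter > 0) coords <- coords + matrix(rng$rnorm(3L * n, sd = jitter), n, 3L)
  ref <- reference_atom(resname)
  atoms <- data.frame(
    index = rep(seq_len(n), each = 3L),
    chain = "A",
    resno = rep(seq_len(n), each = 3L),
    resid = rep(resname, each = 3L),
    elety = as.vector(rbind(ref, "C1'", "P")),
    x = rep(coords[, 1L], each = 3L) + rep(c(0, 1.2, 2.4), n),
    y = rep(coords[, 2L], each = 3L) + rep(c(0, 0.8, 0.2), n),
    z = rep(coords[, 3L], each = 3L) + rep(c(0, 0.5, 1.4), n),
    hydrogen = FALSE, stringsAsFactors = FALSE)
  # place the reference atom exactly at the designed position
  out <- rna_structure(sprintf("toy-%d", seed), atoms)
  colnames(pairing) <- c("i", "j")
  attr(out, "pairing") <- pairing
  out
}

nrow_or0 <- function(m) if (is.null(m)) 0L else nrow(m)

#' Generate a synthetic contact map
#'
#' Plants the two canonical motifs of RNA contact maps: helices as
#' anti-diagonal runs (a stem starting at `(s_i, s_j)` of length `len`
#' contributes cells `(s_i + k, s_j - k)` for `k = 0..len-1`) and tertiary
#' patches as Bernoulli-filled discs around a centre cell.  All requested
#' cells must respect the `min_sep` triangle.
#'
#' @param L Sequence length.
#' @param stems List of `c(start_i, start_j, len)` triples.
#' @param patches List of `c(center_i, center_j, radius, density)`; cells
#'   within Euclidean `radius` of the centre are included independently
#'   with probability `density`.
#' @param min_sep Minimum separation of the map.
#' @param seed Integer seed (used by the patch Bernoulli draws).
#' @return A [contact_map()] with attributes `stem_cells` and
#'   `patch_cells` (ground truth for oracle tests).
#' @examples
#' cm <- generate_synthetic_contact_map(
#'   60, stems = list(c(5, 50, 6)), patches = list(c(15, 40, 2, 1)), seed = 1)
#' @export
generate_synthetic_contact_map <- function(L, stems = list(),
                                           patches = list(), min_sep = 4L,
                                           seed = 0L) {
  L <- as.integer(L)
  min_sep <- as.integer(min_sep)
  rng <- local_rng(seed)
  in_domain <- function(i, j) i >= 1L & j <= L & (j - i) >= min_sep
  stem_cells <- matrix(integer(), ncol = 2L)
  for (s in stems) {
    s <- as.integer(s)
    if (length(s) != 3L || s[3L] < 1L) stop("stem must be (start_i, start_j, len)")
    k <- seq_len(s[3L]) - 1L
    ci <- s[1L] + k
    cj <- s[2L] - k
    if (!all(in_domain(ci, cj)))
      stop(sprintf("stem (%d, %d, %d) leaves the min_sep=%d domain",
                   s[1L], s[2L], s[3L], min_sep))
    stem_cells <- rbind(stem_cells, cbind(ci, cj))
  }
  patch_cells <- matrix(integer(), ncol = 2L)
  for (p in patches) {
    if (length(p) != 4L) stop("patch must be (center_i, center_j, radius, density)")
    ci <- as.integer(p[1L]); cj <- as.integer(p[2L])
    rad <- p[3L]; dens <- p[4L]
    if (dens < 0 || dens > 1) stop("patch density must lie in [0, 1]")
    if (!in_domain(ci, cj))
      stop(sprintf("patch centre (%d, %d) outside the min_sep=%d domain",
                   ci, cj, min_sep))
    r <- as.integer(floor(rad))
    g <- expand.grid(i = (ci - r):(ci + r), j = (cj - r):(cj + r))
    g <- g[(g$i - ci)^2 + (g$j - cj)^2 <= rad^2, , drop = FALSE]
    g <- g[in_domain(g$i, g$j), , drop = FALSE]
    if (nrow(g)) {
      keep <- rng$runif(nrow(g)) < dens
      patch_cells <- rbind(patch_cells, as.matrix(g[keep, , drop = FALSE]))
    }
  }
  cm <- contact_map(L, rbind(stem_cells, patch_cells), min_sep = min_sep)
  attr(cm, "stem_cells") <- normalize_pairs(stem_cells)
  attr(cm, "patch_cells") <- if (nrow(patch_cells))
    normalize_pairs(patch_cells) else patch_cells
  cm
}

#' Generate a planted-cluster contact map
#'
#' Convenience wrapper producing maps with the clustered topology typical
#' of CNN contact predictors: a few stems plus dense tertiary patches,
#' randomly placed in the admissible triangle.  Used by the property and
#' acceptance suites.
#'
#' @param L Sequence length (default 100).
#' @param n_stems,n_patches Number of planted stems / patches.
#' @param min_sep Minimum separation.
#' @param seed Integer seed.
#' @return A [contact_map()].
#' @export
generate_planted_cluster_map <- function(L = 100L, n_stems = 2L,
                                         n_patches = 3L, min_sep = 4L,
                                         seed = 0L) {
  L <- as.integer(L)
  min_sep <- as.integer(min_sep)
  if (L < 4L * min_sep + 20L) stop("L too small for a planted-cluster map")
  rng <- local_rng(seed)
  stems <- patches <- list()
  for (k in seq_len(n_stems)) {
    len <- 4L + rng$sample(4L, 1L) # 5..8 bp
    si <- rng$sample(max(1L, L %/% 4L), 1L)
    lo <- si + 2L * (len - 1L) + min_sep # smallest in-domain stem start j
    if (lo > L) next
    sj <- lo + rng$sample(L - lo + 1L, 1L) - 1L
    stems <- c(stems, list(c(si, sj, len)))
  }
  for (k in seq_len(n_patches)) {
    ci <- rng$sample(L - min_sep - 4L, 1L)
    cj <- ci + min_sep + 4L + rng$sample(L - (ci + min_sep + 4L) + 1L, 1L) - 1L
    patches <- c(patches, list(c(ci, cj, 2.5, 0.9)))
  }
  generate_synthetic_contact_map(L, stems, patches, min_sep = min_sep,
                                 seed = seed + 1L)
}

#' Generate a synthetic RMSD table
#'
#' Emulates a folding benchmark: per molecule, the unrestrained RMSD is
#' drawn from a lognormal distribution (meanlog `log(15)`, sdlog 0.3 A,
#' typical of coarse-grained RNA folding) and the restrained RMSD improves
#' by `effect` A with probability `p`, otherwise worsens by the same
#' amount, floored at 0.
#'
#' @param n Number of molecules.
#' @param p Probability a molecule benefits from restraints.
#' @param L_range Integer range of sequence lengths, e.g. `c(41, 496)`.
#' @param effect Effect size in Angstrom.
#' @param seed Integer seed.
#' @return A data frame usable with [beneficial_fraction()].
#' @export
generate_rmsd_table <- function(n, p = 0.7, L_range = c(41L, 496L),
                                effect = 2, seed) {
  stopifnot(n >= 1, p >= 0, p <= 1, effect >= 0)
  rng <- local_rng(seed)
  L <- L_range[1L] +
    rng$sample(L_range[2L] - L_range[1L] + 1L, n, replace = TRUE) - 1L
  free <- rng$rlnorm(n, meanlog = log(15), sdlog = 0.3)
  gain <- rng$runif(n) < p
  restrained <- pmax(0, free + ifelse(gain, -effect, effect))
  data.frame(molecule = sprintf("mol%04d", seq_len(n)), L = L,
             rmsd_restrained = restrained, rmsd_free = free,
             stringsAsFactors = FALSE)
}
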