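#' Positive predictive value of a contact prediction
#'
#' Fraction of predicted contacts that are native:
#' \eqn{|P \cap N| / |P|}.  Both maps must share the same length and be
#' normalized to the same minimum separation.
#'
#' @param predicted A [contact_map()] or `contact_selection`.
#' @param native The native [contact_map()].
#' @return PPV in `[0, 1]`.
#' @examples
#' native <- contact_map(30, rbind(c(1, 10), c(2, 12), c(4, 20)))
#' pred <- contact_map(30, rbind(c(1, 10), c(2, 12), c(4, 20), c(6, 25)))
#' ppv(pred, native) # 0.75
#' @export
ppv <- function(predicted, native) {
  stopifnot(inherits(native, "contact_map"))
  pc <- if (inherits(predicted, "contact_selection")) predicted$chosen
        else if (inherits(predicted, "contact_map")) predicted$contacts
        else normalize_pairs(predicted)
  if (inherits(predicted, "contact_map") && predicted$L != native$L)
    stop("predicted and native maps have different L")
  if (!nrow(pc)) stop("PPV undefined for an empty prediction")
  hits <- paste(pc[, 1L], pc[, 2L]) %in%
    paste(native$contacts[, 1L], native$contacts[, 2L])
  sum(hits) / nrow(pc)
}

#' Error rate of a selection
#'
#' \eqn{\lambda = |C̄| / |C \cup C̄|}, the fraction of false contacts among
#' the chosen ones; equals `1 - ppv(selection, parent)` when the parent is
#' the native map.
#'
#' @param selection A `contact_selection`.
#' @return \eqn{\lambda} in `[0, 1)`.
#' @export
error_rate <- function(selection) {
  stopifnot(inherits(selection, "contact_selection"))
  if (!nrow(selection$chosen)) stop("empty selection")
  nrow(selection$false_set) / nrow(selection$chosen)
}

check_rmsd_table <- function(table) {
  need <- c("molecule", "L", "rmsd_restrained", "rmsd_free")
  if (!all(need %in% names(table)))
    stop("RMSD table needs columns ", paste(need, collapse = ", "))
  if (!nrow(table)) stop("empty RMSD table")
  if (anyDuplicated(table$molecule)) stop("duplicate molecule ids")
  if (any(table$rmsd_restrained < 0 | table$rmsd_free < 0))
    stop("RMSD values must be >= 0")
  table
}

#' Beneficial fraction of restrained folding
#'
#' \deqn{\xi = \frac{1}{|D|} \sum_d \Theta[\mathrm{RMSD}(d, \varnothing)
#'   - \mathrm{RMSD}(d, C \cup C̄)],}
#' the fraction of molecules whose restrained-folding RMSD is strictly
#' lower than the unrestrained one.  Ties are not a benefit
#' (\eqn{\Theta(0) = 0}).
#'
#' @param table Data frame with columns `molecule`, `L`,
#'   `rmsd_restrained`, `rmsd_free` (Angstrom).
#' @return \eqn{\xi} in `[0, 1]`.
#' @export
beneficial_fraction <- function(table) {
  table <- check_rmsd_table(table)
  mean(table$rmsd_restrained < table$rmsd_free)
}

#' Beneficial fraction split by molecule size
#'
#' Partitions the test set at a residue-count threshold into small
#' molecules (`L <= threshold`) and large ones, and reports \eqn{\xi} on
#' each group together with the group sizes.  An empty group yields an
#' `NA` (undefined) \eqn{\xi}, never 0.
#'
#' @inheritParams beneficial_fraction
#' @param threshold Residue-count threshold (common choices: 60, 75, 100,
#'   150).
#' @return List with `xi_small`, `xi_large`, `n_small`, `n_large`,
#'   `threshold`.
#' @export
partitioned_beneficial_fraction <- function(table, threshold) {
  table <- check_rmsd_table(table)
  stopifnot(is.numeric(threshold), threshold >= 1)
  small <- table[table$L <= threshold, , drop = FALSE]
  large <- table[table$L > threshold, , drop = FALSE]
  list(
    xi_small = if (nrow(small)) beneficial_fraction(small) else NA_real_,
    xi_large = if (nrow(large)) beneficial_fraction(large) else NA_real_,
    n_small = nrow(small), n_large = nrow(large), threshold = threshold)
}

#' Read / write RMSD tables as CSV
#'
#' @param source,table,sink CSV path / data frame / output path.
#' @return The validated data frame.
#' @export
read_rmsd_table <- function(source) {
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  check_rmsd_table(tab)
}

#' @rdname read_rmsd_table
#' @export
write_rmsd_table <- function(table, sink) {
  utils::write.csv(check_rmsd_table(table), sink, row.names = FALSE,
                   quote = FALSE)
  invisible(table)
}

# matched coordinate sets by (chain, resno, atom name); heavy atoms only
# unless policy says otherwise
matched_coords <- function(a, b, policy = c("heavy", "reference", "all")) {
  policy <- match.arg(policy)
  pick <- function(s) {
    at <- s$atoms
    if (policy == "heavy") at <- at[!at$hydrogen, , drop = FALSE]
    if (policy == "reference") {
      ref <- reference_atom(s$residues$resid)
      at <- at[at$elety == ref[at$index], , drop = FALSE]
    }
    at
  }
  aa <- pick(a)
  bb <- pick(b)
  ka <- paste(aa$chain, aa$resno, aa$elety)
  kb <- paste(bb$chain, bb$resno, bb$elety)
  m <- match(ka, kb)
  keep <- !is.na(m)
  list(x = cbind(aa$x, aa$y, aa$z)[keep, , drop = FALSE],
       y = cbind(bb$x, bb$y, bb$z)[m[keep], , drop = FALSE])
}

#' Root-mean-square deviation after optimal superposition
#'
#' Matches atoms of the two structures by chain, residue number and atom
#' name, superimposes them by the Kabsch least-squares rotation (SVD of
#' the cross-covariance of the centred coordinate sets, with the usual
#' determinant correction against reflections) and returns the RMSD in
#' Angstrom.
#'
#' @param a,b [rna_structure()] objects.
#' @param policy Atom set used for matching: all common heavy atoms
#'   (default), the N1/N9 reference atoms only, or all atoms.
#' @return RMSD in Angstrom (0 for congruent structures).
#' @export
rmsd <- function(a, b, policy = c("heavy", "reference", "all")) {
  mc <- matched_coords(a, b, policy)
  kabsch_rmsd(mc$x, mc$y)
}

#' Kabsch superposition RMSD of two coordinate matrices
#'
#' @param x,y `n x 3` matrices of paired coordinates, `n >= 3`.
#' @return RMSD after optimal rigid superposition.
#' @export
kabsch_rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("coordinate sets differ in size")
  if (nrow(x) < 3L) stop("need at least 3 matched atoms for superposition")
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((xc - yc %*% R)^2) / nrow(x))
}
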