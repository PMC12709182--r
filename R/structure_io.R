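#' @importFrom stats setNames
NULL

# residue names accepted as RNA, and modified-residue aliases.
# The table is editable via options(rnatopo.modified_residues = c(XXX = "A")).
.rna_standard <- c(A = "A", U = "U", C = "C", G = "G",
                   RA = "A", RU = "U", RC = "C", RG = "G",
                   ADE = "A", URA = "U", URI = "U", CYT = "C", GUA = "G")
.rna_modified <- c(PSU = "U", H2U = "U", "4SU" = "U", "5MU" = "U", OMU = "U",
                   "1MA" = "A", MA6 = "A", OMA = "A",
                   "5MC" = "C", OMC = "C",
                   "1MG" = "G", "2MG" = "G", "7MG" = "G", M2G = "G", OMG = "G")

resolve_base <- function(resid) {
  resid <- toupper(trimws(resid))
  tab <- c(.rna_standard, .rna_modified,
           unlist(getOption("rnatopo.modified_residues", NULL)))
  out <- unname(tab[resid])
  if (any(is.na(out)))
    stop(sprintf("unknown residue name '%s': not a standard nucleotide and not in the modified-residue table",
                 resid[which(is.na(out))[1L]]))
  out
}

#' Reference atom of a nucleotide
#'
#' Returns the glycosidic nitrogen used as the residue's reference point in
#' the nitrogen contact definition: N9 for purines (A, G), N1 for
#' pyrimidines (C, U).  Modified residue names are first mapped to their
#' parent base through a small editable table (extend it with
#' `options(rnatopo.modified_residues = c(XXX = "A"))`); unmapped names
#' raise an error rather than being skipped.
#'
#' @param resname Residue name(s), e.g. `"A"`, `"PSU"`.
#' @return `"N9"` or `"N1"` for each input.
#' @examples
#' reference_atom(c("A", "U", "PSU"))
#' @export
reference_atom <- function(resname) {
  base <- resolve_base(resname)
  ifelse(base %in% c("A", "G"), "N9", "N1")
}

is_rna_resid <- function(resid) {
  tab <- c(.rna_standard, .rna_modified,
           unlist(getOption("rnatopo.modified_residues", NULL)))
  toupper(trimws(resid)) %in% names(tab)
}

#' Read an RNA structure from PDB or mmCIF
#'
#' Parses a coordinate file (via bio3d), keeps RNA residues only, resolves
#' alternate locations to the highest-occupancy copy, flags (but retains)
#' hydrogens, and renumbers residues `1..L` in file order across chains.
#' Multi-model files are reduced to the first model.
#'
#' @param source Path to a `.pdb`/`.cif` file, or PDB-format text (any
#'   string containing a newline is treated as raw PDB text).
#' @param chain Optional chain identifier(s) to keep.
#' @param id Label for the structure; defaults to the file name.
#' @return An object of class `rna_structure`: a list with `id`, `L`,
#'   `residues` (data frame: `index`, `chain`, `resno`, `resid`) and
#'   `atoms` (data frame: `index`, `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`, `hydrogen`).
#' @export
read_pdb_structure <- function(source, chain = NULL, id = NULL) {
  path <- source
  if (length(source) != 1L || grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(source, path)
  } else if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  pdb <- tryCatch(
    if (grepl("\\.cif$", path, ignore.case = TRUE)) bio3d::read.cif(path)
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE),
    error = function(e) stop("unparseable structure file: ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  at <- at[is_rna_resid(at$resid), , drop = FALSE]
  at <- at[is.finite(at$x) & is.finite(at$y) & is.finite(at$z), , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no RNA residues found")
  # altloc: keep, per (residue, atom name), the highest-occupancy copy
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  pos <- seq_len(nrow(at))
  ord <- order(key, -occ, alt) # per atom: highest occupancy, then altloc label
  keep <- sort(pos[ord][!duplicated(key[ord])]) # back to file order
  at <- at[keep, , drop = FALSE]
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  index <- match(rkey, unique(rkey))
  hyd <- if ("elesy" %in% names(at) && !all(is.na(at$elesy)))
    toupper(trimws(at$elesy)) %in% c("H", "D")
  else grepl("^[0-9]*[HD]", trimws(at$elety))
  atoms <- data.frame(index = index, chain = at$chain, resno = at$resno,
                      resid = toupper(trimws(at$resid)), elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z, hydrogen = hyd,
                      stringsAsFactors = FALSE)
  residues <- atoms[!duplicated(atoms$index),
                    c("index", "chain", "resno", "resid")]
  rownames(atoms) <- rownames(residues) <- NULL
  if (is.null(id)) id <- if (grepl("\n", source[1]) || length(source) > 1)
    "structure" else sub("\\.(pdb|cif)$", "", basename(path), ignore.case = TRUE)
  structure(list(id = id, L = nrow(residues), residues = residues,
                 atoms = atoms), class = "rna_structure")
}

#' Construct an RNA structure from coordinates
#'
#' Low-level constructor used by the synthetic generators and by tests.
#'
#' @param id Text label.
#' @param atoms Data frame with columns `index` (1-based residue index,
#'   non-decreasing), `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`
#'   and optionally `hydrogen`.
#' @return An `rna_structure`.
#' @export
rna_structure <- function(id, atoms) {
  need <- c("index", "chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (is.unsorted(atoms$index)) stop("residue indices must be non-decreasing")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (is.null(atoms$hydrogen))
    atoms$hydrogen <- grepl("^[0-9]*[HD]", trimws(atoms$elety))
  residues <- atoms[!duplicated(atoms$index),
                    c("index", "chain", "resno", "resid")]
  if (!identical(residues$index, seq_len(nrow(residues))))
    stop("residue indices must run 1..L without gaps")
  rownames(residues) <- NULL
  structure(list(id = id, L = nrow(residues), residues = residues,
                 atoms = atoms), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA structure '%s': L=%d residues, %d atoms, chains: %s\n",
              x$id, x$L, nrow(x$atoms),
              paste(unique(x$residues$chain), collapse = ",")))
  invisible(x)
}

# L x 3 matrix of reference-atom (N1/N9) coordinates; errors on missing atoms
reference_coords <- function(structure) {
  ref <- reference_atom(structure$residues$resid)
  out <- matrix(NA_real_, structure$L, 3L)
  key <- paste(structure$atoms$index, structure$atoms$elety)
  m <- match(paste(seq_len(structure$L), ref), key)
  if (anyNA(m)) {
    k <- which(is.na(m))[1L]
    stop(sprintf("missing reference atom %s in residue %d (%s %s%s)",
                 ref[k], k, structure$residues$resid[k],
                 structure$residues$chain[k], structure$residues$resno[k]))
  }
  out[, 1L] <- structure$atoms$x[m]
  out[, 2L] <- structure$atoms$y[m]
  out[, 3L] <- structure$atoms$z[m]
  out
}

#' Extract a contact map from a 3D structure
#'
#' Applies a [contact_definition()] to an [rna_structure()]: in nitrogen
#' mode residues are in contact when their N1/N9 reference atoms are within
#' the threshold (inclusive by default); in heavy mode when the minimum
#' distance over all non-hydrogen atom pairs is under the threshold
#' (strict by default).  Pairs with sequence separation below `min_sep`
#' are excluded.
#'
#' @param structure An [rna_structure()].
#' @param definition A [contact_definition()]; default nitrogen/9.5 A.
#' @return A [contact_map()].
#' @examples
#' s <- generate_toy_structure(n_helices = 1, helix_len = 5, seed = 1)
#' extract_contact_map(s)
#' @export
extract_contact_map <- function(structure, definition = contact_definition()) {
  stopifnot(inherits(structure, "rna_structure"),
            inherits(definition, "contact_definition"))
  L <- structure$L
  cmp <- if (isTRUE(definition$inclusive)) `<=` else `<`
  if (definition$mode == "nitrogen") {
    xyz <- reference_coords(structure)
    D <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(D), arr.ind = TRUE)
    keep <- idx[, 2L] - idx[, 1L] >= definition$min_sep &
      cmp(D[idx], definition$threshold)
    pairs <- idx[keep, , drop = FALSE]
  } else {
    at <- structure$atoms[!structure$atoms$hydrogen, , drop = FALSE]
    if (!all(seq_len(L) %in% at$index))
      stop("residue without heavy atoms present")
    xyz <- cbind(at$x, at$y, at$z)
    ridx <- at$index
    # candidate residue pairs: bound min atom-atom distance by reference/first
    # atom distance minus per-residue radius to avoid the full atom cross-dist
    cen <- rowsum(xyz, ridx) / as.vector(table(ridx))
    rad <- vapply(split(seq_along(ridx), ridx), function(k) {
      max(sqrt(rowSums((xyz[k, , drop = FALSE] -
                          matrix(cen[as.character(ridx[k[1]]), ],
                                 length(k), 3, byrow = TRUE))^2)))
    }, numeric(1))
    Dc <- as.matrix(stats::dist(cen))
    idx <- which(upper.tri(Dc), arr.ind = TRUE)
    cand <- idx[idx[, 2L] - idx[, 1L] >= definition$min_sep &
                  Dc[idx] - rad[idx[, 1L]] - rad[idx[, 2L]] <=
                    definition$threshold, , drop = FALSE]
    hit <- logical(nrow(cand))
    byres <- split(seq_along(ridx), ridx)
    for (k in seq_len(nrow(cand))) {
      a <- xyz[byres[[cand[k, 1L]]], , drop = FALSE]
      b <- xyz[byres[[cand[k, 2L]]], , drop = FALSE]
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      hit[k] <- cmp(sqrt(max(0, min(d2))), definition$threshold)
    }
    pairs <- cand[hit, , drop = FALSE]
  }
  contact_map(L, pairs, definition)
}

#' Write an RNA structure as PDB
#'
#' Emits ATOM records (via bio3d) for the structure's atoms, one chain and
#' author numbering as stored.  Used by the fixture generator; not a
#' general-purpose deposition writer.
#'
#' @param structure An [rna_structure()].
#' @param sink Output path.
#' @return Invisibly, `sink`.
#' @export
write_structure_pdb <- function(structure, sink) {
  at <- structure$atoms
  bio3d::write.pdb(file = sink,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, eleno = seq_len(nrow(at)))
  invisible(sink)
}
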