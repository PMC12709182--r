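#' Build distance restraints from a contact selection
#'
#' Converts each selected contact into a distance-restraint record between
#' the N1/N9 reference atoms of the two residues.  Only the sequence is
#' needed to resolve atom names; coordinates are not required.  The upper
#' bound defaults to the contact-definition threshold of the parent map
#' (9.5 A nitrogen / 10 A heavy) and the penalty profile is flat-bottom
#' with a capped cost, recorded as metadata: zero cost up to the upper
#' bound, rising beyond it, constant above `cap` so a single unfulfilled
#' restraint cannot dominate the energy.
#'
#' @param selection A `contact_selection`.
#' @param context An [rna_structure()] or a character vector of residue
#'   names (length L of the parent map); supplies residue identities and,
#'   for structures, chain ids and author residue numbers.
#' @param upper Upper bound in Angstrom; default from the parent map's
#'   definition, falling back to 9.5.
#' @param lower Lower bound in Angstrom (default 0).
#' @param weight Restraint weight (default 1).
#' @param cap Distance beyond which the penalty stays constant (default
#'   `upper + 10`).
#' @return An object of class `restraint_set`: a data frame of records
#'   (`chain_a`, `pos_a`, `atom_a`, `chain_b`, `pos_b`, `atom_b`, `lower`,
#'   `upper`, `weight`) sorted by `(pos_a, pos_b)`, with the penalty
#'   profile in attributes.
#' @examples
#' cm <- contact_map(12, rbind(c(1, 10), c(2, 12)))
#' sel <- select_random(cm, 2, seed = 1)
#' build_restraint_set(sel, strsplit("GGCAUCCGAUCC", "")[[1]])
#' @export
build_restraint_set <- function(selection, context, upper = NULL, lower = 0,
                                weight = 1, cap = NULL) {
  stopifnot(inherits(selection, "contact_selection"))
  L <- selection$parent$L
  if (inherits(context, "rna_structure")) {
    if (context$L != L) stop("structure length differs from the contact map")
    resid <- context$residues$resid
    chain <- context$residues$chain
    resno <- context$residues$resno
  } else {
    context <- as.character(context)
    if (length(context) == 1L && nchar(context) > 1L)
      context <- strsplit(context, "")[[1L]]
    if (length(context) != L) stop("sequence length differs from the contact map")
    resid <- context
    chain <- rep("A", L)
    resno <- seq_len(L)
  }
  if (is.null(upper)) {
    upper <- selection$parent$definition$threshold
    if (is.na(upper)) upper <- 9.5
  }
  if (is.null(cap)) cap <- upper + 10
  if (!(lower >= 0 && lower < upper)) stop("need 0 <= lower < upper")
  cc <- selection$chosen
  atom <- reference_atom(resid) # errors name the unresolvable residue
  rec <- data.frame(
    chain_a = chain[cc[, 1L]], pos_a = resno[cc[, 1L]], atom_a = atom[cc[, 1L]],
    chain_b = chain[cc[, 2L]], pos_b = resno[cc[, 2L]], atom_b = atom[cc[, 2L]],
    lower = lower, upper = upper, weight = weight,
    stringsAsFactors = FALSE)[order(cc[, 1L], cc[, 2L]), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, class = c("restraint_set", "data.frame"),
            penalty = list(profile = "flat-bottom-capped", cap = cap),
            scheme = selection$scheme, seed = selection$seed,
            lambda = selection$lambda)
}

#' Write SimRNA-style restraint files
#'
#' One whitespace-separated line per restraint: chain, position and atom
#' for each partner, then lower bound, upper bound and weight.  Header
#' comments record the dialect, the flat-bottom penalty cap and selection
#' provenance; ordering is deterministic (by `pos_a`, `pos_b`), so output
#' is byte-stable for fixed input.
#'
#' @param rset A `restraint_set` from [build_restraint_set()].
#' @param sink Output path or `NULL`.
#' @param dialect Format dialect tag; `"generic"` is the documented
#'   column format above.
#' @return Invisibly, the lines written.
#' @export
write_simrna_restraints <- function(rset, sink = NULL, dialect = "generic") {
  stopifnot(inherits(rset, "restraint_set"))
  pen <- attr(rset, "penalty")
  ord <- order(rset$pos_a, rset$pos_b)
  r <- rset[ord, , drop = FALSE]
  lines <- c(
    sprintf("# dialect=%s", dialect),
    sprintf("# penalty=%s cap=%s", pen$profile, format(pen$cap)),
    sprintf("# scheme=%s seed=%s lambda=%.10g",
            attr(rset, "scheme"), format(attr(rset, "seed")),
            attr(rset, "lambda")),
    if (nrow(r))
      sprintf("%s %d %s %s %d %s %s %s %s",
              r$chain_a, r$pos_a, r$atom_a, r$chain_b, r$pos_b, r$atom_b,
              format(r$lower), format(r$upper), format(r$weight)))
  if (!is.null(sink)) writeLines(lines, sink)
  invisible(lines)
}

#' Read a SimRNA-style restraint file
#'
#' Inverse of [write_simrna_restraints()] for the generic dialect.
#'
#' @param source Path or character lines.
#' @return A `restraint_set`.
#' @export
read_simrna_restraints <- function(source) {
  lines <- read_source_lines(source)
  hdr <- parse_header_meta(lines)
  body <- lines[grep("^\\s*(#|$)", lines, invert = TRUE)]
  tok <- strsplit(trimws(body), "\\s+")
  if (any(lengths(tok) != 9L)) stop("malformed restraint record")
  g <- function(k) vapply(tok, `[[`, "", k)
  rec <- data.frame(
    chain_a = g(1), pos_a = as.integer(g(2)), atom_a = g(3),
    chain_b = g(4), pos_b = as.integer(g(5)), atom_b = g(6),
    lower = as.numeric(g(7)), upper = as.numeric(g(8)),
    weight = as.numeric(g(9)), stringsAsFactors = FALSE)
  structure(rec, class = c("restraint_set", "data.frame"),
            penalty = list(profile = "flat-bottom-capped",
                           cap = as.numeric(hdr$cap)),
            scheme = if (is.null(hdr$scheme)) NA_character_ else hdr$scheme,
            seed = if (is.null(hdr$seed)) NA_integer_ else as.integer(hdr$seed),
            lambda = if (is.null(hdr$lambda)) NA_real_ else as.numeric(hdr$lambda))
}
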