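#' Contact definition
#'
#' Describes how residue-residue contacts are called from 3D coordinates.
#' Two conventions are supported: `"nitrogen"` calls a contact when the
#' glycosidic nitrogen atoms (N9 for purines A/G, N1 for pyrimidines C/U)
#' are within 9.5 Angstrom (inclusive); `"heavy"` when the closest pair of
#' non-hydrogen atoms of the two residues is under 10 Angstrom (strict).
#' Pairs closer than `min_sep` along the sequence are never counted, which
#' removes the trivial near-diagonal band of a contact map.
#'
#' @param mode `"nitrogen"` or `"heavy"`.
#' @param threshold Distance threshold in Angstrom. Defaults to 9.5 for
#'   nitrogen mode and 10 for heavy mode.
#' @param min_sep Minimum sequence separation `|i - j|` for a pair to count.
#' @param inclusive Whether the threshold comparison is `<=` (default for
#'   nitrogen mode) or `<` (default for heavy mode).
#' @return An object of class `contact_definition`.
#' @examples
#' contact_definition("nitrogen")
#' contact_definition("heavy", threshold = 8)
#' @export
contact_definition <- function(mode = c("nitrogen", "heavy"), threshold = NULL,
                               min_sep = 4L, inclusive = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "nitrogen") 9.5 else 10
  if (is.null(inclusive)) inclusive <- (mode == "nitrogen")
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  min_sep <- as.integer(min_sep)
  if (is.na(min_sep) || min_sep < 1L) stop("min_sep must be >= 1")
  structure(list(mode = mode, threshold = threshold, min_sep = min_sep,
                 inclusive = inclusive),
            class = "contact_definition")
}

external_definition <- function(min_sep = 4L) {
  structure(list(mode = "external", threshold = NA_real_,
                 min_sep = as.integer(min_sep), inclusive = NA),
            class = "contact_definition")
}

#' @export
print.contact_definition <- function(x, ...) {
  cat(sprintf("Contact definition: mode=%s threshold=%s min_sep=%d\n",
              x$mode, format(x$threshold), x$min_sep))
  invisible(x)
}

#' Contact map
#'
#' A binary symmetric relation on residue indices `1..L` marking pairs in
#' spatial contact.  Only the upper-triangle representative `(i, j)` with
#' `i < j` is stored; pairs are deduplicated and sorted lexicographically.
#'
#' @param L Residue count (sequence length).
#' @param contacts Two-column integer matrix (or data frame) of residue
#'   index pairs, 1-based.  Order within a pair is irrelevant.
#' @param definition A [contact_definition()], or `NULL` for contacts of
#'   external origin (e.g. a coevolution predictor), in which case only
#'   `min_sep` is recorded.
#' @param min_sep Minimum separation used when `definition` is `NULL`.
#' @return An object of class `contact_map` with fields `L`, `contacts`
#'   (sorted upper-triangle matrix) and `definition`.
#' @examples
#' cm <- contact_map(20, rbind(c(1, 10), c(12, 2)))
#' cm$contacts
#' @export
contact_map <- function(L, contacts, definition = NULL, min_sep = 4L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be >= 1")
  if (is.null(definition)) definition <- external_definition(min_sep)
  if (!inherits(definition, "contact_definition"))
    stop("definition must be a contact_definition")
  contacts <- normalize_pairs(contacts)
  if (nrow(contacts)) {
    bad <- contacts[, 1L] < 1L | contacts[, 2L] > L
    if (any(bad))
      stop(sprintf("contact indices out of [1, %d]: e.g. (%d, %d)", L,
                   contacts[which(bad)[1L], 1L], contacts[which(bad)[1L], 2L]))
    sep <- contacts[, 2L] - contacts[, 1L]
    if (any(sep < definition$min_sep))
      stop(sprintf("pair closer than min_sep=%d present", definition$min_sep))
  }
  structure(list(L = L, contacts = contacts, definition = definition),
            class = "contact_map")
}

# i<j normalization, dedup, lexicographic sort; returns 0-row matrix if empty
normalize_pairs <- function(contacts) {
  if (is.data.frame(contacts)) contacts <- as.matrix(contacts)
  if (is.null(contacts) || length(contacts) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  if (is.vector(contacts)) contacts <- matrix(contacts, ncol = 2L, byrow = TRUE)
  storage.mode(contacts) <- "integer"
  if (ncol(contacts) < 2L) stop("contacts need two index columns")
  contacts <- contacts[, 1:2, drop = FALSE]
  if (any(!is.finite(contacts))) stop("non-finite contact index")
  if (any(contacts[, 1L] == contacts[, 2L])) stop("self-pair i == j not allowed")
  swap <- contacts[, 1L] > contacts[, 2L]
  contacts[swap, ] <- contacts[swap, c(2L, 1L), drop = FALSE]
  contacts <- unique(contacts)
  contacts <- contacts[order(contacts[, 1L], contacts[, 2L]), , drop = FALSE]
  colnames(contacts) <- c("i", "j")
  contacts
}

n_contacts <- function(cmap) nrow(cmap$contacts)

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: L=%d, %d contacts (%s, min_sep=%d)\n",
              x$L, nrow(x$contacts), x$definition$mode, x$definition$min_sep))
  invisible(x)
}

#' Read a plain-text contact table
#'
#' Parses DCA-style contact tables: one pair per line as `i j` or
#' `i j score`, whitespace-separated, 1-based indices, `#` comments.
#' Header comments of the form `# key=value` written by
#' [write_contact_table()] restore `L` and the contact definition.
#'
#' @param source Path to the file, or a character vector of lines.
#' @param L Sequence length; required unless present in a header comment
#'   (falls back to `max(j)` with a warning).
#' @param min_sep Minimum separation recorded when no header states one.
#' @return A [contact_map()].  Scores, when present, are attached as the
#'   `scores` attribute of the contact matrix in file order of the kept pairs.
#' @export
read_contact_table <- function(source, L = NULL, min_sep = 4L) {
  lines <- read_source_lines(source)
  hdr <- parse_header_meta(lines)
  body <- grep("^\\s*(#|$)", lines, invert = TRUE)
  if (!is.null(hdr$L)) L <- as.integer(hdr$L)
  if (!is.null(hdr$min_sep)) min_sep <- as.integer(hdr$min_sep)
  def <- if (!is.null(hdr$mode) && hdr$mode %in% c("nitrogen", "heavy")) {
    contact_definition(hdr$mode, threshold = as.numeric(hdr$threshold),
                       min_sep = min_sep)
  } else external_definition(min_sep)
  if (!length(body)) {
    if (is.null(L)) stop("empty table and no L given")
    return(contact_map(L, NULL, def))
  }
  rec <- lapply(body, function(ln) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 2L)
      stop(sprintf("malformed record at line %d: '%s'", ln, lines[ln]))
    i <- suppressWarnings(as.integer(tok[1L]))
    j <- suppressWarnings(as.integer(tok[2L]))
    if (is.na(i) || is.na(j))
      stop(sprintf("malformed record at line %d: non-integer index", ln))
    if (i == j)
      stop(sprintf("malformed record at line %d: i == j", ln))
    s <- if (length(tok) >= 3L) suppressWarnings(as.numeric(tok[3L])) else NA_real_
    list(i = i, j = j, s = s, ln = ln)
  })
  ii <- vapply(rec, `[[`, integer(1), "i")
  jj <- vapply(rec, `[[`, integer(1), "j")
  if (is.null(L)) {
    L <- max(jj, ii)
    warning("no L given or in header; using max index ", L)
  }
  oob <- ii < 1L | jj < 1L | ii > L | jj > L
  if (any(oob)) {
    k <- which(oob)[1L]
    stop(sprintf("malformed record at line %d: index out of [1, %d]",
                 rec[[k]]$ln, L))
  }
  cm <- contact_map(L, cbind(ii, jj), def)
  sc <- vapply(rec, `[[`, numeric(1), "s")
  if (any(!is.na(sc))) {
    key <- paste(pmin(ii, jj), pmax(ii, jj))
    keep <- !duplicated(key)
    m <- match(paste(cm$contacts[, 1L], cm$contacts[, 2L]), key[keep])
    attr(cm$contacts, "scores") <- sc[keep][m]
  }
  cm
}

#' Write a contact map as a plain-text table
#'
#' Emits the upper-triangle pairs, one per line, preceded by `# key=value`
#' header comments recording `L`, the definition mode, threshold and
#' `min_sep`, so that [read_contact_table()] round-trips exactly.
#'
#' @param cmap A [contact_map()].
#' @param sink Output path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_contact_table <- function(cmap, sink = NULL) {
  stopifnot(inherits(cmap, "contact_map"))
  d <- cmap$definition
  lines <- c(
    sprintf("# L=%d", cmap$L),
    sprintf("# mode=%s", d$mode),
    if (!is.na(d$threshold)) sprintf("# threshold=%s", format(d$threshold)),
    sprintf("# min_sep=%d", d$min_sep),
    if (nrow(cmap$contacts))
      sprintf("%d %d", cmap$contacts[, 1L], cmap$contacts[, 2L]))
  if (!is.null(sink)) writeLines(lines, sink)
  invisible(lines)
}

read_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE))
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

parse_header_meta <- function(lines) {
  h <- grep("^\\s*#", lines, value = TRUE)
  kv <- unlist(regmatches(h, gregexpr("[A-Za-z_0-9]+\\s*=\\s*\\S+", h)))
  if (!length(kv)) return(list())
  parts <- strsplit(kv, "\\s*=\\s*")
  stats::setNames(lapply(parts, `[[`, 2L), vapply(parts, `[[`, "", 1L))
}

# all index pairs (i, j), i < j, j - i >= min_sep, as a 2-col matrix
domain_pairs <- function(L, min_sep) {
  if (L <= min_sep) return(matrix(integer(), ncol = 2L))
  i <- sequence(seq_len(L - min_sep))
  j <- rep(seq.int(min_sep + 1L, L), seq_len(L - min_sep)) # j fixed, i = 1..j-min_sep
  cbind(i = i, j = j)
}
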