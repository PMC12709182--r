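#' Contact clusters on the map
#'
#' Partitions the contacts of a map into clusters: two contacts belong to
#' the same cluster when a path of pixel-adjacent contacts connects them.
#' Adjacency is 8-connectivity by default (horizontal, vertical and
#' diagonal neighbours on the upper-triangle pixel grid); 4-connectivity
#' drops the diagonals.  Clusters are returned sorted by size descending,
#' ties broken by the lexicographically smallest member cell.
#'
#' @param cmap A [contact_map()].
#' @param connectivity 8 (default) or 4.
#' @return An object of class `cluster_partition`: list with `clusters`
#'   (list of 2-column matrices, each sorted), `sizes` and `connectivity`.
#' @examples
#' cm <- contact_map(30, rbind(c(1, 10), c(1, 11), c(2, 10), c(5, 20)))
#' find_clusters(cm)$sizes
#' @export
find_clusters <- function(cmap, connectivity = 8L) {
  stopifnot(inherits(cmap, "contact_map"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  cc <- cmap$contacts
  n <- nrow(cc)
  if (!n)
    return(structure(list(clusters = list(), sizes = integer(),
                          connectivity = connectivity),
                     class = "cluster_partition"))
  # union-find over contact cells; neighbours found via a cell hash
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  key <- cc[, 1L] * (cmap$L + 2L) + cc[, 2L]
  lut <- stats::setNames(seq_len(n), key)
  offs <- if (connectivity == 8L)
    cbind(di = c(0L, 1L, 1L, 1L), dj = c(1L, -1L, 0L, 1L))
  else cbind(di = c(0L, 1L), dj = c(1L, 0L))
  for (o in seq_len(nrow(offs))) {
    nk <- (cc[, 1L] + offs[o, 1L]) * (cmap$L + 2L) + (cc[, 2L] + offs[o, 2L])
    nb <- lut[as.character(nk)]
    hit <- which(!is.na(nb))
    for (a in hit) {
      ra <- find(a); rb <- find(nb[[a]])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  clusters <- lapply(groups, function(ix) cc[ix, , drop = FALSE])
  sizes <- lengths(groups)
  # descending size; ties by smallest (i, j) of the cluster
  first_i <- vapply(clusters, function(m) m[1L, 1L], integer(1))
  first_j <- vapply(clusters, function(m) m[1L, 2L], integer(1))
  ord <- order(-sizes, first_i, first_j)
  structure(list(clusters = unname(clusters[ord]),
                 sizes = unname(sizes[ord]),
                 connectivity = connectivity),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Cluster partition: %d clusters (%d-connectivity); sizes: %s\n",
              length(x$clusters), x$connectivity,
              paste(utils::head(x$sizes, 10L), collapse = " ")))
  invisible(x)
}
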