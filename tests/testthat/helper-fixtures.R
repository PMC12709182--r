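# Handcrafted fixtures and independent oracles used across the suite.

# one PDB ATOM record, fixed-width columns
pdb_atom <- function(serial, name, res, chain, resno, x, y, z,
                     occ = 1, alt = "", element = substr(trimws(name), 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          serial, name, alt, res, chain, resno, x, y, z, occ, 0, element)
}

# minimal two-residue PDB text
two_residue_pdb <- function() {
  paste(c(pdb_atom(1, " N9", "G", "A", 1, 0, 0, 0),
          pdb_atom(2, " C1'", "G", "A", 1, 1.2, 0.8, 0.5),
          pdb_atom(3, " N1", "C", "A", 2, 5, 0, 0),
          "END"), collapse = "\n")
}

# n residues, reference atoms collinear on the x axis at `spacing` Angstrom
collinear_pdb <- function(n = 6, spacing = 1.8) {
  res <- rep_len(c("G", "C"), n)
  atom <- ifelse(res == "G", " N9", " N1")
  paste(c(vapply(seq_len(n), function(k) {
    pdb_atom(k, atom[k], res[k], "A", k, (k - 1) * spacing, 0, 0)
  }, ""), "END"), collapse = "\n")
}

# quaternion (Horn) superposition RMSD: independent of the SVD route
quaternion_rmsd <- function(x, y) {
  x <- scale(as.matrix(x), scale = FALSE)
  y <- scale(as.matrix(y), scale = FALSE)
  S <- crossprod(x, y) # S[a, b] = sum_k x_ka y_kb
  N <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(x^2) + sum(y^2) - 2 * lam
  sqrt(max(0, e2) / nrow(x))
}

# Gauss score of an explicit contact set, straight from the definition
omega_direct <- function(pairs, sigma2 = 4) {
  pairs <- matrix(as.numeric(pairs), ncol = 2)
  n <- nrow(pairs)
  nu <- vapply(seq_len(n), function(i) {
    sum(exp(-((pairs[i, 1] - pairs[, 1])^2 +
                (pairs[i, 2] - pairs[, 2])^2) / sigma2))
  }, numeric(1))
  sum(1 / nu)
}

# best Omega over all n-subsets by full enumeration
omega_exhaustive_best <- function(pairs, n, sigma2 = 4) {
  idx <- utils::combn(nrow(pairs), n)
  best <- -Inf
  for (k in seq_len(ncol(idx))) {
    om <- omega_direct(pairs[idx[, k], , drop = FALSE], sigma2)
    if (om > best) best <- om
  }
  best
}

# connected components via igraph: the independent clustering oracle
igraph_clusters <- function(cmap, connectivity = 8) {
  cc <- cmap$contacts
  n <- nrow(cc)
  if (!n) return(integer())
  D_i <- abs(outer(cc[, 1], cc[, 1], "-"))
  D_j <- abs(outer(cc[, 2], cc[, 2], "-"))
  adj <- if (connectivity == 8) (D_i <= 1 & D_j <= 1) else (D_i + D_j <= 1)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  sort(as.integer(table(memb)), decreasing = TRUE)
}

# a well-separated two-cluster map: one stem run and one dense patch
two_cluster_map <- function(L = 80) {
  generate_synthetic_contact_map(
    L, stems = list(c(5, 70, 8)), patches = list(c(30, 60, 2.5, 1)),
    seed = 424242)
}

random_contact_map <- function(L, n, min_sep = 4, seed) {
  dom <- rnatopo:::domain_pairs(L, min_sep)
  set.seed(seed)
  contact_map(L, dom[sample.int(nrow(dom), n), , drop = FALSE],
              min_sep = min_sep)
}

cli_path <- function() system.file("cli", "rnatopo.R", package = "rnatopo")

run_cli <- function(...) {
  out <- suppressWarnings(system2("Rscript", c(cli_path(), ...),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  list(stdout = out, status = if (is.null(status)) 0L else status)
}

normalize_pairs_for_test <- function(m) {
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("i", "j")
  rownames(m) <- NULL
  m
}
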