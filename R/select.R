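#' Contact selections
#'
#' A selection is a chosen subset of contacts, tagged with the scheme that
#' produced it, the partition into true contacts (present in the parent
#' native map) and injected false contacts, the seed, and the realized
#' error rate \eqn{\lambda = |C̄| / |C \cup C̄|}.
#'
#' @name contact_selection
#' @keywords internal
NULL

new_selection <- function(parent, true_set, false_set, scheme, seed,
                          sigma2 = NA_real_) {
  true_set <- normalize_pairs(true_set)
  false_set <- normalize_pairs(false_set)
  chosen <- normalize_pairs(rbind(true_set, false_set))
  lambda <- if (nrow(chosen)) nrow(false_set) / nrow(chosen) else 0
  structure(list(parent = parent, chosen = chosen, scheme = scheme,
                 true_set = true_set, false_set = false_set,
                 seed = seed, lambda = lambda, sigma2 = sigma2),
            class = "contact_selection")
}

#' @export
print.contact_selection <- function(x, ...) {
  cat(sprintf(
    "Contact selection: %d contacts (scheme=%s, seed=%s, lambda=%.4g)\n",
    nrow(x$chosen), x$scheme, format(x$seed), x$lambda))
  invisible(x)
}

check_selection_n <- function(cmap, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (n > nrow(cmap$contacts))
    stop(sprintf("requested %d contacts but the map has only %d",
                 n, nrow(cmap$contacts)))
  n
}

#' Default selection size L/2
#'
#' The standard restraint budget is half the sequence length, floored for
#' odd L and capped at the number of available contacts.
#'
#' @param cmap A [contact_map()].
#' @return An integer count.
#' @export
default_selection_size <- function(cmap) {
  min(nrow(cmap$contacts), max(1L, cmap$L %/% 2L))
}

#' Clustered contact selection
#'
#' Emulates the topology of cluster-prone contact predictors: contacts are
#' drawn at random from the largest cluster until it is exhausted, then
#' from the next cluster in descending-size order, and so on until `n`
#' contacts are selected.
#'
#' @param cmap A [contact_map()].
#' @param n Number of contacts to select (default `floor(L/2)`, capped at
#'   the map size).
#' @param seed Integer seed; all randomness flows from it.
#' @param connectivity Pixel adjacency for the cluster partition (8 or 4).
#' @return A `contact_selection` with `lambda = 0`.
#' @export
select_clustered <- function(cmap, n = default_selection_size(cmap), seed,
                             connectivity = 8L) {
  n <- check_selection_n(cmap, n)
  part <- find_clusters(cmap, connectivity)
  rng <- local_rng(seed)
  picked <- matrix(integer(), ncol = 2L)
  for (cl in part$clusters) {
    if (nrow(picked) >= n) break
    take <- min(n - nrow(picked), nrow(cl))
    idx <- if (take == nrow(cl)) seq_len(nrow(cl))
           else rng$sample(nrow(cl), take)
    picked <- rbind(picked, cl[idx, , drop = FALSE])
  }
  new_selection(cmap, picked, NULL, "clustered", seed)
}

#' Random contact selection
#'
#' Uniform sample of `n` contacts without replacement from the whole map;
#' the dispersed extreme against which clustered topologies are compared.
#'
#' @inheritParams select_clustered
#' @return A `contact_selection` with `lambda = 0`.
#' @export
select_random <- function(cmap, n = default_selection_size(cmap), seed) {
  n <- check_selection_n(cmap, n)
  rng <- local_rng(seed)
  idx <- rng$sample(nrow(cmap$contacts), n)
  new_selection(cmap, cmap$contacts[idx, , drop = FALSE], NULL, "random", seed)
}

#' Gaussian-optimized contact selection
#'
#' Selects `n` contacts maximizing the Gauss score of the subset: a greedy
#' construction (seeded with the pair of contacts at maximal index
#' distance, then repeatedly adding the contact that maximizes the score
#' of the augmented set) followed by single-swap hill climbing until no
#' exchange of one chosen contact for one unchosen contact increases the
#' score.  The result is therefore single-swap locally optimal; ties are
#' broken lexicographically, so the procedure is deterministic.
#'
#' @inheritParams select_clustered
#' @param sigma2 Kernel variance of the Gauss score (default 4).
#' @param seed Recorded in the result for provenance; the optimizer itself
#'   is deterministic.
#' @param max_passes Safety cap on hill-climbing sweeps.
#' @return A `contact_selection` with `lambda = 0`.
#' @export
select_gauss_optimized <- function(cmap, n = default_selection_size(cmap),
                                   sigma2 = 4, seed = 0L, max_passes = 100L) {
  n <- check_selection_n(cmap, n)
  cc <- cmap$contacts
  m <- nrow(cc)
  if (n == m) {
    sel <- new_selection(cmap, cc, NULL, "gauss", seed, sigma2)
    return(sel)
  }
  K <- gauss_kernel_matrix(cc, sigma2)
  omega_of <- function(S) sum(1 / rowSums(K[S, S, drop = FALSE]))
  # seed pair: maximal squared index distance, lexicographic tie-break;
  # rows of cc are lexicographically sorted so which.max picks the smallest
  if (n == 1L) {
    S <- 1L
  } else {
    sq <- rowSums(cc^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(cc)
    D2[lower.tri(D2, diag = TRUE)] <- -Inf
    best <- which(D2 == max(D2), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    S <- c(best[1L, 1L], best[1L, 2L])
  }
  nu <- rowSums(K[S, S, drop = FALSE]) # running kernel sums of chosen
  while (length(S) < n) {
    cand <- setdiff(seq_len(m), S)
    # score of S + c: members' nu gain K[S, c]; candidate gets 1 + sum K[c, S]
    gains <- vapply(cand, function(cix) {
      sum(1 / (nu + K[S, cix])) + 1 / (1 + sum(K[cix, S]))
    }, numeric(1))
    pick <- cand[which.max(gains)] # ties: first = lexicographically smallest
    nu <- c(nu + K[S, pick], 1 + sum(K[pick, S]))
    S <- c(S, pick)
  }
  # single-swap hill climbing, best-improvement
  for (pass in seq_len(max_passes)) {
    S <- sort(S)
    cur <- omega_of(S)
    best_gain <- 0
    best_swap <- NULL
    out <- setdiff(seq_len(m), S)
    for (r in S) {
      keep <- setdiff(S, r)
      nu_keep <- rowSums(K[keep, keep, drop = FALSE])
      for (a in out) {
        val <- sum(1 / (nu_keep + K[keep, a])) + 1 / (1 + sum(K[a, keep]))
        if (val > cur + best_gain + 1e-12) {
          best_gain <- val - cur
          best_swap <- c(r, a)
        }
      }
    }
    if (is.null(best_swap)) break
    S <- c(setdiff(S, best_swap[1L]), best_swap[2L])
  }
  new_selection(cmap, cc[S, , drop = FALSE], NULL, "gauss", seed, sigma2)
}

#' Inject false contacts at a target error rate
#'
#' Augments a selection with contacts drawn uniformly from the index pairs
#' that are *not* native contacts, emulating the false positives of a real
#' predictor.  To reach error rate \eqn{\lambda = |C̄|/(|C| + |C̄|)},
#' \eqn{k = \mathrm{round}(\lambda |C| / (1 - \lambda))} false pairs are
#' added; the achieved \eqn{\lambda} is recorded on the result.  The PPV
#' of the augmented selection against the native map is \eqn{1 - \lambda}
#' by construction.
#'
#' @param cmap_native The native [contact_map()] defining which pairs are
#'   true; candidates respect its `min_sep`.
#' @param base A `contact_selection` of true contacts.
#' @param lambda_target Target error rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return A new `contact_selection` with the false set filled in.
#' @export
inject_false_contacts <- function(cmap_native, base, lambda_target, seed) {
  stopifnot(inherits(cmap_native, "contact_map"),
            inherits(base, "contact_selection"))
  if (!is.numeric(lambda_target) || lambda_target < 0 || lambda_target >= 1)
    stop("lambda_target must lie in [0, 1)")
  nb <- nrow(base$chosen)
  if (!nb) stop("empty base selection")
  k <- round(lambda_target * nb / (1 - lambda_target))
  if (k == 0) return(base)
  dom <- domain_pairs(cmap_native$L, cmap_native$definition$min_sep)
  native_key <- paste(cmap_native$contacts[, 1L], cmap_native$contacts[, 2L])
  pool <- dom[!paste(dom[, 1L], dom[, 2L]) %in% native_key, , drop = FALSE]
  if (nrow(pool) < k)
    stop(sprintf("only %d non-contact pairs available, %d needed",
                 nrow(pool), k))
  rng <- local_rng(seed)
  false_set <- pool[rng$sample(nrow(pool), k), , drop = FALSE]
  new_selection(cmap_native, base$true_set, rbind(base$false_set, false_set),
                base$scheme, seed, base$sigma2)
}

# seeded RNG scoped to one invocation; does not disturb the global stream
local_rng <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  env <- new.env()
  assign("state", {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  }, envir = env)
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", get("state", env), envir = globalenv())
    on.exit({
      assign("state", get(".Random.seed", globalenv()), envir = env)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    runif = function(n) with_state(stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    rlnorm = function(n, meanlog = 0, sdlog = 1)
      with_state(stats::rlnorm(n, meanlog, sdlog)),
    rbinom = function(n, size, prob) with_state(stats::rbinom(n, size, prob))
  )
}

#' Serialize a selection to a contact table with labels
#'
#' Writes the chosen contacts in the plain-text contact-table format with a
#' third column `true`/`false`, plus header metadata (`scheme`, `seed`,
#' `sigma2`, `lambda`, `L`, `min_sep`) so [read_selection_table()] can
#' reconstruct the selection (against a supplied native map).
#'
#' @param sel A `contact_selection`.
#' @param sink Output path or `NULL`.
#' @return Invisibly, the lines written.
#' @export
write_selection_table <- function(sel, sink = NULL) {
  stopifnot(inherits(sel, "contact_selection"))
  fk <- paste(sel$false_set[, 1L], sel$false_set[, 2L])
  lab <- ifelse(paste(sel$chosen[, 1L], sel$chosen[, 2L]) %in% fk,
                "false", "true")
  lines <- c(
    sprintf("# L=%d", sel$parent$L),
    sprintf("# min_sep=%d", sel$parent$definition$min_sep),
    sprintf("# scheme=%s", sel$scheme),
    sprintf("# seed=%s", format(sel$seed)),
    if (!is.na(sel$sigma2)) sprintf("# sigma2=%s", format(sel$sigma2)),
    sprintf("# lambda=%.10g", sel$lambda),
    if (nrow(sel$chosen))
      sprintf("%d %d %s", sel$chosen[, 1L], sel$chosen[, 2L], lab))
  if (!is.null(sink)) writeLines(lines, sink)
  invisible(lines)
}

#' Read a labelled selection table
#'
#' @param source Path or character lines from [write_selection_table()].
#' @param parent The parent [contact_map()]; if `NULL` a bare external map
#'   of the true contacts is reconstructed from the header.
#' @return A `contact_selection`.
#' @export
read_selection_table <- function(source, parent = NULL) {
  lines <- read_source_lines(source)
  hdr <- parse_header_meta(lines)
  body <- lines[grep("^\\s*(#|$)", lines, invert = TRUE)]
  tok <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(tok) < 3L)
  if (length(bad)) stop("selection record without true/false label")
  ii <- as.integer(vapply(tok, `[[`, "", 1L))
  jj <- as.integer(vapply(tok, `[[`, "", 2L))
  lab <- vapply(tok, `[[`, "", 3L)
  if (!all(lab %in% c("true", "false"))) stop("labels must be true/false")
  if (is.null(parent)) {
    L <- as.integer(hdr$L)
    ms <- if (!is.null(hdr$min_sep)) as.integer(hdr$min_sep) else 4L
    parent <- contact_map(L, cbind(ii, jj)[lab == "true", , drop = FALSE],
                          min_sep = ms)
  }
  new_selection(parent,
                cbind(ii, jj)[lab == "true", , drop = FALSE],
                cbind(ii, jj)[lab == "false", , drop = FALSE],
                if (!is.null(hdr$scheme)) hdr$scheme else "external",
                if (!is.null(hdr$seed)) as.integer(hdr$seed) else NA_integer_,
                if (!is.null(hdr$sigma2)) as.numeric(hdr$sigma2) else NA_real_)
}
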