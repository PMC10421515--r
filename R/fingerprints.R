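#' Circular (Morgan-style) molecular fingerprint
#'
#' Extended-connectivity fingerprint of radius 2 (diameter 4) folded to a
#' fixed-length bit set. Each atom starts from an invariant code built from
#' (atomic number, heavy degree, attached hydrogens, formal charge,
#' aromatic-bond membership); per iteration the code is re-hashed together
#' with the sorted (bond order, neighbor code) list, and every code from
#' every radius sets one bit modulo the fingerprint length. The bits depend
#' only on the molecular graph, so equivalent SMILES spellings of one
#' structure give identical fingerprints.
#'
#' @param g A [molecular_graph()].
#' @param nbits Fingerprint length (default 2048).
#' @param radius Neighborhood radius (default 2, i.e. ECFP4-like).
#' @return Object of class \code{fingerprint}: list with \code{bits}
#'   (sorted unique 1-based bit positions), \code{nbits}, \code{id}.
#' @export
morgan_fingerprint <- function(g, nbits = 2048, radius = 2) {
  stopifnot(inherits(g, "molecular_graph"), is_count(nbits), is_count(radius, 0))
  n <- n_atoms(g)
  adj <- rep(list(integer()), n)
  bord <- rep(list(numeric()), n)
  arom <- rep(FALSE, n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]; o <- g$bonds$order[b]
    adj[[i]] <- c(adj[[i]], j); bord[[i]] <- c(bord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); bord[[j]] <- c(bord[[j]], o)
    if (o == 1.5) arom[i] <- arom[j] <- TRUE
  }
  zn <- .atom_props$atomic_number[match(g$atoms$element, .atom_props$element)]
  deg <- lengths(adj)
  code <- vapply(seq_len(n), function(a)
    hash_ints(c(zn[a], deg[a], g$atoms$hcount[a], g$atoms$charge[a] + 10,
                as.integer(arom[a]))), numeric(1))
  all_codes <- code
  for (r in seq_len(radius)) {
    newcode <- numeric(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      if (length(nb)) {
        pairs <- cbind(round(bord[[a]] * 10), code[nb])
        ord <- order(pairs[, 1L], pairs[, 2L])
        newcode[a] <- hash_ints(c(r, code[a], t(pairs[ord, , drop = FALSE])))
      } else newcode[a] <- hash_ints(c(r, code[a]))
    }
    code <- newcode
    all_codes <- c(all_codes, code)
  }
  bits <- sort(unique(as.integer(all_codes %% nbits) + 1L))
  structure(list(bits = bits, nbits = as.integer(nbits), id = g$id),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s: %d of %d bits set\n", x$id,
              length(x$bits), x$nbits))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over the set bits; symmetric, in
#' \eqn{[0, 1]}; two empty fingerprints score 0 by convention.
#'
#' @param a,b \code{fingerprint} objects of equal length.
#' @return Similarity in \eqn{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits)
    stopf("fingerprint length mismatch (%d vs %d)", a$nbits, b$nbits)
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

# fingerprints -> dense 0/1 matrix (rows = compounds)
fingerprint_matrix <- function(fps) {
  stopifnot(length(fps) >= 1L)
  nbits <- fps[[1L]]$nbits
  m <- matrix(0, length(fps), nbits,
              dimnames = list(vapply(fps, `[[`, character(1), "id"), NULL))
  for (k in seq_along(fps)) m[k, fps[[k]]$bits] <- 1
  m
}

#' Mini-batch k-means clustering of fingerprints
#'
#' Mini-batch k-means (Sculley-style per-center learning rates) on
#' fingerprints treated as 0/1 real vectors, followed by one full
#' assignment pass and exact centroid recomputation. Deterministic given
#' the seed.
#'
#' @param fps List of \code{fingerprint} objects.
#' @param k Number of clusters (1 <= k <= length(fps)).
#' @param batch_size Mini-batch size (default 100, capped at n).
#' @param iterations Mini-batch iterations (default 100).
#' @param seed Integer seed.
#' @return List of class \code{fp_clustering}: \code{cluster} (named
#'   integer vector), \code{centroids} (k x nbits matrix), \code{inertia}
#'   (total squared distance to assigned centroid), \code{seed}.
#' @export
cluster_library <- function(fps, k, batch_size = 100, iterations = 100,
                            seed = 1L) {
  stopifnot(is.list(fps), length(fps) >= 1L, is_count(k), is_count(seed, 0))
  n <- length(fps)
  if (k > n) stopf("k = %d exceeds library size %d", k, n)
  m <- fingerprint_matrix(fps)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  batch_size <- min(batch_size, n)
  centroids <- m[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  assign_to <- function(rows) {
    # squared Euclidean distance to each centroid
    d <- outer(rowSums(rows^2), rowSums(centroids^2), `+`) -
      2 * rows %*% t(centroids)
    max.col(-d, ties.method = "first")
  }
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, batch_size)
    rows <- m[idx, , drop = FALSE]
    a <- assign_to(rows)
    for (r in seq_along(idx)) {
      c0 <- a[r]
      counts[c0] <- counts[c0] + 1
      eta <- 1 / counts[c0]
      centroids[c0, ] <- (1 - eta) * centroids[c0, ] + eta * rows[r, ]
    }
  }
  cl <- assign_to(m)
  for (c0 in seq_len(k)) {
    rows <- which(cl == c0)
    if (length(rows))
      centroids[c0, ] <- colMeans(m[rows, , drop = FALSE])
  }
  cl <- assign_to(m)
  inertia <- sum((m - centroids[cl, , drop = FALSE])^2)
  names(cl) <- rownames(m)
  structure(list(cluster = cl, centroids = centroids, inertia = inertia,
                 seed = as.integer(seed)),
            class = "fp_clustering")
}

#' @export
print.fp_clustering <- function(x, ...) {
  cat(sprintf("<fp_clustering> %d compounds in %d clusters, inertia %.3f\n",
              length(x$cluster), nrow(x$centroids), x$inertia))
  invisible(x)
}
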