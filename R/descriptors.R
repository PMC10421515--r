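#' Descriptor specifications and canonical names
#'
#' A descriptor spec names one 2D topological descriptor: a family, a lag
#' (autocorrelations) or eigenvalue rank (Burden / eigenvector indices), and
#' an atomic weighting scheme. Canonical names follow the field's convention:
#' \code{ATSC<k><w>}, \code{MATS<k><w>}, \code{GATS<k><w>} with weight codes
#' \code{e} (Sanderson electronegativity), \code{p} (polarizability),
#' \code{i} (first ionization energy), \code{Z} (atomic number);
#' \code{SpMin<n>_Bh<w>} for the n-th smallest absolute eigenvalue of the
#' Burden-modified matrix; \code{VR<n>_D} for the Randic-like eigenvector
#' index on the topological distance matrix.
#'
#' @param family One of \code{"ATSC"}, \code{"MATS"}, \code{"GATS"},
#'   \code{"SpMin_Bh"}, \code{"VR_D"}.
#' @param lag Lag (autocorrelations) or rank/variant (eigen families).
#' @param scheme Weight scheme as in [atom_weights()] (ignored for
#'   \code{VR_D}).
#' @return An object of class \code{descriptor_spec} with a \code{name}
#'   field that round-trips through [parse_descriptor_name()].
#' @examples
#' descriptor_spec("MATS", 1, "polarizability")$name   # "MATS1p"
#' parse_descriptor_name("SpMin8_Bhi")
#' @export
descriptor_spec <- function(family = c("ATSC", "MATS", "GATS", "SpMin_Bh",
                                       "VR_D"),
                            lag, scheme = "electronegativity") {
  family <- match.arg(family)
  stopifnot(is_count(lag))
  lag <- as.integer(lag)
  code <- names(.scheme_codes)[match(scheme, .scheme_codes)]
  if (family != "VR_D" && is.na(code))
    stopf("unknown weight scheme '%s'", scheme)
  name <- switch(family,
    ATSC = paste0("ATSC", lag, code),
    MATS = paste0("MATS", lag, code),
    GATS = paste0("GATS", lag, code),
    SpMin_Bh = paste0("SpMin", lag, "_Bh", code),
    VR_D = paste0("VR", lag, "_D"))
  structure(list(family = family, lag = lag,
                 scheme = if (family == "VR_D") NA_character_ else scheme,
                 name = name),
            class = "descriptor_spec")
}

#' @rdname descriptor_spec
#' @param name Canonical descriptor name string.
#' @export
parse_descriptor_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^(ATSC|MATS|GATS)([0-9]+)([epiZ])$", name))[[1]]
  if (length(m))
    return(descriptor_spec(m[2], as.integer(m[3]), .scheme_codes[[m[4]]]))
  m <- regmatches(name, regexec("^SpMin([0-9]+)_Bh([epiZ])$", name))[[1]]
  if (length(m))
    return(descriptor_spec("SpMin_Bh", as.integer(m[2]), .scheme_codes[[m[3]]]))
  m <- regmatches(name, regexec("^VR([0-9]+)_D$", name))[[1]]
  if (length(m))
    return(descriptor_spec("VR_D", as.integer(m[2])))
  stopf("cannot parse descriptor name '%s'", name)
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat(sprintf("<descriptor_spec> %s (family %s, lag/rank %d, scheme %s)\n",
              x$name, x$family, x$lag, x$scheme))
  invisible(x)
}

.resolve_weights <- function(g, scheme) {
  if (is.numeric(scheme)) {
    stopifnot(length(scheme) == n_atoms(g))
    return(scheme)
  }
  atom_weights(g, scheme)
}

# unordered atom pairs at topological distance k
.pairs_at_lag <- function(d, k) {
  idx <- which(d == k & upper.tri(d), arr.ind = TRUE)
  idx
}

#' Centered Broto-Moreau autocorrelation (ATSC)
#'
#' Sum over unordered heavy-atom pairs at topological distance \code{lag} of
#' the products of mean-centered atomic weights:
#' \deqn{ATSC_k = \sum_{d(i,j)=k} (w_i - \bar w)(w_j - \bar w).}
#' Zero when no pair sits at the requested lag.
#'
#' @param g A [molecular_graph()].
#' @param lag Topological distance, >= 1.
#' @param scheme Weight scheme name as in [atom_weights()], or a numeric
#'   vector of explicit per-atom weights (length = heavy-atom count).
#' @return A single numeric value.
#' @export
atsc <- function(g, lag, scheme = "electronegativity") {
  stopifnot(is_count(lag))
  w <- .resolve_weights(g, scheme)
  d <- topological_distances(g)
  pr <- .pairs_at_lag(d, lag)
  if (nrow(pr) == 0L) return(0)
  wc <- w - mean(w)
  sum(wc[pr[, 1L]] * wc[pr[, 2L]])
}

#' Moran autocorrelation (MATS)
#'
#' Moran spatial autocorrelation of atomic weights at topological lag k:
#' the mean centered cross-product over pairs at distance k divided by the
#' mean squared deviation over atoms. Typically falls in \eqn{[-1, 1]}.
#' Undefined (masked) when the weights have zero variance or no pair sits
#' at the lag.
#'
#' @inheritParams atsc
#' @return A single numeric value.
#' @export
mats <- function(g, lag, scheme = "electronegativity") {
  stopifnot(is_count(lag))
  w <- .resolve_weights(g, scheme)
  d <- topological_distances(g)
  pr <- .pairs_at_lag(d, lag)
  wc <- w - mean(w)
  denom <- mean(wc^2)
  if (denom == 0)
    stopf("MATS%d undefined for '%s': zero weight variance", lag, g$id,
          class = "plqsar_undefined_descriptor")
  if (nrow(pr) == 0L)
    stopf("MATS%d undefined for '%s': no atom pair at lag %d", lag, g$id, lag,
          class = "plqsar_undefined_descriptor")
  mean(wc[pr[, 1L]] * wc[pr[, 2L]]) / denom
}

#' Geary autocorrelation (GATS)
#'
#' Geary spatial autocorrelation of atomic weights at topological lag k:
#' \deqn{GATS_k = \frac{\frac{1}{2\Delta_k}\sum_{d(i,j)=k}(w_i-w_j)^2}
#'                     {\frac{1}{A-1}\sum_i (w_i-\bar w)^2}}
#' with \eqn{\Delta_k} the number of unordered pairs at distance k and A the
#' heavy-atom count. Always non-negative; undefined under zero weight
#' variance or an empty lag.
#'
#' @inheritParams atsc
#' @return A single numeric value.
#' @export
gats <- function(g, lag, scheme = "electronegativity") {
  stopifnot(is_count(lag))
  w <- .resolve_weights(g, scheme)
  if (length(w) < 2L)
    stopf("GATS%d undefined for '%s': fewer than 2 atoms", lag, g$id,
          class = "plqsar_undefined_descriptor")
  d <- topological_distances(g)
  pr <- .pairs_at_lag(d, lag)
  denom <- sum((w - mean(w))^2) / (length(w) - 1L)
  if (denom == 0)
    stopf("GATS%d undefined for '%s': zero weight variance", lag, g$id,
          class = "plqsar_undefined_descriptor")
  if (nrow(pr) == 0L)
    stopf("GATS%d undefined for '%s': no atom pair at lag %d", lag, g$id, lag,
          class = "plqsar_undefined_descriptor")
  num <- sum((w[pr[, 1L]] - w[pr[, 2L]])^2) / (2 * nrow(pr))
  num / denom
}

# Burden-modified matrix: diagonal = carbon-relative weights; bonded
# off-diagonals 0.1 * order (aromatic 1.5), +0.01 when the bond touches a
# terminal atom; every non-bonded off-diagonal 0.001
burden_matrix <- function(g, scheme = "ionization") {
  w <- atom_weights(g, scheme, relative = TRUE)
  n <- n_atoms(g)
  B <- matrix(0.001, n, n)
  diag(B) <- w
  if (nrow(g$bonds)) {
    degree <- tabulate(c(g$bonds$i, g$bonds$j), nbins = n)
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[b]; j <- g$bonds$j[b]
      v <- 0.1 * g$bonds$order[b]
      if (degree[i] == 1L || degree[j] == 1L) v <- v + 0.01
      B[i, j] <- B[j, i] <- v
    }
  }
  B
}

#' Burden-modified matrix eigenvalue descriptor (SpMin_Bh)
#'
#' Builds the Burden-modified matrix (property-weighted diagonal,
#' bond-derived off-diagonals) and returns its \code{rank}-th smallest
#' eigenvalue by absolute value. \code{SpMin8_Bhi} is rank 8 under the
#' carbon-relative first-ionization-potential weighting.
#'
#' @param g A [molecular_graph()].
#' @param rank 1-based rank into the absolute-value-sorted spectrum.
#' @inheritParams atom_weights
#' @return A single numeric value (sign preserved from the eigenvalue).
#' @export
burden_spmin <- function(g, rank = 8, scheme = "ionization") {
  stopifnot(is_count(rank))
  if (n_atoms(g) < rank)
    stopf("SpMin%d undefined for '%s': only %d atoms", rank, g$id, n_atoms(g),
          class = "plqsar_undefined_descriptor")
  ev <- eigen(burden_matrix(g, scheme), symmetric = TRUE,
              only.values = TRUE)$values
  ev[order(abs(ev))][rank]
}

#' Randic-like eigenvector index on the distance matrix (VR_D)
#'
#' Takes the principal eigenvector v (largest eigenvalue, entries in
#' absolute value) of the topological distance matrix and sums
#' \eqn{(|v_i| |v_j|)^{-1/2}} over bonded pairs (the VR1 index);
#' \code{variant = 2} normalizes by the heavy-atom count (VR2).
#'
#' @param g A [molecular_graph()].
#' @param variant 1 for the raw sum, 2 for the atom-count-normalized value.
#' @return A single numeric value.
#' @export
vr_d <- function(g, variant = 2) {
  stopifnot(variant %in% c(1, 2))
  if (n_atoms(g) < 2L)
    stopf("VR%d_D undefined for '%s': fewer than 2 atoms", variant, g$id,
          class = "plqsar_undefined_descriptor")
  d <- topological_distances(g)
  es <- eigen(d, symmetric = TRUE)
  v <- abs(es$vectors[, which.max(es$values)])
  prods <- v[g$bonds$i] * v[g$bonds$j]
  if (any(prods <= 0))
    stopf("VR%d_D undefined for '%s': degenerate principal eigenvector",
          variant, g$id, class = "plqsar_undefined_descriptor")
  vr1 <- sum(prods^(-0.5))
  if (variant == 1) vr1 else vr1 / n_atoms(g)
}

compute_descriptor <- function(g, spec) {
  if (is.character(spec)) spec <- parse_descriptor_name(spec)
  switch(spec$family,
    ATSC = atsc(g, spec$lag, spec$scheme),
    MATS = mats(g, spec$lag, spec$scheme),
    GATS = gats(g, spec$lag, spec$scheme),
    SpMin_Bh = burden_spmin(g, spec$lag, spec$scheme),
    VR_D = vr_d(g, spec$lag))
}

#' The five descriptors of the reference pIC50 model
#'
#' @return Character vector of canonical names: MATS1p, ATSC6e, GATS2p,
#'   SpMin8_Bhi, VR2_D.
#' @export
reference_descriptor_names <- function() {
  c("MATS1p", "ATSC6e", "GATS2p", "SpMin8_Bhi", "VR2_D")
}

#' Compute a compounds-by-descriptors matrix
#'
#' Evaluates every descriptor spec for every molecule. Undefined descriptors
#' (zero weight variance, empty lag, too few atoms) are masked as \code{NA}
#' and collected — with their reason — in the \code{"failures"} attribute;
#' the batch never aborts on a per-compound failure.
#'
#' @param molecules List of [molecular_graph()] objects with unique ids.
#' @param specs Character vector of canonical descriptor names, or a list of
#'   [descriptor_spec()] objects.
#' @return Numeric matrix, rows named by compound id (input order), columns
#'   by canonical descriptor name; attribute \code{failures} is a data frame
#'   (id, descriptor, reason).
#' @examples
#' m <- compute_descriptor_matrix(list(parse_smiles("CCO", "ethanol")),
#'                                c("MATS1p", "GATS2p"))
#' @export
compute_descriptor_matrix <- function(molecules, specs) {
  if (inherits(molecules, "molecular_graph")) molecules <- list(molecules)
  if (length(molecules) == 0L) stopf("no molecules supplied")
  if (length(specs) == 0L) stopf("no descriptor specs supplied")
  if (is.character(specs)) specs <- lapply(specs, parse_descriptor_name)
  if (inherits(specs, "descriptor_spec")) specs <- list(specs)
  ids <- vapply(molecules, function(g) g$id, character(1))
  if (anyDuplicated(ids))
    stopf("duplicate compound ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(cols))
    stopf("duplicate descriptor names: %s",
          paste(unique(cols[duplicated(cols)]), collapse = ", "))
  m <- matrix(NA_real_, length(molecules), length(specs),
              dimnames = list(ids, cols))
  fails <- list()
  for (r in seq_along(molecules)) {
    for (c in seq_along(specs)) {
      val <- tryCatch(compute_descriptor(molecules[[r]], specs[[c]]),
                      plqsar_undefined_descriptor = function(e) e,
                      plqsar_error = function(e) e)
      if (inherits(val, "condition")) {
        fails[[length(fails) + 1L]] <-
          data.frame(id = ids[r], descriptor = cols[c],
                     reason = conditionMessage(val))
      } else m[r, c] <- val
    }
  }
  attr(m, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(id = character(), descriptor = character(),
               reason = character())
  m
}
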