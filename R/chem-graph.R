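#' Hydrogen-suppressed molecular graph
#'
#' The substrate for all descriptor calculations: heavy atoms with element,
#' formal charge and attached-hydrogen count, plus bonds with a conventional
#' order (1, 2, 3, or 1.5 for aromatic). Hydrogens are suppressed — their
#' count is kept per atom but they never enter descriptor sums.
#'
#' @param atoms Data frame with columns \code{element} (symbol),
#'   \code{charge} (integer) and \code{hcount} (attached hydrogens).
#' @param bonds Data frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (1, 2, 3 or 1.5).
#' @param id Compound identifier string.
#' @return An object of class \code{molecular_graph}.
#' @export
molecular_graph <- function(atoms, bonds, id = "mol") {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("element", "charge", "hcount") %in% names(atoms)))
  n <- nrow(atoms)
  if (n < 1L) stopf("compound '%s': no heavy atoms", id)
  if (nrow(bonds) > 0L) {
    stopifnot(all(c("i", "j", "order") %in% names(bonds)))
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stopf("compound '%s': bond atom index out of range", id)
    if (any(bonds$i == bonds$j))
      stopf("compound '%s': self-bond", id)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key))
      stopf("compound '%s': duplicate bond", id)
    if (!all(bonds$order %in% c(1, 2, 3, 1.5)))
      stopf("compound '%s': bond order must be 1, 2, 3 or 1.5 (aromatic)", id)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  bad <- setdiff(unique(atoms$element), .atom_props$element)
  if (length(bad))
    stopf("compound '%s': element(s) %s not in the property table", id,
          paste(bad, collapse = ", "), class = "plqsar_unknown_element")
  g <- structure(list(atoms = atoms, bonds = bonds, id = as.character(id)),
                 class = "molecular_graph")
  if (n > 1L && !all(.graph_component(g) == 1L))
    stopf("compound '%s': disconnected structure (strip salts upstream)", id,
          class = "plqsar_disconnected")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("<molecular_graph> %s: %d heavy atoms (%s), %d bonds\n",
              x$id, nrow(x$atoms),
              paste0(names(comp), comp, collapse = " "), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

adjacency_list <- function(g) {
  adj <- rep(list(integer()), n_atoms(g))
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[b]; j <- g$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# connected-component labels by BFS
.graph_component <- function(g) {
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][comp[adj[[v]]] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Topological distance matrix
#'
#' All-pairs shortest path lengths, in bonds, over the heavy atoms of a
#' connected molecular graph (breadth-first search from every atom).
#'
#' @param g A [molecular_graph()].
#' @return Symmetric integer matrix with zero diagonal; \code{d[i, j] == 1}
#'   exactly when i and j are bonded.
#' @examples
#' topological_distances(parse_smiles("CCO"))
#' @export
topological_distances <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- n_atoms(g)
  adj <- adjacency_list(g)
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][is.na(dist[adj[[v]]])]
      dist[nb] <- dist[v] + 1L
      queue <- c(queue, nb)
    }
    d[s, ] <- dist
  }
  if (anyNA(d))
    stopf("compound '%s': disconnected graph", g$id,
          class = "plqsar_disconnected")
  d
}

# default valences used for implicit-hydrogen bookkeeping; the formal charge
# is added (N+ -> 4, O- -> 1, C- -> 3, ...)
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

# mark 6-membered rings whose kekulized bond orders alternate 1/2 as
# aromatic (order 1.5); the benzenoid convention used throughout
.perceive_aromatic <- function(atoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(list(atoms = atoms, bonds = bonds))
  n <- nrow(atoms)
  adj <- rep(list(integer()), n)
  for (b in seq_len(nb)) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], b)
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], b)
  }
  other <- function(b, v) if (bonds$i[b] == v) bonds$j[b] else bonds$i[b]
  aromatic <- rep(FALSE, nb)
  for (b0 in seq_len(nb)) {
    u <- bonds$i[b0]; v <- bonds$j[b0]
    # shortest path u -> v avoiding bond b0 (BFS over bonds)
    prev <- rep(NA_integer_, n)   # bond used to reach atom
    dist <- rep(NA_integer_, n); dist[u] <- 0L
    queue <- u
    while (length(queue) && is.na(dist[v])) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in adj[[a]]) {
        if (b == b0) next
        w <- other(b, a)
        if (is.na(dist[w])) {
          dist[w] <- dist[a] + 1L; prev[w] <- b
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[v]) || dist[v] != 5L) next   # want a 6-ring
    ring <- b0
    a <- v
    while (a != u) { ring <- c(ring, prev[a]); a <- other(prev[a], a) }
    ord <- bonds$order[ring]
    if (setequal(unique(ord), c(1, 2)) &&
        all(abs(diff(ord)) == 1) && ord[1L] != ord[length(ord)])
      aromatic[ring] <- TRUE
  }
  bonds$order[aromatic] <- 1.5
  list(atoms = atoms, bonds = bonds)
}

# build a molecular_graph from one ChemmineR SDF record; explicit hydrogens
# are folded into the heavy-atom hcount
.graph_from_sdf_record <- function(sdf, id, chg_override = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_\\d+$", "", rownames(ab))
  na <- nrow(ab)
  # V2000 atom-block charge code: 1..3 = +3..+1, 5..7 = -1..-3
  code <- if (ncol(ab) >= 5L) as.integer(ab[, 5L]) else integer(na)
  charge <- ifelse(code %in% 1:3, 4L - code,
                   ifelse(code %in% 5:7, 4L - code, 0L))
  if (!is.null(chg_override) && nrow(chg_override))
    charge[chg_override$atom] <- chg_override$charge
  bi <- bj <- integer(0); bo <- numeric(0)
  if (!is.null(bb) && length(bb)) {
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L,
                                       dimnames = list(NULL, names(bb)))
    if (nrow(bb) > 0L && ncol(bb) >= 3L) {
      bi <- as.integer(bb[, 1L]); bj <- as.integer(bb[, 2L])
      bo <- as.numeric(bb[, 3L])
      bo[bo == 4] <- 1.5                     # MDL aromatic code
    }
  }
  heavy <- elem != "H"
  hidx <- which(!heavy)
  hcount <- integer(na)
  keep <- rep(TRUE, length(bi))
  for (b in seq_along(bi)) {
    if (bi[b] %in% hidx || bj[b] %in% hidx) {
      keep[b] <- FALSE
      hv <- if (bi[b] %in% hidx) bj[b] else bi[b]
      if (elem[hv] != "H") hcount[hv] <- hcount[hv] + 1L
    }
  }
  map <- cumsum(heavy)
  atoms <- data.frame(element = elem[heavy], charge = charge[heavy],
                      hcount = hcount[heavy], stringsAsFactors = FALSE)
  bonds <- data.frame(i = map[bi[keep]], j = map[bj[keep]],
                      order = bo[keep])
  # implicit hydrogens from default valence + formal charge
  vsum <- numeric(nrow(atoms))
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) {
    vsum[bonds$i[b]] <- vsum[bonds$i[b]] + bonds$order[b]
    vsum[bonds$j[b]] <- vsum[bonds$j[b]] + bonds$order[b]
  }
  dv <- .default_valence[atoms$element]
  if (anyNA(dv))
    stopf("compound '%s': element(s) %s not supported", id,
          paste(unique(atoms$element[is.na(dv)]), collapse = ", "),
          class = "plqsar_unknown_element")
  imp <- pmax(0, round(dv + atoms$charge - vsum) - atoms$hcount)
  atoms$hcount <- atoms$hcount + as.integer(imp)
  pr <- .perceive_aromatic(atoms, bonds)
  molecular_graph(pr$atoms, pr$bonds, id = id)
}

# M CHG lines per record of an SDF text (ChemmineR drops them)
.parse_mchg <- function(lines) {
  rec_end <- grep("^\\$\\$\\$\\$", lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  lapply(seq_along(rec_start), function(r) {
    block <- lines[rec_start[r]:rec_end[r]]
    chg <- grep("^M  CHG", block, value = TRUE)
    out <- data.frame(atom = integer(), charge = integer())
    for (line in chg) {
      f <- as.integer(strsplit(trimws(substring(line, 7)), "\\s+")[[1]])
      k <- f[1L]
      pairs <- matrix(f[-1L], ncol = 2L, byrow = TRUE)
      out <- rbind(out, data.frame(atom = pairs[, 1L], charge = pairs[, 2L]))
    }
    out
  })
}

# fallback for zero-bond records (single heavy atom after suppression),
# which ChemmineR flags invalid: read the V2000 atom lines directly
.graph_from_v2000_lines <- function(block, id, chg_override = NULL) {
  counts <- block[4L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  if (is.na(na) || na < 1L || (!is.na(nb) && nb > 0L))
    stopf("cannot parse SDF record '%s'", id, class = "plqsar_parse_error")
  f <- strsplit(trimws(block[5L:(4L + na)]), "\\s+")
  elem <- vapply(f, `[[`, character(1), 4L)
  code <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 6L)))
  charge <- ifelse(code %in% c(1:3, 5:7), 4L - code, 0L)
  if (!is.null(chg_override) && nrow(chg_override))
    charge[chg_override$atom] <- chg_override$charge
  heavy <- elem != "H"
  atoms <- data.frame(element = elem[heavy], charge = charge[heavy],
                      hcount = sum(!heavy), stringsAsFactors = FALSE)
  dv <- .default_valence[atoms$element]
  atoms$hcount <- as.integer(pmax(atoms$hcount,
                                  round(dv + atoms$charge)))
  molecular_graph(atoms,
                  data.frame(i = integer(), j = integer(),
                             order = numeric()), id = id)
}

.parse_sdf_text <- function(text, ids = NULL) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  if (!length(grep("^\\$\\$\\$\\$", lines)))
    lines <- c(lines, "$$$$")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  valid <- suppressWarnings(ChemmineR::validSDF(sdfset))
  chg <- .parse_mchg(lines)
  rec_end <- grep("^\\$\\$\\$\\$", lines)
  rec_start <- c(1L, head(rec_end, -1L) + 1L)
  titles <- vapply(rec_start, function(s) trimws(lines[s]), character(1))
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    id <- if (!is.null(ids)) ids[k]
          else if (nzchar(titles[k])) titles[k]
          else as.character(k)
    out[[k]] <- if (valid[k])
      .graph_from_sdf_record(sdfset[[k]], id, chg_override = chg[[k]])
    else
      .graph_from_v2000_lines(lines[rec_start[k]:rec_end[k]], id,
                              chg_override = chg[[k]])
  }
  out
}

#' Parse SMILES into molecular graphs
#'
#' Converts SMILES strings (via OpenBabel) into hydrogen-suppressed
#' [molecular_graph()] objects. Implicit hydrogen counts are recorded per
#' atom; benzenoid aromatic rings are perceived and their bonds given
#' order 1.5. Multi-fragment inputs (salts, mixtures) are rejected.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers (defaults to 1-based index).
#' @return A single \code{molecular_graph} if one SMILES was given,
#'   otherwise a list of them.
#' @examples
#' parse_smiles("c1ccccc1", "benzene")
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  ids <- as.character(ids)
  stopifnot(length(ids) == length(smiles))
  if (any(grepl("\\s", smiles)))
    stopf("SMILES must not contain whitespace")
  if (any(grepl("\\.", smiles, fixed = FALSE))) {
    bad <- ids[grepl(".", smiles, fixed = TRUE)]
    stopf("multi-fragment SMILES for id(s) %s: strip salts upstream",
          paste(bad, collapse = ", "), class = "plqsar_disconnected")
  }
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    sdf <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF",
                                paste0(smiles[k], " ", ids[k], "\n")),
      error = function(e) "")
    if (!nzchar(sdf) || !grepl("V2000", sdf, fixed = TRUE))
      stopf("cannot parse SMILES for id '%s': %s", ids[k], smiles[k],
            class = "plqsar_parse_error")
    out[[k]] <- .parse_sdf_text(sdf, ids = ids[k])[[1L]]
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Read structures from a SMILES or SDF file
#'
#' SMILES files hold one record per line: the SMILES string optionally
#' followed by whitespace and an identifier. SDF files are V2000
#' multi-record; the identifier is the title line, falling back to the
#' 1-based record index.
#'
#' @param path File path; format inferred from the extension
#'   (\code{.smi}/\code{.smiles} vs \code{.sdf}/\code{.mol}) unless given.
#' @param format \code{"smiles"} or \code{"sdf"}.
#' @return List of [molecular_graph()] objects.
#' @export
read_structures <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol")) "sdf" else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stopf("no records in '%s'", path)
    smi <- sub("\\s.*$", "", lines)
    rest <- trimws(sub("^\\S+", "", lines))
    ids <- ifelse(nzchar(rest), rest, as.character(seq_along(lines)))
    g <- parse_smiles(smi, ids)
    if (inherits(g, "molecular_graph")) list(g) else g
  } else {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    .parse_sdf_text(text)
  }
}
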