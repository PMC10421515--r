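# scoped RNG: run code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a descriptor matrix with a planted sparse linear signal
#'
#' Draws an n x p design of equicorrelated standard-normal "descriptors"
#' (pairwise correlation \code{rho}) and a response
#' \code{y = intercept + X[, support] \%*\% beta + eps},
#' \code{eps ~ N(0, sigma^2)} — the statistical structure of a descriptor
#' table with a small true subset driving activity. Compounds are split
#' 70/30 into train/test at random (seeded).
#'
#' @param n Number of compounds.
#' @param p Number of descriptors.
#' @param k Size of the true support.
#' @param beta True coefficients (length k; recycled scalar allowed).
#' @param intercept True intercept.
#' @param rho Equicorrelation between descriptor columns, in \eqn{[0, 1)}.
#' @param sigma Noise standard deviation (pIC50 units), >= 0.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List of class \code{qsar_simulation}: \code{x} (matrix, columns
#'   \code{D001...}), \code{activity} (data frame: id, pic50, partition),
#'   \code{truth} (support names, beta, intercept, sigma, rho, seed).
#' @examples
#' sim <- sim_linear_dataset(n = 40, p = 10, k = 3, beta = 1, sigma = 0.1,
#'                           seed = 1)
#' @export
sim_linear_dataset <- function(n, p, k, beta = 1, intercept = 4,
                               rho = 0, sigma = 0.2, seed = 1L) {
  stopifnot(is_count(n, 2), is_count(p), is_count(k), k <= p,
            is_number(rho), rho >= 0, rho < 1,
            is_number(sigma), sigma >= 0, is_number(intercept),
            is_count(seed, 0))
  beta <- rep_len(beta, k)
  with_seed(seed, {
    z0 <- rnorm(n)
    x <- sqrt(rho) * matrix(z0, n, p) +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    colnames(x) <- sprintf("D%03d", seq_len(p))
    rownames(x) <- sprintf("cmpd%03d", seq_len(n))
    support <- colnames(x)[seq_len(k)]
    y <- intercept + drop(x[, support, drop = FALSE] %*% beta) +
      rnorm(n, sd = sigma)
    ntr <- round(0.7 * n)
    part <- rep("test", n)
    part[sample.int(n, ntr)] <- "train"
    structure(list(
      x = x,
      activity = data.frame(id = rownames(x), pic50 = y, partition = part,
                            stringsAsFactors = FALSE),
      truth = list(support = support, beta = beta, intercept = intercept,
                   sigma = sigma, rho = rho, seed = as.integer(seed))),
      class = "qsar_simulation")
  })
}

# scaffold templates: each is a function of a substituent SMILES fragment
# placed at a distal peripheral position ("" leaves the parent scaffold).
# Large scaffolds (31-44 heavy atoms) with tip edits keep the circular-
# fingerprint Tanimoto to the parent high; the allowed substituents per
# scaffold all sit clearly above the 0.8 similarity cutoff, which is what
# makes the planted records usable as enrichment ground truth.
.planted_scaffolds <- list(
  glycoflavonol = function(s) sprintf(
    "CC1OC(OCC2OC(Oc3c(-c4ccc(O)c(O%s)c4)oc4cc(O)cc(O)c4c3=O)C(O)C(O)C2O)C(O)C(O)C1O", s),
  glycoflavone = function(s) sprintf(
    "CC1OC(OCC2OC(Oc3c(-c4ccc(O%s)cc4)oc4cc(O)cc(O)c4c3=O)C(O)C(O)C2O)C(O)C(O)C1O", s),
  prenylflavanone = function(s) sprintf(
    "CC(C)=CCc1c(O)cc2c(c1O)C(=O)C(CC=C(C%s)C)C(c1ccc(O)cc1O)O2", s),
  ascorbyl_gallate = function(s) sprintf(
    "OC%sC(O)C1OC(=O)C(c2c(O)cc(O)c3c2OC(c2cc(O)c(O)c(O)c2)C(OC(=O)c2cc(O)c(O)c(O)c2)C3)=C1O", s),
  biflavone = function(s) sprintf(
    "C%sOc1ccc(-c2cc(=O)c3c(O)cc(O)c(-c4c(O)cc5oc(-c6ccc(O)cc6)cc(=O)c5c4O)c3o2)cc1", s))

.planted_subs <- list(
  glycoflavonol = c("", "C", "CC", "O"),
  glycoflavone = c("", "C", "CC", "O"),
  prenylflavanone = c("", "C", "CC", "O"),
  ascorbyl_gallate = c("", "C", "CC"),
  biflavone = c("", "O"))

# decoy templates: unrelated chemotypes (aliphatic chains, sugars, simple
# heterocycles) whose fingerprints share little with flavonoid scaffolds
.decoy_templates <- c(
  "CCCCCCCC(=O)OCC(O)CO",
  "CC(C)CC(N)C(=O)NCC(=O)O",
  "OCC1OC(O)C(O)C(O)C1O",
  "c1ccncc1",
  "CCN(CC)CCOC(=O)C1CCCCC1",
  "CC1CCC(C(C)C)CC1",
  "O=S(=O)(N)c1ccc(N)cc1",
  "CCOC(=O)CC(=O)OCC",
  "NC1CCCCC1N",
  "CC(=O)NC1C(O)OC(CO)C(O)C1O")

#' Generate a synthetic screening library with planted near-duplicates
#'
#' Builds a SMILES library for testing fingerprint enrichment: "planted"
#' records are flavonoid seed scaffolds carrying at most a small peripheral
#' substituent edit (known-high similarity to their parent scaffold), and
#' "decoy" records are drawn from unrelated chemotypes decorated with small
#' aliphatic substituents. Truth labels (role, parent scaffold) ride along.
#'
#' @param n_decoys,n_planted Record counts (>= 0).
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List of class \code{screening_library}: \code{library} (data
#'   frame: id, smiles, role, parent), \code{seeds} (data frame: id,
#'   smiles — the undecorated parent scaffolds).
#' @examples
#' lib <- sim_screening_library(20, 5, seed = 7)
#' table(lib$library$role)
#' @export
sim_screening_library <- function(n_decoys = 200, n_planted = 10,
                                  seed = 1L) {
  stopifnot(is_count(n_decoys, 0), is_count(n_planted, 0), is_count(seed, 0))
  seeds <- data.frame(
    id = names(.planted_scaffolds),
    smiles = vapply(.planted_scaffolds, function(f) f(""), character(1)),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    rows <- list()
    if (n_planted > 0L) {
      fam <- sample(names(.planted_scaffolds), n_planted, replace = TRUE)
      for (k in seq_len(n_planted)) {
        sub <- sample(.planted_subs[[fam[k]]], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("planted%03d", k),
          smiles = .planted_scaffolds[[fam[k]]](sub),
          role = "planted", parent = fam[k], stringsAsFactors = FALSE)
      }
    }
    if (n_decoys > 0L) {
      tpl <- sample(.decoy_templates, n_decoys, replace = TRUE)
      dec <- sample(c("", "C", "CC", "O"), n_decoys, replace = TRUE)
      for (k in seq_len(n_decoys)) {
        smi <- if (nzchar(dec[k])) paste0(tpl[k], dec[k]) else tpl[k]
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("decoy%03d", k), smiles = smi,
          role = "decoy", parent = NA_character_, stringsAsFactors = FALSE)
      }
    }
    lib <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(), smiles = character(),
                 role = character(), parent = character())
    structure(list(library = lib, seeds = seeds),
              class = "screening_library")
  })
}
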