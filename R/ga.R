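#' Genetic-algorithm configuration for descriptor subset selection
#'
#' @param population Chromosomes per generation.
#' @param generations Number of generations.
#' @param k Descriptor subset size (chromosome cardinality).
#' @param crossover Crossover probability per mating pair.
#' @param mutation Per-bit swap-mutation probability.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param tournament Tournament size for parent selection.
#' @param fitness \code{"r2"} (training R-squared) or \code{"q2"}
#'   (leave-one-out Q2).
#' @param seed Integer random seed, recorded in all outputs.
#' @return Object of class \code{ga_config}.
#' @export
ga_config <- function(population = 100, generations = 200, k = 5,
                      crossover = 0.8, mutation = 0.02, elitism = 2,
                      tournament = 3, fitness = c("r2", "q2"),
                      seed = 20230807) {
  fitness <- match.arg(fitness)
  stopifnot(is_count(population, 2), is_count(generations),
            is_count(k), is_count(elitism, 0), is_count(tournament),
            is_number(crossover), crossover >= 0, crossover <= 1,
            is_number(mutation), mutation >= 0, mutation <= 1,
            is_count(seed, 0))
  structure(list(population = as.integer(population),
                 generations = as.integer(generations), k = as.integer(k),
                 crossover = crossover, mutation = mutation,
                 elitism = as.integer(elitism),
                 tournament = as.integer(tournament),
                 fitness = fitness, seed = as.integer(seed)),
            class = "ga_config")
}

.subset_fitness <- function(x, y, cols, type) {
  xs <- x[, cols, drop = FALSE]
  if (type == "q2")
    return(tryCatch(loo_q2(xs, y), error = function(e) -Inf))
  X <- cbind(1, xs)
  fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(X)) return(-Inf)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# repair a bit mask to cardinality k: deterministically ranked random
# add/remove
.repair_mask <- function(mask, k) {
  on <- which(mask)
  if (length(on) > k) {
    mask[sample(on, length(on) - k)] <- FALSE
  } else if (length(on) < k) {
    off <- which(!mask)
    mask[sample(off, k - length(on))] <- TRUE
  }
  mask
}

#' Select a descriptor subset by genetic algorithm
#'
#' Searches for the size-k descriptor subset maximizing the fitness of its
#' OLS pIC50 model. Chromosomes are fixed-cardinality bit masks evolved by
#' tournament selection, uniform crossover (repaired back to cardinality
#' k), per-bit swap mutation, and elitism; fitness values are cached per
#' subset. The per-generation best-fitness trace is monotone non-decreasing
#' because elitism always preserves the incumbent.
#'
#' @param x Numeric descriptor matrix (named columns, no \code{NA}).
#' @param y Activity vector.
#' @param cfg A [ga_config()].
#' @return List of class \code{ga_selection}: \code{names} (selected
#'   descriptors, matrix column order), \code{model} (the fitted
#'   [qsar_model()]), \code{fitness}, \code{trace} (best fitness per
#'   generation), \code{cfg}.
#' @export
ga_select <- function(x, y, cfg = ga_config()) {
  x <- as.matrix(x)
  stopifnot(inherits(cfg, "ga_config"), is.numeric(y),
            nrow(x) == length(y))
  if (anyNA(x) || anyNA(y)) stopf("masked cells in the modelling data")
  p <- ncol(x)
  if (p < cfg$k) stopf("k = %d exceeds the %d available descriptors",
                       cfg$k, p)
  if (length(y) <= cfg$k + 1L)
    stopf("need n > k + 1 observations for a k-descriptor fit")
  cache <- new.env(parent = emptyenv())
  fit_of <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- .subset_fitness(x, y, which(mask), cfg$fitness)
    cache[[key]] <- val
    val
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  if (p == cfg$k) {
    model <- qsar_fit(x, y, provenance = "GA selection (degenerate: k = p)")
    fitv <- .subset_fitness(x, y, seq_len(p), cfg$fitness)
    return(structure(list(names = colnames(x), model = model,
                          fitness = fitv, trace = fitv, cfg = cfg),
                     class = "ga_selection"))
  }

  pop <- replicate(cfg$population, {
    m <- rep(FALSE, p); m[sample.int(p, cfg$k)] <- TRUE; m
  }, simplify = FALSE)
  fitv <- vapply(pop, fit_of, numeric(1))
  trace <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fitv, decreasing = TRUE)
    elite <- pop[ord[seq_len(min(cfg$elitism, cfg$population))]]
    newpop <- elite
    while (length(newpop) < cfg$population) {
      pick <- function() {
        cand <- sample.int(cfg$population, cfg$tournament, replace = TRUE)
        pop[[cand[which.max(fitv[cand])]]]
      }
      a <- pick(); b <- pick()
      if (runif(1) < cfg$crossover) {
        take_a <- runif(p) < 0.5
        c1 <- ifelse(take_a, a, b)
        c2 <- ifelse(take_a, b, a)
      } else {
        c1 <- a; c2 <- b
      }
      for (child in list(c1, c2)) {
        # swap mutation: flip an on/off pair, preserving cardinality
        nswap <- stats::rbinom(1, cfg$k, cfg$mutation)
        if (nswap > 0) {
          on <- which(child); off <- which(!child)
          nswap <- min(nswap, length(on), length(off))
          child[sample(on, nswap)] <- FALSE
          child[sample(off, nswap)] <- TRUE
        }
        child <- .repair_mask(child, cfg$k)
        if (length(newpop) < cfg$population)
          newpop[[length(newpop) + 1L]] <- child
      }
    }
    pop <- newpop
    fitv <- vapply(pop, fit_of, numeric(1))
    trace[gen] <- max(fitv)
  }
  best <- pop[[which.max(fitv)]]
  sel <- colnames(x)[best]
  model <- qsar_fit(x[, best, drop = FALSE], y,
                    provenance = sprintf("GA selection (seed %d)", cfg$seed))
  structure(list(names = sel, model = model, fitness = max(fitv),
                 trace = trace, cfg = cfg),
            class = "ga_selection")
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("<ga_selection> k = %d, fitness (%s) = %.6f, seed = %d\n",
              x$cfg$k, x$cfg$fitness, x$fitness, x$cfg$seed))
  cat("  selected:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustively score every size-k descriptor subset
#'
#' Brute-force counterpart of [ga_select()] for small pools; used as an
#' oracle and for verifying GA convergence.
#'
#' @inheritParams ga_select
#' @param k Subset size.
#' @param fitness \code{"r2"} or \code{"q2"}.
#' @return List with \code{names}, \code{fitness} of the best subset.
#' @export
exhaustive_select <- function(x, y, k, fitness = c("r2", "q2")) {
  fitness <- match.arg(fitness)
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(is_count(k), k <= p)
  combos <- utils::combn(p, k)
  best <- -Inf; best_cols <- NULL
  for (j in seq_len(ncol(combos))) {
    f <- .subset_fitness(x, y, combos[, j], fitness)
    if (f > best) { best <- f; best_cols <- combos[, j] }
  }
  list(names = colnames(x)[best_cols], fitness = best)
}
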