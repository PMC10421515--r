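#' Enrich a candidate library against seed compounds
#'
#' For every library compound, the fingerprint similarity FS is the maximum
#' Tanimoto coefficient over all seed fingerprints; compounds are retained
#' when FS strictly exceeds the threshold. Each hit records its
#' best-matching seed and (when a clustering is supplied) its cluster id.
#'
#' @param seeds List of \code{fingerprint}s for the active seed set.
#' @param library List of \code{fingerprint}s for the candidate library
#'   (unique ids; duplicates are deduplicated, first occurrence kept).
#' @param threshold Strict FS cutoff in (0, 1]; default 0.8.
#' @param clustering Optional [cluster_library()] result for the library.
#' @return Data frame of class \code{screening_hits}: columns \code{id},
#'   \code{seed_id}, \code{fs}, \code{cluster} (NA without a clustering),
#'   one row per retained compound, in library order.
#' @export
enrich_library <- function(seeds, library, threshold = 0.8,
                           clustering = NULL) {
  stopifnot(is.list(seeds), is.list(library))
  if (length(seeds) == 0L) stopf("empty seed set")
  stopifnot(is_number(threshold), threshold > 0, threshold <= 1)
  lib_ids <- vapply(library, `[[`, character(1), "id")
  library <- library[!duplicated(lib_ids)]
  lib_ids <- lib_ids[!duplicated(lib_ids)]
  seed_ids <- vapply(seeds, `[[`, character(1), "id")
  rows <- lapply(seq_along(library), function(k) {
    sims <- vapply(seeds, tanimoto, numeric(1), b = library[[k]])
    best <- which.max(sims)
    if (sims[best] > threshold)
      data.frame(id = lib_ids[k], seed_id = seed_ids[best],
                 fs = sims[best], stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), seed_id = character(),
                      fs = numeric(), stringsAsFactors = FALSE)
  out$cluster <- if (!is.null(clustering))
    as.integer(clustering$cluster[out$id]) else
    rep(NA_integer_, nrow(out))
  class(out) <- c("screening_hits", "data.frame")
  out
}

#' Predict activity for screening hits and rank them
#'
#' Attaches model-predicted pIC50 (and the equivalent IC50 in micromolar)
#' to enrichment hits and sorts them in decreasing predicted potency, ties
#' broken by ascending compound id. Hits without a complete descriptor row
#' are dropped with a logged reason (attribute \code{"dropped"}).
#'
#' @param hits A [enrich_library()] result.
#' @param model A [qsar_model()].
#' @param descriptors Descriptor matrix with rows named by compound id.
#' @param top_n Optional: keep only the first \code{top_n} ranked rows.
#' @return The hits data frame with added \code{pic50_pre} and
#'   \code{ic50_pre_uM} columns, ranked.
#' @export
rank_candidates <- function(hits, model, descriptors, top_n = NULL) {
  stopifnot(inherits(model, "qsar_model"))
  descriptors <- as.matrix(descriptors)
  dropped <- data.frame(id = character(), reason = character())
  keep <- rep(TRUE, nrow(hits))
  need <- names(model$coefficients)
  missing_cols <- setdiff(need, colnames(descriptors))
  if (length(missing_cols))
    stopf("descriptor column(s) missing: %s",
          paste(missing_cols, collapse = ", "))
  for (r in seq_len(nrow(hits))) {
    id <- hits$id[r]
    if (!id %in% rownames(descriptors)) {
      keep[r] <- FALSE
      dropped <- rbind(dropped,
                       data.frame(id = id, reason = "no descriptor row"))
    } else if (anyNA(descriptors[id, need])) {
      keep[r] <- FALSE
      dropped <- rbind(dropped,
                       data.frame(id = id, reason = "masked descriptor"))
    }
  }
  out <- hits[keep, , drop = FALSE]
  if (nrow(out)) {
    out$pic50_pre <- unname(predict(model,
                                    descriptors[out$id, , drop = FALSE]))
    out$ic50_pre_uM <- ic50_from_pic50(out$pic50_pre)
    out <- out[order(-out$pic50_pre, out$id), , drop = FALSE]
  } else {
    out$pic50_pre <- numeric(0)
    out$ic50_pre_uM <- numeric(0)
  }
  if (!is.null(top_n)) {
    stopifnot(is_count(top_n, 0))
    out <- utils::head(out, top_n)
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("screening_hits", "data.frame")
  out
}

#' Join externally computed ADMET annotations onto screening hits
#'
#' Pure pass-through join (no property computation): ADMET fields supplied
#' by an external predictor are attached by compound id. Annotation ids
#' must be unique; hits without an annotation keep \code{NA} fields, hits
#' with unknown annotation ids are logged in attribute \code{"unmatched"}.
#'
#' @param hits A ranked [rank_candidates()] data frame.
#' @param annotations Data frame keyed by an \code{id} column; remaining
#'   columns are joined verbatim.
#' @return The annotated hits data frame.
#' @export
annotate_admet <- function(hits, annotations) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) == 0L || ncol(annotations) < 2L) {
    attr(hits, "unmatched") <- character(0)
    return(hits)
  }
  if (!"id" %in% names(annotations))
    stopf("annotation table needs an 'id' column")
  if (anyDuplicated(annotations$id))
    stopf("duplicate annotation id(s): %s",
          paste(unique(annotations$id[duplicated(annotations$id)]),
                collapse = ", "))
  idx <- match(hits$id, annotations$id)
  for (col in setdiff(names(annotations), "id"))
    hits[[col]] <- annotations[[col]][idx]
  attr(hits, "unmatched") <- setdiff(annotations$id, hits$id)
  class(hits) <- c("screening_hits", "data.frame")
  hits
}
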