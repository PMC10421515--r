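#' Read and write descriptor matrices as CSV
#'
#' First column \code{id}, header row of canonical descriptor names, empty
#' cells for masked values.
#'
#' @param x Descriptor matrix (rows named by compound id).
#' @param path Output / input file path.
#' @return \code{write_descriptor_csv} returns \code{path} invisibly;
#'   \code{read_descriptor_csv} returns a numeric matrix with row names.
#' @export
write_descriptor_csv <- function(x, path) {
  x <- as.matrix(x)
  df <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stopf("descriptor CSV needs an 'id' column")
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' Read a compound activity table
#'
#' CSV with columns \code{id}, optional \code{ic50_uM}, optional
#' \code{pic50}, and \code{partition} (train/test). When both IC50 and
#' pIC50 are present their consistency with
#' \code{pic50 = -log10(ic50_uM * 1e-6)} is enforced to 5e-4; when pIC50 is
#' absent it is derived from IC50.
#'
#' @param path CSV path.
#' @return Data frame with \code{id}, \code{pic50}, \code{partition} (and
#'   \code{ic50_uM} when supplied).
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stopf("activity CSV needs an 'id' column")
  has_ic <- "ic50_uM" %in% names(df)
  has_p <- "pic50" %in% names(df)
  if (!has_ic && !has_p) stopf("activity CSV needs ic50_uM and/or pic50")
  if (has_ic && has_p) {
    both <- !is.na(df$ic50_uM) & !is.na(df$pic50)
    dev <- abs(df$pic50[both] - pic50_from_ic50(df$ic50_uM[both]))
    if (any(dev > 5e-4))
      stopf("pic50 and ic50_uM disagree for id(s): %s",
            paste(df$id[both][dev > 5e-4], collapse = ", "))
  }
  if (!has_p) df$pic50 <- pic50_from_ic50(df$ic50_uM)
  if (!"partition" %in% names(df)) df$partition <- "train"
  bad <- !df$partition %in% c("train", "test")
  if (any(bad))
    stopf("partition must be train/test; offending id(s): %s",
          paste(df$id[bad], collapse = ", "))
  if (anyDuplicated(df$id))
    stopf("duplicate compound id(s) in activity table")
  df
}

#' Serialize a fitted model (with provenance) to JSON and back
#'
#' @param model A [qsar_model()].
#' @param path JSON file path.
#' @param extra Optional named list stored alongside (e.g. GA config, seed).
#' @return \code{write_model_json} returns \code{path} invisibly;
#'   \code{read_model_json} returns the [qsar_model()] with attribute
#'   \code{"extra"}.
#' @export
write_model_json <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "qsar_model"))
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              provenance = model$provenance,
              extra = extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- qsar_model(obj$intercept, unlist(obj$coefficients),
                  provenance = obj$provenance %||% "from JSON")
  attr(m, "extra") <- obj$extra
  m
}

#' Write a validation report as JSON or plain text
#'
#' @param report A [qsar_validate()] result.
#' @param path Output path.
#' @param format \code{"json"} or \code{"text"}.
#' @return \code{path}, invisibly.
#' @export
write_validation_report <- function(report, path,
                                    format = c("json", "text")) {
  stopifnot(inherits(report, "validation_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(path)
}

#' Write screening hits as CSV or JSON
#'
#' @param hits A [rank_candidates()] (or [enrich_library()]) data frame.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_hits <- function(hits, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(hits)
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE, na = "")
  else jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ADMET annotation table (CSV keyed by compound id)
#'
#' @param path CSV path with an \code{id} column.
#' @return Data frame.
#' @export
read_admet_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stopf("ADMET CSV needs an 'id' column")
  df
}
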