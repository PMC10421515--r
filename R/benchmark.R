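# pinned md5 checksums of the shipped fixture files
.fixture_md5 <- c(
  pl_activity_benchmark.csv = "a0ca2d34aed75d973350ad9627dabfb4",
  pl_candidates.csv         = "cfc6de5b42ce93ea3b24cc8eebbb17b9",
  flavonoids_synthetic.smi  = "edfcf4c3a07a687b0cb908a8d835b7a0")

#' Load the embedded 40-flavonoid pancreatic lipase benchmark
#'
#' Returns the package's embedded benchmark for flavonoid pancreatic-lipase
#' inhibition: the 40-compound activity table (experimental pIC50, predicted
#' pIC50, absolute residual, 29-train / 11-test partition), the reference
#' five-descriptor MLR model, the five top-ranked natural-product candidates
#' with externally predicted IC50 and ADMET annotations, and a curated
#' (partly reconstructed, see the fixture file header) SMILES table for the
#' 40 compounds.
#'
#' The loader self-checks the fixture: pinned md5 checksums, the 29/11
#' partition, and the residual identity
#' \code{abs(pic50_exp - pic50_pred) == residual} to 1e-3 on every row. It
#' also adds a \code{pic50_pred_refined} column: the predicted values are
#' printed to 3 decimals, but the signed residual column pins them one step
#' tighter, so \code{pic50_exp - sign(pic50_exp - pic50_pred) * residual}
#' reconstructs the predictions at the residual column's precision.
#'
#' @return List of class \code{pl_benchmark} with elements \code{activity}
#'   (data frame), \code{model} ([qsar_model()]), \code{candidates}
#'   (data frame), \code{smiles} (data frame with \code{id}, \code{smiles}).
#' @examples
#' bench <- load_pl_benchmark()
#' table(bench$activity$partition)
#' @export
load_pl_benchmark <- function() {
  dir <- system.file("extdata", package = "plqsar")
  paths <- file.path(dir, names(.fixture_md5))
  sums <- tools::md5sum(paths)
  bad <- names(.fixture_md5)[is.na(sums) | sums != .fixture_md5]
  if (length(bad))
    stopf("fixture checksum mismatch: %s", paste(bad, collapse = ", "),
          class = "plqsar_fixture_error")
  act <- utils::read.csv(paths[1L], stringsAsFactors = FALSE)
  if (nrow(act) != 40L || sum(act$partition == "train") != 29L ||
      sum(act$partition == "test") != 11L)
    stopf("benchmark activity table must hold 29 train + 11 test rows",
          class = "plqsar_fixture_error")
  dev <- abs(abs(act$pic50_exp - act$pic50_pred) - act$residual)
  if (max(dev) > 1e-3 + 1e-12)
    stopf("residual identity violated for row(s): %s",
          paste(act$name[dev > 1e-3 + 1e-12], collapse = ", "),
          class = "plqsar_fixture_error")
  act$pic50_pred_refined <-
    act$pic50_exp - sign(act$pic50_exp - act$pic50_pred) * act$residual
  cand <- utils::read.csv(paths[2L], stringsAsFactors = FALSE)
  lines <- readLines(paths[3L], warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  smi <- data.frame(smiles = sub("\\s.*$", "", lines),
                    id = trimws(sub("^\\S+", "", lines)),
                    stringsAsFactors = FALSE)[, c("id", "smiles")]
  if (!setequal(smi$id, act$name))
    stopf("SMILES fixture ids do not match the activity table",
          class = "plqsar_fixture_error")
  structure(list(activity = act, model = pl_reference_model(),
                 candidates = cand, smiles = smi),
            class = "pl_benchmark")
}

#' @export
print.pl_benchmark <- function(x, ...) {
  cat("<pl_benchmark> 40 flavonoids (29 train / 11 test),",
      nrow(x$candidates), "screened candidates\n")
  invisible(x)
}
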