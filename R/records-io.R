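#' Read and write survival / behaviour record tables
#'
#' Thin CSV wrappers around the record schemas: columns are exactly the
#' fields documented in [genPredation()] and [genBehavior()], and the
#' readers validate them on import (a behaviour file with a `sex` column
#' has males excluded, since the phenotypic models are fitted on females).
#'
#' @param path CSV file path.
#' @param records a record data.frame.
#' @return the validated data.frame (readers) or `path` invisibly
#'   (writers).
#' @name records-io
NULL

#' @rdname records-io
#' @export
readSurvivalRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$replacement <- as.logical(rec$replacement)
  checkSurvivalRecords(rec)
  rec
}

#' @rdname records-io
#' @export
writeSurvivalRecords <- function(records, path) {
  checkSurvivalRecords(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname records-io
#' @export
readBehaviorRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  checkBehaviorRecords(rec)
}

#' @rdname records-io
#' @export
writeBehaviorRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
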