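#' Feature-by-sample count matrix with a normalization state
#'
#' A thin wrapper around a numeric matrix (features in rows, samples in
#' columns) that records how far along the normalization pipeline the values
#' are: `raw` (summed estimated reads), `normalized` (divided by size
#' factors), `log` (log2(normalized + 1)) or `zscore` (per-feature centred
#' and scaled).
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param state One of `"raw"`, `"normalized"`, `"log"`, `"zscore"`.
#' @param ... Further attributes to attach (e.g. `assigned_reads`).
#' @return A `CountMatrix`.
#' @export
count_matrix <- function(m, state = c("raw", "normalized", "log", "zscore"), ...) {
  state <- match.arg(state)
  stopifnot(is.matrix(m), is.numeric(m),
            !is.null(rownames(m)), !is.null(colnames(m)))
  if (state %in% c("raw", "normalized") && any(m < 0)) {
    stop("negative entries not allowed in ", state, " state")
  }
  extra <- list(...)
  for (nm in names(extra)) attr(m, nm) <- extra[[nm]]
  attr(m, "state") <- state
  class(m) <- c("CountMatrix", "matrix", "array")
  m
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", nrow(x), " features x ", ncol(x),
      " samples [state: ", cm_state(x), "]\n", sep = "")
  invisible(x)
}

#' @rdname count_matrix
#' @param x A `CountMatrix`.
#' @export
cm_state <- function(x) attr(x, "state")

#' @export
as.matrix.CountMatrix <- function(x, ...) {
  attrs <- names(attributes(x))
  for (nm in setdiff(attrs, c("dim", "dimnames"))) attr(x, nm) <- NULL
  class(x) <- NULL
  x
}

#' Write / read a count matrix TSV with a state sidecar
#'
#' The matrix goes to `<path>` (first column `feature_id`); the
#' normalization state and matrix shape go to `<path>.json`.
#' @param cm A `CountMatrix`.
#' @param path Output TSV path.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm), as.matrix(cm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(state = cm_state(cm), n_features = nrow(cm),
                            n_samples = ncol(cm)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  sidecar <- paste0(path, ".json")
  state <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$state
  } else "raw"
  count_matrix(m, state = state)
}
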