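#' Write an analysis report to a self-describing JSON file
#'
#' Every result object in the package (agreement battery pieces, fuzzy
#' C-means results, fitted fuzzy inference systems, relative-risk results,
#' ...) serializes to one hierarchical JSON layout: a metadata envelope
#' (schema version, package version, result class, optional MD5 checksum of
#' the input file) around a lossless payload encoding of the R
#' object. Doubles are written with 17 significant digits so that
#' `read_report(write_report(x))` reproduces `x` bit-for-bit; a fitted model
#' saved and reloaded predicts identically to full precision.
#'
#' Reports containing non-finite numeric values are refused: a NaN or
#' infinity in a saved result almost always indicates a degenerate upstream
#' computation that should be handled before archiving.
#'
#' @param report any package result object (a list-based S3 object).
#' @param path output file path.
#' @param input_path optional path of the raw input table; when given its
#'   MD5 checksum is embedded in the envelope.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path, input_path = NULL) {
  nf <- find_non_finite(report)
  if (!is.null(nf)) {
    stop("report contains a non-finite value at field '", nf,
         "'; refusing to serialize", call. = FALSE)
  }
  payload <- jsonlite::fromJSON(
    jsonlite::serializeJSON(report, digits = I(17)),
    simplifyVector = FALSE
  )
  envelope <- list(
    schema_version = 1L,
    package = "fuzzyagree",
    package_version = as.character(utils::packageVersion("fuzzyagree")),
    class = class(report)[1],
    input_md5 = if (is.null(input_path)) NA_character_ else
      unname(tools::md5sum(input_path)),
    payload = payload
  )
  txt <- jsonlite::toJSON(envelope, auto_unbox = TRUE, digits = I(17),
                          pretty = TRUE, null = "null", na = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path path to a report JSON file.
#' @return The original R object, reconstructed exactly. The envelope
#'   metadata are attached as attribute `"report_meta"`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  envelope <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                 simplifyVector = FALSE)
  if (is.null(envelope$schema_version) || is.null(envelope$payload)) {
    stop("'", path, "' is not a fuzzyagree report file", call. = FALSE)
  }
  obj <- jsonlite::unserializeJSON(
    jsonlite::toJSON(envelope$payload, auto_unbox = TRUE, digits = I(17))
  )
  meta <- envelope[setdiff(names(envelope), "payload")]
  attr(obj, "report_meta") <- meta
  obj
}

# depth-first search for a non-finite numeric; returns a dotted field path
# or NULL when the object is clean
find_non_finite <- function(x, path = "") {
  if (is.numeric(x)) {
    if (any(!is.finite(x))) return(if (nzchar(path)) path else "<root>")
    return(NULL)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      label <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else
        sprintf("[[%d]]", i)
      sub <- find_non_finite(x[[i]],
                             if (nzchar(path)) paste(path, label, sep = ".")
                             else label)
      if (!is.null(sub)) return(sub)
    }
  }
  NULL
}
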