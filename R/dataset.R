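#' Construct a paired-assay dataset
#'
#' A `paired_dataset` holds one row per subject: an identifier, demographics
#' (age in years, sex), and the two 25(OH)D assay results in ng/mL — the
#' chemiluminescence immunoassay (CLIA) value and the LC-MS/MS value. The
#' inter-method difference `diff = lcms - clia` is always recomputed here,
#' never trusted from the caller or an input file.
#'
#' @param sample_id character vector of unique subject identifiers.
#' @param age numeric, years; must lie in (0, 120).
#' @param sex character or factor with levels `"male"`/`"female"` (aliases are
#'   resolved by [read_paired_dataset()], not here).
#' @param clia numeric, ng/mL; finite and non-negative.
#' @param lcms numeric, ng/mL; finite and non-negative.
#' @param provenance free-text label recording where the rows came from.
#'
#' @return A data frame of class `paired_dataset` with columns `sample_id`,
#'   `age`, `sex`, `clia`, `lcms`, `diff` and a `provenance` attribute.
#' @examples
#' d <- paired_dataset(c("a", "b", "c"), c(30, 45, 60),
#'                     c("female", "male", "female"),
#'                     clia = c(18, 25, 12), lcms = c(20, 26, 13))
#' d$diff
#' @export
paired_dataset <- function(sample_id, age, sex, clia, lcms,
                           provenance = "unspecified") {
  sample_id <- as.character(sample_id)
  sex <- as.character(sex)
  n <- length(sample_id)
  if (length(age) != n || length(sex) != n || length(clia) != n ||
      length(lcms) != n) {
    stop("all columns must have the same length", call. = FALSE)
  }
  bad <- validate_rows(age, sex, clia, lcms)
  if (length(bad$messages) > 0) {
    stop("invalid rows:\n  ",
         paste(sprintf("row %d: %s", bad$idx, bad$messages),
               collapse = "\n  "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample_id value(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    sample_id = sample_id,
    age = as.numeric(age),
    sex = factor(sex, levels = c("male", "female")),
    clia = as.numeric(clia),
    lcms = as.numeric(lcms),
    stringsAsFactors = FALSE
  )
  out$diff <- out$lcms - out$clia
  attr(out, "provenance") <- provenance
  class(out) <- c("paired_dataset", "data.frame")
  out
}

# per-row validation; returns parallel vectors of row indices and messages
validate_rows <- function(age, sex, clia, lcms) {
  msgs <- character(0)
  idx <- integer(0)
  flag <- function(i, what) {
    idx <<- c(idx, i)
    msgs <<- c(msgs, what)
  }
  for (i in seq_along(age)) {
    if (!is.finite(age[i]) || age[i] <= 0 || age[i] >= 120)
      flag(i, sprintf("age %s outside (0, 120)", format(age[i])))
    if (!sex[i] %in% c("male", "female"))
      flag(i, sprintf("unrecognised sex '%s'", sex[i]))
    if (!is.finite(clia[i]) || clia[i] < 0)
      flag(i, sprintf("clia value '%s' not a finite non-negative number",
                      format(clia[i])))
    if (!is.finite(lcms[i]) || lcms[i] < 0)
      flag(i, sprintf("lcms value '%s' not a finite non-negative number",
                      format(lcms[i])))
  }
  list(idx = idx, messages = msgs)
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("paired_dataset: %d samples (%s)\n", nrow(x),
              attr(x, "provenance")))
  cat(sprintf("  %.1f%% female; age %.1f +/- %.1f y\n",
              100 * mean(x$sex == "female"), mean(x$age), stats::sd(x$age)))
  cat(sprintf("  CLIA %.2f +/- %.2f ng/mL; LC-MS/MS %.2f +/- %.2f ng/mL; diff %.2f +/- %.2f ng/mL\n",
              mean(x$clia), stats::sd(x$clia), mean(x$lcms), stats::sd(x$lcms),
              mean(x$diff), stats::sd(x$diff)))
  invisible(x)
}

#' Default sex aliasing table
#'
#' Maps common raw codings onto the canonical `male`/`female` levels,
#' case-insensitively. Clinical exports rarely agree on a coding, so the map
#' is configuration rather than a constant.
#'
#' @return Named character vector: names are lower-cased raw values, values
#'   are `"male"` or `"female"`.
#' @export
default_sex_aliases <- function() {
  c(male = "male", m = "male", "0" = "male",
    female = "female", f = "female", "1" = "female")
}

#' Sex-to-numeric encoding for model inputs
#'
#' The fuzzy inference system takes sex as a numeric input; the coding is
#' arbitrary as long as the two levels differ, and model predictions are
#' invariant to swapping it (covered by tests). Default: male = 0, female = 1.
#'
#' @param male_code,female_code distinct finite numerics.
#' @return A list of class `sex_encoding`.
#' @export
sex_encoding <- function(male_code = 0, female_code = 1) {
  if (!is.finite(male_code) || !is.finite(female_code) ||
      male_code == female_code) {
    stop("male_code and female_code must be distinct finite numbers",
         call. = FALSE)
  }
  structure(list(male_code = male_code, female_code = female_code),
            class = "sex_encoding")
}

encode_sex <- function(sex, encoding) {
  ifelse(as.character(sex) == "female", encoding$female_code,
         encoding$male_code)
}

#' Read a paired-assay table from delimited text
#'
#' Accepts comma- or tab-separated text with a header row (the delimiter is
#' sniffed from the header line). Column names are mapped onto the five
#' canonical fields through `col_map`; sex values are resolved through a
#' case-insensitive alias table. Rows that fail validation are rejected with
#' line-numbered diagnostics; the difference column, if present in the file,
#' is ignored and recomputed.
#'
#' @param path path to a CSV/TSV file.
#' @param col_map named character vector mapping canonical field names
#'   (`sample_id`, `age`, `sex`, `clia`, `lcms`) to the file's column names.
#' @param sex_aliases alias table as produced by [default_sex_aliases()].
#' @param provenance provenance label; defaults to the file path.
#' @return A [paired_dataset()].
#' @export
read_paired_dataset <- function(path,
                                col_map = c(sample_id = "sample_id",
                                            age = "age", sex = "sex",
                                            clia = "clia", lcms = "lcms"),
                                sex_aliases = default_sex_aliases(),
                                provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  needed <- c("sample_id", "age", "sex", "clia", "lcms")
  missing_map <- setdiff(needed, names(col_map))
  if (length(missing_map) > 0) {
    stop("col_map lacks entries for: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  absent <- col_map[needed][!col_map[needed] %in% names(raw)]
  if (length(absent) > 0) {
    stop("input table lacks column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sid <- raw[[col_map[["sample_id"]]]]
  age <- suppressWarnings(as.numeric(raw[[col_map[["age"]]]]))
  sex_raw <- tolower(trimws(raw[[col_map[["sex"]]]]))
  sex <- unname(sex_aliases[sex_raw])
  sex[is.na(sex)] <- sex_raw[is.na(sex)]   # leave unknowns for validation
  clia <- suppressWarnings(as.numeric(raw[[col_map[["clia"]]]]))
  lcms <- suppressWarnings(as.numeric(raw[[col_map[["lcms"]]]]))

  age[is.na(age)] <- NaN
  clia[is.na(clia)] <- NaN
  lcms[is.na(lcms)] <- NaN
  bad <- validate_rows(age, sex, clia, lcms)
  if (length(bad$messages) > 0) {
    # +1 for the header line: report file line numbers, not data-frame rows
    stop("rejected rows:\n  ",
         paste(sprintf("line %d: %s", bad$idx + 1L, bad$messages),
               collapse = "\n  "),
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample_id value(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  paired_dataset(sid, age, sex, clia, lcms, provenance = provenance)
}

#' Write a paired-assay table
#'
#' Writes the canonical five input columns (plus the recomputed difference)
#' as comma-separated text, the same shape [read_paired_dataset()] accepts.
#'
#' @param data a [paired_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paired_dataset <- function(data, path) {
  stopifnot(inherits(data, "paired_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
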