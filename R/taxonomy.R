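#' Land-cover taxonomy table
#'
#' Loads the 19-type land-cover taxonomy used throughout the package: each
#' type (identified by a three-letter code, e.g. `OPL` for oil palm
#' plantation) carries its full name, its high-level class (9 classes), and
#' its aggregation to the three-class (`P`/`F`/`O`), four-class
#' (`P`/`F`/`B`/`O`, `B` = bare soil) and binary (`P`/`nonP`) schemes.
#'
#' The mapping is data, not code: an alternative taxonomy with the same
#' column contract (`code`, `full_name`, `high_level`, `aggregated3`,
#' `aggregated4`, `aggregated2`) can be supplied via `path`. Totality is
#' enforced strictly: every code must map to exactly one label in every
#' scheme.
#'
#' @param path Path to a taxonomy CSV. Default: the packaged table.
#' @return A data.frame with one row per land-cover code.
#' @export
#' @examples
#' tax <- taxonomy()
#' nrow(tax)  # 19
taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxonomy.csv", package = "plantmapr")
  }
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  tax <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("code", "full_name", "high_level",
                "aggregated3", "aggregated4", "aggregated2")
  missing_cols <- setdiff(required, names(tax))
  if (length(missing_cols) > 0) {
    stop("taxonomy table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tax$code)) stop("duplicated land-cover codes in taxonomy")
  if (any(is.na(tax[required]))) stop("taxonomy table contains missing values")
  bad3 <- setdiff(unique(tax$aggregated3), c("P", "F", "O"))
  if (length(bad3) > 0) {
    stop("aggregated3 labels must be P/F/O, found: ", paste(bad3, collapse = ", "))
  }
  tax
}

#' Build a class scheme over the taxonomy
#'
#' A class scheme is a named, ordered label set plus a total mapping from
#' the 19 land-cover codes onto those labels. Five schemes are supported:
#'
#' * `"binary"` — `P`, `nonP` (forest and other merged into non-plantation);
#' * `"three"` — `P` (plantation), `F` (forest), `O` (other), the scheme the
#'   pairwise ensemble is built on;
#' * `"four"` — adds `B` (bare soil) carved out of `O`;
#' * `"nine"` — the high-level classes;
#' * `"nineteen"` — the codes themselves.
#'
#' @param name One of `"binary"`, `"three"`, `"four"`, `"nine"`, `"nineteen"`.
#' @param tax A taxonomy table from [taxonomy()].
#' @return An object of class `class_scheme`: list with `name`, `labels`
#'   (ordered character vector) and `mapping` (named character vector,
#'   code -> label).
#' @export
#' @examples
#' sc <- class_scheme("three")
#' sc$labels                       # "P" "F" "O"
#' aggregate_code("OPL", sc)       # "P"
class_scheme <- function(name = c("three", "binary", "four", "nine", "nineteen"),
                         tax = taxonomy()) {
  name <- match.arg(name)
  nine_labels <- c("Oil palm", "Timber plantation", "Agriculture", "Built-up",
                   "Mining", "Bare soil", "Water body", "Disturbed forest",
                   "Undisturbed forest")
  mapping <- switch(name,
    binary   = stats::setNames(tax$aggregated2, tax$code),
    three    = stats::setNames(tax$aggregated3, tax$code),
    four     = stats::setNames(tax$aggregated4, tax$code),
    nine     = stats::setNames(tax$high_level, tax$code),
    nineteen = stats::setNames(tax$code, tax$code)
  )
  labels <- switch(name,
    binary   = c("P", "nonP"),
    three    = c("P", "F", "O"),
    four     = c("P", "F", "B", "O"),
    nine     = nine_labels,
    nineteen = tax$code
  )
  extra <- setdiff(unique(mapping), labels)
  if (length(extra) > 0) {
    stop("taxonomy maps to labels outside the '", name, "' scheme: ",
         paste(extra, collapse = ", "))
  }
  structure(list(name = name, labels = labels, mapping = mapping),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme>", x$name, "with", length(x$labels), "labels:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate land-cover codes to a scheme label
#'
#' @param code Character vector of land-cover codes.
#' @param scheme A [class_scheme()].
#' @return Character vector of scheme labels, same length as `code`.
#' @export
aggregate_code <- function(code, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  out <- unname(scheme$mapping[code])
  if (anyNA(out)) {
    bad <- unique(code[is.na(out)])
    stop("unknown land-cover code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Ordered label list of a scheme
#'
#' @param scheme A [class_scheme()].
#' @return Character vector of the scheme's labels in their fixed order.
#' @export
scheme_classes <- function(scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  scheme$labels
}

#' Subclasses (codes) belonging to each label of a scheme
#'
#' @param scheme A [class_scheme()].
#' @return Named list: scheme label -> character vector of codes.
#' @export
scheme_subclasses <- function(scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  codes <- names(scheme$mapping)
  split(codes, factor(unname(scheme$mapping), levels = scheme$labels))
}
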