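#' Normalize a drug name to canonical form
#'
#' Canonical form is lowercase, trimmed, with internal runs of whitespace
#' collapsed to single spaces. All matching anywhere in the package happens
#' on canonical names, so `"Ubrogepant"` and `"ubrogepant "` denote the same
#' drug. Normalization is idempotent.
#'
#' @param raw Character vector of raw drug names.
#' @return Character vector of canonical names, same length as `raw`.
#' @examples
#' normalize_drug_name("Ubrogepant")
#' normalize_drug_name("  Mefenamic   Acid ")
#' @export
normalize_drug_name <- function(raw) {
  if (!is.character(raw)) {
    ddi_error("ddi_invalid_name", "drug names must be a character vector")
  }
  out <- tolower(gsub("[[:space:]]+", " ", trimws(raw)))
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    ddi_error("ddi_invalid_name",
              sprintf("empty or missing drug name at position %s",
                      paste(which(bad), collapse = ", ")))
  }
  out
}

#' Construct a drug universe
#'
#' A drug universe is the ordered set of canonical drug names over which
#' combinations are enumerated. Input order is preserved; names are
#' normalized with [normalize_drug_name()].
#'
#' @param names Character vector of drug names.
#' @return A `ddi_universe`: a character vector of canonical names.
#' @examples
#' drug_universe(c("Aspirin", "Naproxen", "Sumatriptan"))
#' @export
drug_universe <- function(names) {
  canon <- normalize_drug_name(names)
  if (anyDuplicated(canon)) {
    dup <- canon[duplicated(canon)][1L]
    pair <- names[canon == dup]
    ddi_error("ddi_duplicate_drug",
              sprintf("duplicate drug after normalization: %s",
                      paste(sQuote(pair), collapse = " and ")))
  }
  if (length(canon) == 0L) {
    ddi_error("ddi_empty_universe", "drug universe is empty")
  }
  structure(canon, class = "ddi_universe")
}

#' @export
print.ddi_universe <- function(x, ...) {
  cat(sprintf("<ddi_universe> %d drugs\n", length(x)))
  cat(strwrap(paste(unclass(x), collapse = ", "), width = 76, prefix = "  "),
      sep = "\n")
  invisible(x)
}

#' @export
as.character.ddi_universe <- function(x, ...) unclass(x)

# Read non-comment, non-blank lines from a plain-text list file.
read_list_lines <- function(path) {
  if (!file.exists(path)) {
    ddi_error("ddi_missing_file", sprintf("file not found: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Load a drug universe from a text file
#'
#' One drug name per line; blank lines and lines starting with `#` are
#' ignored. Names are normalized and must be unique after normalization.
#'
#' @param path Path to the drug list file.
#' @return A [drug_universe()].
#' @export
read_drug_list <- function(path) {
  lines <- read_list_lines(path)
  if (length(lines) == 0L) {
    ddi_error("ddi_empty_universe", sprintf("no drug names in %s", path))
  }
  drug_universe(lines)
}

#' Write a drug universe to a text file
#'
#' Writes one canonical name per line, so `read_drug_list(write_drug_list(u))`
#' round-trips exactly.
#'
#' @param universe A [drug_universe()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_list <- function(universe, path) {
  writeLines(as.character(universe), path)
  invisible(path)
}

#' Construct a drug-class map
#'
#' Maps every universe drug to a class label; drugs without an assignment
#' default to class `"other"`.
#'
#' @param universe A [drug_universe()].
#' @param assignments Named character vector: names are drug names (any
#'   casing), values are class labels. May be empty.
#' @return A `ddi_class_map`: named character vector with one label per
#'   universe drug, in universe order.
#' @export
class_map <- function(universe, assignments = character()) {
  map <- stats::setNames(rep("other", length(universe)), as.character(universe))
  if (length(assignments)) {
    keys <- normalize_drug_name(names(assignments))
    unknown <- setdiff(keys, as.character(universe))
    if (length(unknown)) {
      ddi_warning("ddi_unknown_drug_warning",
                  sprintf("class map names drugs outside the universe (ignored): %s",
                          paste(unknown, collapse = ", ")))
    }
    keep <- keys %in% as.character(universe)
    map[keys[keep]] <- as.character(assignments)[keep]
  }
  structure(map, class = "ddi_class_map")
}

# Split delimited two-column lines, auto-detecting tab vs comma.
split_map_line <- function(line, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\t", line, fixed = TRUE)) "\t" else ","
  strsplit(line, sep, fixed = TRUE)[[1L]]
}

#' Load a drug-class map from a delimited file
#'
#' Two columns (drug, class), tab- or comma-delimited; the delimiter is
#' auto-detected per line unless `sep` is given. Drugs listed in the file
#' but absent from the universe are ignored with a warning; universe drugs
#' not listed default to class `"other"`.
#'
#' @param path Path to the class-map file.
#' @param universe A [drug_universe()].
#' @param sep Optional delimiter override (`"\t"` or `","`).
#' @return A [class_map()].
#' @export
read_class_map <- function(path, universe, sep = NULL) {
  if (!file.exists(path)) {
    ddi_error("ddi_missing_file", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  assignments <- character()
  for (i in which(keep)) {
    fields <- trimws(split_map_line(lines[[i]], sep))
    if (length(fields) != 2L || any(!nzchar(fields))) {
      ddi_error("ddi_parse_error",
                sprintf("malformed class-map row at %s line %d: %s",
                        path, i, sQuote(lines[[i]])))
    }
    assignments[[fields[[1L]]]] <- fields[[2L]]
  }
  class_map(universe, assignments)
}

#' Load an allow-list of drugs
#'
#' One drug name per line (`#` comments ignored). Every member must belong
#' to the universe; unknown members are an error naming the offenders, never
#' silently dropped.
#'
#' @param path Path to the allow-list file.
#' @param universe A [drug_universe()].
#' @return Character vector of canonical names (class `ddi_allowlist`).
#' @export
read_allow_list <- function(path, universe) {
  members <- unique(normalize_drug_name(read_list_lines(path)))
  allow_list(members, universe)
}

#' @rdname read_allow_list
#' @param members Character vector of drug names.
#' @export
allow_list <- function(members, universe) {
  members <- unique(normalize_drug_name(members))
  unknown <- setdiff(members, as.character(universe))
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("allow-list members outside the universe: %s",
                      paste(unknown, collapse = ", ")))
  }
  structure(members, class = "ddi_allowlist")
}
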