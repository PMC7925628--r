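# Results-style summaries over a screened family: per-drug inclusion
# counts, per-class tallies, size distribution with raw ratios, and the
# allow-list restriction.

#' Per-drug inclusion counts
#'
#' For every universe drug, the number of family combinations containing
#' it — including zeros for drugs that survive in no combination. The sum
#' of all counts equals the sum of combination sizes over the family.
#'
#' @param family A `ddi_family`.
#' @param universe A [drug_universe()] covering the family.
#' @return Data.frame with columns `drug` and `count`, sorted by
#'   descending count then drug name.
#' @export
inclusion_counts <- function(family, universe) {
  drugs <- as.character(universe)
  tab <- table(factor(unlist(family$combinations), levels = drugs))
  out <- data.frame(drug = drugs, count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$drug), ]
  rownames(out) <- NULL
  out
}

#' Per-class inclusion tallies
#'
#' Sums member inclusion counts within each class: a combination holding
#' two same-class drugs contributes twice to that class. Drugs without an
#' explicit class fall under `"other"`.
#'
#' @param counts Data.frame from [inclusion_counts()].
#' @param classes A [class_map()] over the same universe.
#' @return Data.frame with columns `class` and `total`, sorted by
#'   descending total then class name.
#' @export
class_tally <- function(counts, classes) {
  label <- unname(unclass(classes)[counts$drug])
  label[is.na(label)] <- "other"
  agg <- tapply(counts$count, label, sum)
  out <- data.frame(class = names(agg), total = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$class), ]
  rownames(out) <- NULL
  out
}

#' Combination-size distribution of a family
#'
#' Per size k in the family's window: the survivor count, its share of the
#' family, the number C(a, k) of possible combinations, and the raw
#' survivor fraction count / C(a, k). Shares are raw ratios; any rounding
#' is presentation only.
#'
#' @param family A `ddi_family`.
#' @param universe A [drug_universe()]; its size sets the C(a, k) column.
#' @return Data.frame with columns `size`, `count`, `family_share`,
#'   `possible`, `survivor_fraction`.
#' @export
size_distribution <- function(family, universe) {
  a <- length(universe)
  ks <- family$k_min:family$k_max
  counts <- as.integer(table(factor(lengths(family$combinations), levels = ks)))
  total <- sum(counts)
  possible <- choose(a, ks)
  data.frame(size = ks,
             count = counts,
             family_share = if (total > 0) counts / total else rep(0, length(ks)),
             possible = possible,
             survivor_fraction = ifelse(possible > 0, counts / possible, 0),
             stringsAsFactors = FALSE)
}

#' Restrict a family to an allow-list of drugs
#'
#' Keeps exactly the combinations all of whose members belong to the
#' allow-list. Because membership filtering removes whole combinations but
#' never members, the result is still hereditary; the operation is
#' idempotent and its output is always a subset of the input.
#'
#' @param family A `ddi_family`.
#' @param allow An [allow_list()] or character vector of drug names.
#' @return A `ddi_family` over the same universe.
#' @export
filter_allowlist <- function(family, allow) {
  allow <- if (length(allow)) unique(normalize_drug_name(allow)) else character()
  keep <- vapply(family$combinations, function(m) all(m %in% allow), logical(1))
  new_ddi_family(family$combinations[keep], family$k_min, family$k_max,
                 family$universe)
}

#' Write the full screen report to a directory
#'
#' Emits `family.csv`, `maximal_sets.csv`, `inclusion_counts.csv`,
#' `size_distribution.csv`, `class_tally.csv`, and a `manifest.json`
#' recording universe size, size window, interacting-pair count, per-size
#' survivor counts, pruned drugs, and the seed, plus a timestamp. All CSV
#' content is deterministic for identical inputs; only the manifest
#' timestamp varies between runs.
#'
#' @param dir Output directory (created if needed).
#' @param family A `ddi_family`.
#' @param universe The working [drug_universe()].
#' @param graph The `ddi_graph` screened against.
#' @param classes Optional [class_map()]; defaults to all-`"other"`.
#' @param removed Drugs pruned before screening, for the manifest.
#' @param seed Seed recorded in the manifest (may be `NULL`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_screen_report <- function(dir, family, universe, graph,
                                classes = NULL, removed = character(),
                                seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(classes)) classes <- class_map(universe)
  counts <- inclusion_counts(family, universe)
  maximal <- condense_maximal(family)
  sizes <- size_distribution(family, universe)

  paths <- c(family = file.path(dir, "family.csv"),
             maximal = file.path(dir, "maximal_sets.csv"),
             inclusions = file.path(dir, "inclusion_counts.csv"),
             sizes = file.path(dir, "size_distribution.csv"),
             classes = file.path(dir, "class_tally.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_family_csv(family, paths[["family"]])
  write_family_csv(maximal, paths[["maximal"]])
  utils::write.csv(counts, paths[["inclusions"]], row.names = FALSE)
  utils::write.csv(sizes, paths[["sizes"]], row.names = FALSE)
  utils::write.csv(class_tally(counts, classes), paths[["classes"]],
                   row.names = FALSE)

  manifest <- list(
    universe_size = length(universe),
    k_min = family$k_min,
    k_max = family$k_max,
    interacting_pairs = edge_count(graph),
    survivors_total = length(family),
    survivors_by_size = stats::setNames(as.list(sizes$count),
                                        paste0("k", sizes$size)),
    maximal_sets = length(maximal),
    pruned_drugs = as.list(removed),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(paths)
}
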