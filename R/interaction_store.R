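#' Read pairwise interaction records from a delimited file
#'
#' Expected dialect: TSV with header `drug_a, drug_b, description, severity`
#' (`severity` optional). A description of `"None"` (case-insensitive) marks
#' a pair that was looked up and found non-interacting: it contributes
#' source coverage for both drugs but no interaction edge.
#'
#' @param path Path to the interactions file.
#' @param sep Field delimiter; default tab.
#' @return A data.frame with columns `drug_a`, `drug_b`, `description`,
#'   `severity`.
#' @export
read_interactions <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    ddi_error("ddi_missing_file", sprintf("file not found: %s", path))
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE, fill = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  required <- c("drug_a", "drug_b")
  if (!all(required %in% names(df))) {
    ddi_error("ddi_parse_error",
              sprintf("%s must have columns drug_a and drug_b", path))
  }
  if (is.null(df$description)) df$description <- ""
  if (is.null(df$severity)) df$severity <- NA_character_
  df$description[is.na(df$description)] <- ""
  df[c("drug_a", "drug_b", "description", "severity")]
}

# Internal constructor: universe, logical adjacency over the universe
# (symmetric, FALSE diagonal), coverage = drugs with source data.
new_ddi_graph <- function(universe, adjacency, coverage) {
  structure(list(universe = universe, adjacency = adjacency,
                 coverage = coverage),
            class = "ddi_graph")
}

is_none_description <- function(x) {
  !is.na(x) & tolower(trimws(x)) == "none"
}

#' Build an interaction graph from pairwise records
#'
#' The graph is a symmetric, irreflexive relation over the universe: an
#' edge joins two drugs iff some record reports an interaction between
#' them. Records are unordered — `(a, b)` and `(b, a)` are the same pair —
#' and duplicates are collapsed. A pair reported both as `"None"` and as an
#' interaction is a conflict error, never last-write-wins.
#'
#' @param records Data.frame of records as from [read_interactions()], or a
#'   data.frame with at least `drug_a` and `drug_b` columns.
#' @param universe A [drug_universe()].
#' @return A `ddi_graph` with fields `universe`, `adjacency` (logical
#'   matrix), and `coverage` (canonical names of drugs with source data).
#' @export
interaction_graph <- function(records, universe) {
  drugs <- as.character(universe)
  n <- length(drugs)
  adjacency <- matrix(FALSE, n, n, dimnames = list(drugs, drugs))
  if (NROW(records) == 0L) {
    return(new_ddi_graph(universe, adjacency, coverage = character()))
  }
  a <- normalize_drug_name(records$drug_a)
  b <- normalize_drug_name(records$drug_b)
  unknown <- setdiff(unique(c(a, b)), drugs)
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("interaction records name drugs outside the universe: %s",
                      paste(unknown, collapse = ", ")))
  }
  if (any(a == b)) {
    ddi_error("ddi_self_pair",
              sprintf("self-pair record for %s",
                      paste(unique(a[a == b]), collapse = ", ")))
  }
  desc <- if (is.null(records$description)) rep("", length(a)) else
    as.character(records$description)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  has_edge <- !is_none_description(desc)
  conflict <- intersect(unique(key[has_edge]), unique(key[!has_edge]))
  if (length(conflict)) {
    ddi_error("ddi_conflict",
              sprintf("conflicting records (both 'None' and an interaction) for: %s",
                      paste(gsub("\r", " + ", conflict), collapse = "; ")))
  }
  edge_a <- a[has_edge]
  edge_b <- b[has_edge]
  adjacency[cbind(edge_a, edge_b)] <- TRUE
  adjacency[cbind(edge_b, edge_a)] <- TRUE
  new_ddi_graph(universe, adjacency, coverage = intersect(drugs, unique(c(a, b))))
}

#' @export
print.ddi_graph <- function(x, ...) {
  cat(sprintf("<ddi_graph> %d drugs, %d interacting pairs, coverage %d/%d\n",
              length(x$universe), edge_count(x), length(x$coverage),
              length(x$universe)))
  invisible(x)
}

#' Number of interacting pairs in a graph
#'
#' @param graph A `ddi_graph`.
#' @return Integer count of unordered interacting pairs.
#' @export
edge_count <- function(graph) {
  sum(graph$adjacency) / 2L
}

#' Do two drugs interact?
#'
#' Symmetric and irreflexive: `drugs_interact(g, a, b)` equals
#' `drugs_interact(g, b, a)`, and querying a drug against itself is an
#' error rather than a vacuous answer.
#'
#' @param graph A `ddi_graph`.
#' @param a,b Drug names (any casing).
#' @return `TRUE` iff the unordered pair is an interacting pair.
#' @export
drugs_interact <- function(graph, a, b) {
  a <- normalize_drug_name(a)
  b <- normalize_drug_name(b)
  unknown <- setdiff(c(a, b), as.character(graph$universe))
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("unknown drug: %s", paste(unknown, collapse = ", ")))
  }
  if (a == b) {
    ddi_error("ddi_self_pair", sprintf("self-pair query for %s", a))
  }
  graph$adjacency[a, b]
}

#' Remove drugs without interaction-source coverage
#'
#' A drug the source knows nothing about cannot be screened: every
#' combination containing it would be vacuously "interaction-free". Such
#' drugs are removed from the working universe before screening; drugs the
#' source covers but reports zero interactions for are kept.
#'
#' @param graph A `ddi_graph`.
#' @return A list with `universe` (pruned, input order preserved), `graph`
#'   (restricted to the pruned universe), and `removed` (canonical names
#'   dropped, possibly empty).
#' @export
prune_uncovered <- function(graph) {
  drugs <- as.character(graph$universe)
  removed <- setdiff(drugs, graph$coverage)
  if (length(removed) == 0L) {
    return(list(universe = graph$universe, graph = graph, removed = character()))
  }
  kept <- setdiff(drugs, removed)
  if (length(kept) == 0L) {
    ddi_warning("ddi_empty_after_prune",
                "no drug has interaction-source coverage; universe is empty")
    empty_adj <- matrix(FALSE, 0L, 0L, dimnames = list(character(), character()))
    return(list(universe = structure(character(), class = "ddi_universe"),
                graph = new_ddi_graph(structure(character(), class = "ddi_universe"),
                                      empty_adj, character()),
                removed = removed))
  }
  universe <- structure(kept, class = "ddi_universe")
  graph <- new_ddi_graph(universe,
                         graph$adjacency[kept, kept, drop = FALSE],
                         intersect(kept, graph$coverage))
  list(universe = universe, graph = graph, removed = removed)
}

#' Define a remote interaction source
#'
#' A source is anything implementing `lookup(drug) -> list(known, interactions)`:
#' `known = FALSE` means the source has no data for the drug (the drug is
#' excluded from coverage and later pruned); otherwise `interactions` is a
#' data.frame with columns `partner`, `description`, and optionally
#' `severity`, listing the drug's known interactions. Partners not listed
#' are taken as looked-up-but-non-interacting.
#'
#' @param lookup Function of one drug name returning the list above.
#' @return A `ddi_source`.
#' @export
interaction_source <- function(lookup) {
  stopifnot(is.function(lookup))
  structure(list(lookup = lookup), class = "ddi_source")
}

#' Mock interaction source backed by a known graph
#'
#' Encodes an existing `ddi_graph` as a deterministic [interaction_source()]
#' for tests and offline demonstration: `lookup(d)` returns `d`'s
#' interacting partners, and drugs in `unknown` report `known = FALSE`.
#' The returned object counts lookups (`$calls()`), so cache behaviour can
#' be asserted.
#'
#' @param graph A `ddi_graph`.
#' @param unknown Drugs the source should claim no data for.
#' @return A `ddi_source` with an extra `calls()` accessor.
#' @export
mock_interaction_source <- function(graph, unknown = character()) {
  unknown <- if (length(unknown)) normalize_drug_name(unknown) else character()
  n_calls <- 0L
  lookup <- function(drug) {
    n_calls <<- n_calls + 1L
    drug <- normalize_drug_name(drug)
    if (drug %in% unknown) {
      return(list(known = FALSE, interactions = NULL))
    }
    partners <- names(which(graph$adjacency[drug, ]))
    list(known = TRUE,
         interactions = data.frame(
           partner = partners,
           description = if (length(partners))
             sprintf("interaction between %s and %s", drug, partners)
           else character(),
           severity = rep(NA_character_, length(partners)),
           stringsAsFactors = FALSE))
  }
  src <- interaction_source(lookup)
  src$calls <- function() n_calls
  src
}

#' Local cache for remote interaction lookups
#'
#' A read-before-fetch key-value store keyed by canonical drug name. When
#' `path` is given and exists, the cache starts warm from its JSON
#' serialization; [cache_save()] persists the current contents.
#'
#' @param path Optional JSON file backing the cache.
#' @return A `ddi_cache`.
#' @export
interaction_cache <- function(path = NULL) {
  store <- new.env(parent = emptyenv())
  if (!is.null(path) && file.exists(path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (drug in names(raw)) {
      entry <- raw[[drug]]
      inter <- entry$interactions
      if (is.null(inter) || length(inter) == 0L) {
        inter <- data.frame(partner = character(), description = character(),
                            severity = character(), stringsAsFactors = FALSE)
      }
      assign(drug, list(known = isTRUE(entry$known), interactions = inter),
             envir = store)
    }
  }
  structure(list(store = store, path = path), class = "ddi_cache")
}

cache_get <- function(cache, drug) {
  if (is.null(cache)) return(NULL)
  if (exists(drug, envir = cache$store, inherits = FALSE)) {
    get(drug, envir = cache$store, inherits = FALSE)
  } else NULL
}

cache_set <- function(cache, drug, value) {
  if (!is.null(cache)) assign(drug, value, envir = cache$store)
  invisible(value)
}

#' Persist an interaction cache to its JSON file
#'
#' @param cache A [interaction_cache()] created with a `path`.
#' @param path Optional override of the cache's own path.
#' @return The path written, invisibly.
#' @export
cache_save <- function(cache, path = cache$path) {
  if (is.null(path)) {
    ddi_error("ddi_cache_error", "cache has no backing path")
  }
  keys <- sort(ls(cache$store))
  payload <- stats::setNames(lapply(keys, get, envir = cache$store), keys)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, dataframe = "rows",
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Fetch all pairwise interactions for a universe from a source
#'
#' Queries the source once per drug (cache read-before-fetch; a warm cache
#' performs zero remote calls), then collapses the per-drug interaction
#' lists to one record per unordered pair of covered drugs. Pairs neither
#' side lists are recorded with description `"None"` — covered but
#' non-interacting. Drugs with `known = FALSE` are excluded entirely, so
#' they fall out of coverage and are later removed by [prune_uncovered()].
#' Transient lookup errors are retried up to `max_retries` times.
#'
#' @param source A [interaction_source()].
#' @param universe A [drug_universe()].
#' @param cache Optional [interaction_cache()].
#' @param max_retries Bounded retries per lookup before giving up.
#' @return Data.frame of records as accepted by [interaction_graph()].
#' @export
fetch_pairwise <- function(source, universe, cache = NULL, max_retries = 3L) {
  drugs <- as.character(universe)
  responses <- vector("list", length(drugs))
  names(responses) <- drugs
  for (drug in drugs) {
    hit <- cache_get(cache, drug)
    if (is.null(hit)) {
      hit <- lookup_with_retries(source, drug, max_retries)
      cache_set(cache, drug, hit)
    }
    responses[[drug]] <- hit
  }
  known <- drugs[vapply(responses, function(r) isTRUE(r$known), logical(1))]
  if (length(known) < 2L) {
    return(data.frame(drug_a = character(), drug_b = character(),
                      description = character(), severity = character(),
                      stringsAsFactors = FALSE))
  }
  listed <- function(resp, partner) {
    inter <- resp$interactions
    if (is.null(inter) || NROW(inter) == 0L) return(NULL)
    i <- match(partner, normalize_drug_name(inter$partner))
    if (is.na(i)) return(NULL)
    sev <- if (!is.null(inter$severity)) as.character(inter$severity)[i] else NA_character_
    list(description = as.character(inter$description)[i], severity = sev)
  }
  pairs <- utils::combn(known, 2L)
  rec <- function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    hit <- listed(responses[[a]], b)
    if (is.null(hit)) hit <- listed(responses[[b]], a)
    if (is.null(hit)) hit <- list(description = "None", severity = NA_character_)
    data.frame(drug_a = a, drug_b = b, description = hit$description,
               severity = hit$severity, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(ncol(pairs)), rec))
}

lookup_with_retries <- function(source, drug, max_retries) {
  for (attempt in seq_len(max_retries)) {
    result <- tryCatch(source$lookup(drug), error = identity)
    if (!inherits(result, "error")) {
      if (!is.list(result) || is.null(result$known)) {
        ddi_error("ddi_source_format",
                  sprintf("malformed source response for %s", drug))
      }
      return(result)
    }
  }
  ddi_error("ddi_source_error",
            sprintf("lookup for %s failed after %d attempts: %s",
                    drug, max_retries, conditionMessage(result)))
}
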