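# The screening core: enumerate k-subsets of the universe, keep those in
# which no pair of members interacts, condense the surviving hereditary
# family to its maximal sets, and expand back.
#
# Combination identity throughout is the lexicographically sorted canonical
# name vector; its comma-joined string is the hash key used for membership
# tests and deduplication.

combo_key <- function(members) paste(members, collapse = ",")

# Internal family constructor. `combinations` is a list of sorted canonical
# name vectors; stored sorted by size then lexicographic key so output is
# deterministic.
new_ddi_family <- function(combinations, k_min, k_max, universe) {
  if (length(combinations)) {
    keys <- vapply(combinations, combo_key, character(1))
    sizes <- lengths(combinations)
    combinations <- combinations[order(sizes, keys)]
  }
  structure(list(combinations = combinations,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 universe = universe),
            class = "ddi_family")
}

#' @export
print.ddi_family <- function(x, ...) {
  sizes <- lengths(x$combinations)
  cat(sprintf("<ddi_family> %d interaction-free combinations (sizes %d-%d)\n",
              length(x$combinations), x$k_min, x$k_max))
  if (length(sizes)) {
    tab <- table(factor(sizes, levels = x$k_min:x$k_max))
    for (k in names(tab)) cat(sprintf("  %s drugs: %d\n", k, tab[[k]]))
  }
  invisible(x)
}

#' @export
length.ddi_family <- function(x) length(x$combinations)

#' Comma-joined canonical keys of a family's combinations
#'
#' @param family A `ddi_family`.
#' @return Character vector of keys, one per combination, in stored order.
#' @export
family_keys <- function(family) {
  vapply(family$combinations, combo_key, character(1))
}

#' @export
as.data.frame.ddi_family <- function(x, ...) {
  data.frame(size = lengths(x$combinations),
             drugs = family_keys(x),
             stringsAsFactors = FALSE)
}

#' Stream k-combinations of a drug universe in lexicographic order
#'
#' Returns a generator: each call yields the next combination as a sorted
#' character vector, then `NULL` once exhausted. Memory per step is
#' constant in the number of combinations, so the C(44, 4) = 135,751
#' four-drug subsets never need materializing at once.
#'
#' @param universe A [drug_universe()] or character vector of drug names.
#' @param k Combination size; must be at least 2. `k > |universe|` yields
#'   an immediately exhausted stream (not an error).
#' @return A function of no arguments: the next combination, or `NULL`.
#' @examples
#' s <- combination_stream(drug_universe(c("a", "b", "c")), 2)
#' s(); s(); s(); s()
#' @export
combination_stream <- function(universe, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) {
    ddi_error("ddi_invalid_size", "combination size k must be at least 2")
  }
  items <- sort(as.character(universe))
  n <- length(items)
  if (k > n) return(function() NULL)
  idx <- NULL
  done <- FALSE
  function() {
    if (done) return(NULL)
    if (is.null(idx)) {
      idx <<- seq_len(k)
    } else {
      i <- k
      while (i >= 1L && idx[i] == n - k + i) i <- i - 1L
      if (i < 1L) {
        done <<- TRUE
        return(NULL)
      }
      idx[i] <<- idx[i] + 1L
      if (i < k) idx[(i + 1L):k] <<- idx[i] + seq_len(k - i)
    }
    items[idx]
  }
}

#' Materialize all k-combinations of a universe
#'
#' Convenience wrapper over [combination_stream()]: returns the full
#' lexicographically ordered enumeration as a `k x C(n, k)` character
#' matrix (columns are combinations).
#'
#' @inheritParams combination_stream
#' @return Character matrix with one column per combination.
#' @export
enumerate_combinations <- function(universe, k) {
  stream <- combination_stream(universe, k)
  n <- length(universe)
  total <- if (k > n) 0L else choose(n, k)
  out <- matrix(NA_character_, nrow = k, ncol = total)
  j <- 0L
  while (!is.null(combo <- stream())) {
    j <- j + 1L
    out[, j] <- combo
  }
  stopifnot(j == total)
  out
}

#' Is a combination free of pairwise interactions?
#'
#' Checks every one of the C(k, 2) member pairs against the graph.
#'
#' @param combo Character vector of at least two distinct drug names.
#' @param graph A `ddi_graph` whose universe contains all members.
#' @return `TRUE` iff no member pair is an interacting pair.
#' @export
is_interaction_free <- function(combo, graph) {
  members <- normalize_drug_name(combo)
  unknown <- setdiff(members, as.character(graph$universe))
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("combination members outside the graph universe: %s",
                      paste(unknown, collapse = ", ")))
  }
  if (length(members) < 2L) return(TRUE)
  pairs <- utils::combn(members, 2L)
  !any(graph$adjacency[cbind(pairs[1L, ], pairs[2L, ])])
}

#' Screen all k-drug combinations for interaction-free sets
#'
#' The central computation: over all combinations of sizes `k_min` to
#' `k_max` from the universe, keep exactly those in which no pair of
#' members interacts. The result is a hereditary family — every size-≥2
#' subset of a surviving combination also survives — because the defining
#' property is purely pairwise.
#'
#' Implementation walks a depth-first extension tree in lexicographic
#' order, extending each partial combination only with drugs that
#' interact with none of its members; subtrees containing an interacting
#' pair are never visited, so runtime scales with the number of
#' interaction-free sets rather than with C(n, k).
#' [brute_force_screen()] provides the independent, exhaustive oracle.
#'
#' @param universe A [drug_universe()].
#' @param graph A `ddi_graph` over (at least) the universe.
#' @param k_min,k_max Inclusive size bounds; `k_min` must be at least 2.
#' @return A `ddi_family`.
#' @export
screen_combinations <- function(universe, graph, k_min = 2L, k_max = 4L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 2L) {
    ddi_error("ddi_invalid_size", "k_min must be at least 2")
  }
  if (is.na(k_max) || k_max < k_min) {
    ddi_error("ddi_invalid_size", "k_max must be at least k_min")
  }
  drugs <- sort(as.character(universe))
  unknown <- setdiff(drugs, as.character(graph$universe))
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("universe drugs missing from the graph: %s",
                      paste(unknown, collapse = ", ")))
  }
  n <- length(drugs)
  adj <- graph$adjacency[drugs, drugs, drop = FALSE]
  acc <- new.env(parent = emptyenv())
  acc$combos <- vector("list", 256L)
  acc$n <- 0L
  emit <- function(members_idx) {
    if (acc$n == length(acc$combos)) {
      length(acc$combos) <- 2L * length(acc$combos)
    }
    acc$n <- acc$n + 1L
    acc$combos[[acc$n]] <- drugs[members_idx]
  }
  extend <- function(members_idx, candidates) {
    for (i in candidates) {
      chosen <- c(members_idx, i)
      k <- length(chosen)
      if (k >= k_min) emit(chosen)
      if (k < k_max) {
        after <- candidates[candidates > i]
        compatible <- after[!adj[i, after]]
        if (length(compatible)) extend(chosen, compatible)
      }
    }
  }
  for (i in seq_len(n)) {
    after <- seq_len(n)[-seq_len(i)]
    compatible <- after[!adj[i, after]]
    if (length(compatible)) extend(i, compatible)
  }
  new_ddi_family(acc$combos[seq_len(acc$n)], k_min, k_max,
                 structure(drugs, class = "ddi_universe"))
}

#' Exhaustive brute-force screen (independent oracle)
#'
#' Same contract as [screen_combinations()], implemented the slow, obvious
#' way: materialize every k-subset with [utils::combn()] and recheck every
#' member pair directly against the adjacency relation. Shares no code
#' with the pruned depth-first screen, so agreement between the two is a
#' meaningful correctness check. Deliberately capped at 20 drugs.
#'
#' @inheritParams screen_combinations
#' @return A `ddi_family`.
#' @export
brute_force_screen <- function(universe, graph, k_min = 2L, k_max = 4L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || k_min < 2L || is.na(k_max) || k_max < k_min) {
    ddi_error("ddi_invalid_size", "need 2 <= k_min <= k_max")
  }
  drugs <- sort(as.character(universe))
  if (length(drugs) > 20L) {
    ddi_error("ddi_oracle_scale",
              "brute-force oracle is limited to universes of at most 20 drugs")
  }
  adj <- graph$adjacency[drugs, drugs, drop = FALSE]
  survivors <- list()
  for (k in k_min:min(k_max, length(drugs))) {
    cm <- utils::combn(drugs, k)
    pair_rows <- utils::combn(seq_len(k), 2L)
    bad <- rep(FALSE, ncol(cm))
    for (j in seq_len(ncol(pair_rows))) {
      bad <- bad | adj[cbind(cm[pair_rows[1L, j], ], cm[pair_rows[2L, j], ])]
    }
    keep <- which(!bad)
    survivors <- c(survivors, lapply(keep, function(col) cm[, col]))
  }
  new_ddi_family(survivors, k_min, k_max,
                 structure(drugs, class = "ddi_universe"))
}

# Assert the downward-closure that every screen output must satisfy; a
# violation means the family was not produced by a pairwise screen.
assert_hereditary <- function(family) {
  keys <- new.env(parent = emptyenv())
  for (key in family_keys(family)) assign(key, TRUE, envir = keys)
  for (members in family$combinations) {
    k <- length(members)
    if (k <= family$k_min) next
    for (drop in seq_len(k)) {
      if (!exists(combo_key(members[-drop]), envir = keys, inherits = FALSE)) {
        ddi_error("ddi_not_hereditary",
                  sprintf("family is not hereditary: subset %s of %s is missing",
                          combo_key(members[-drop]), combo_key(members)))
      }
    }
  }
  invisible(family)
}

# Internal maximal-set-list constructor; sets ordered by descending size
# then lexicographic key.
new_ddi_maximal <- function(sets, universe, k_min, k_max) {
  if (length(sets)) {
    keys <- vapply(sets, combo_key, character(1))
    sets <- sets[order(-lengths(sets), keys)]
  }
  structure(list(sets = sets, universe = universe,
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "ddi_maximal")
}

#' @export
print.ddi_maximal <- function(x, ...) {
  cat(sprintf("<ddi_maximal> %d maximal interaction-free sets\n",
              length(x$sets)))
  invisible(x)
}

#' @export
length.ddi_maximal <- function(x) length(x$sets)

#' @export
as.data.frame.ddi_maximal <- function(x, ...) {
  data.frame(size = lengths(x$sets),
             drugs = vapply(x$sets, combo_key, character(1)),
             stringsAsFactors = FALSE)
}

#' Condense a hereditary family to its maximal sets
#'
#' Every interaction-free 4-set implies all its 2- and 3-subsets, so the
#' family is fully determined by its maximal members: those not strictly
#' contained in another member. Maximality is relative to the enumerated
#' size window — a `k_max`-set is maximal here even if a larger
#' interaction-free set exists outside the window.
#'
#' @param family A hereditary `ddi_family` (validated; a non-hereditary
#'   input is a consistency error signalling an upstream bug).
#' @return A `ddi_maximal`, ordered by descending size then name.
#' @export
condense_maximal <- function(family) {
  assert_hereditary(family)
  keys <- new.env(parent = emptyenv())
  for (key in family_keys(family)) assign(key, TRUE, envir = keys)
  drugs <- as.character(family$universe)
  is_maximal <- vapply(family$combinations, function(members) {
    if (length(members) >= family$k_max) return(TRUE)
    # hereditary family: any strict superset implies an immediate one
    for (extra in setdiff(drugs, members)) {
      if (exists(combo_key(sort(c(members, extra))), envir = keys,
                 inherits = FALSE)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  new_ddi_maximal(family$combinations[is_maximal], family$universe,
                  family$k_min, family$k_max)
}

#' Expand maximal sets back to the full combination family
#'
#' Inverse of [condense_maximal()] on hereditary families: the union over
#' all maximal sets of their size-`k_min` to size-`k_max` subsets,
#' deduplicated.
#'
#' @param maximal A `ddi_maximal`, or a plain list of drug-name vectors.
#' @param k_min,k_max Size window to expand into.
#' @param universe Universe for the resulting family; defaults to the one
#'   carried by `maximal`.
#' @return A `ddi_family`.
#' @export
expand_maximal <- function(maximal, k_min = 2L, k_max = 4L, universe = NULL) {
  sets <- if (inherits(maximal, "ddi_maximal")) maximal$sets else
    lapply(maximal, function(s) sort(normalize_drug_name(s)))
  if (is.null(universe)) {
    universe <- if (inherits(maximal, "ddi_maximal")) maximal$universe else
      structure(sort(unique(unlist(sets))), class = "ddi_universe")
  }
  seen <- new.env(parent = emptyenv())
  combos <- vector("list", 256L)
  n <- 0L
  for (s in sets) {
    s <- sort(s)
    if (length(s) < k_min) next
    for (k in k_min:min(k_max, length(s))) {
      subs <- utils::combn(s, k)
      for (j in seq_len(ncol(subs))) {
        key <- combo_key(subs[, j])
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          if (n == length(combos)) length(combos) <- 2L * length(combos)
          n <- n + 1L
          combos[[n]] <- subs[, j]
        }
      }
    }
  }
  new_ddi_family(combos[seq_len(n)], k_min, k_max, universe)
}

#' Write a combination family (or maximal-set list) to CSV
#'
#' One row per combination: a `size` column and the comma-joined canonical
#' member names. Output order is the object's deterministic stored order,
#' so identical inputs give byte-identical files.
#'
#' @param x A `ddi_family` or `ddi_maximal`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_family_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a combination family from CSV
#'
#' Inverse of [write_family_csv()] for families.
#'
#' @param path CSV with `size` and `drugs` columns.
#' @param universe Optional [drug_universe()]; defaults to the drugs seen.
#' @return A `ddi_family`.
#' @export
read_family_csv <- function(path, universe = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  combos <- lapply(strsplit(df$drugs, ",", fixed = TRUE),
                   function(m) sort(normalize_drug_name(m)))
  if (is.null(universe)) {
    universe <- structure(sort(unique(unlist(combos))), class = "ddi_universe")
  }
  sizes <- lengths(combos)
  k_min <- if (length(sizes)) min(sizes) else 2L
  k_max <- if (length(sizes)) max(sizes) else 2L
  new_ddi_family(combos, k_min, k_max, universe)
}
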