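# Ground-truth fixture and synthetic graph generators. The bundled
# reference dataset covers 44 non-opioid, non-barbiturate headache
# abortive medications; its interaction graph is reconstructed from the
# published condensed list of interaction-free sets, so the whole pipeline
# is exercisable offline.

#' Read a condensed-set list from a text file
#'
#' One set per line, comma-joined drug names; `#` comments and blank lines
#' ignored. Names are normalized and validated against the universe.
#'
#' @param path Path to the sets file.
#' @param universe A [drug_universe()].
#' @return List of sorted canonical-name character vectors.
#' @export
read_maximal_sets <- function(path, universe) {
  lines <- read_list_lines(path)
  sets <- lapply(strsplit(lines, ",", fixed = TRUE), function(m) {
    sort(normalize_drug_name(m))
  })
  unknown <- setdiff(unique(unlist(sets)), as.character(universe))
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("set members outside the universe: %s",
                      paste(unknown, collapse = ", ")))
  }
  sets
}

#' Reconstruct an interaction graph from non-interacting sets
#'
#' Inverts a condensed interaction-free set list: every unordered pair
#' co-occurring in at least one set is non-interacting; every other
#' universe pair interacts. Coverage is the whole universe. Because the
#' screen is purely pairwise, the co-occurrence pairs fully determine it,
#' so screening the reconstructed graph regenerates the exact family the
#' condensed list summarizes.
#'
#' @param sets List of drug-name vectors (or a `ddi_maximal`).
#' @param universe A [drug_universe()].
#' @return A `ddi_graph` with coverage = universe.
#' @export
graph_from_noninteracting_sets <- function(sets, universe) {
  if (inherits(sets, "ddi_maximal")) sets <- sets$sets
  drugs <- as.character(universe)
  n <- length(drugs)
  sets <- lapply(sets, normalize_drug_name)
  unknown <- setdiff(unique(unlist(sets)), drugs)
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("set members outside the universe: %s",
                      paste(unknown, collapse = ", ")))
  }
  adjacency <- matrix(TRUE, n, n, dimnames = list(drugs, drugs))
  diag(adjacency) <- FALSE
  for (s in sets) {
    if (length(s) < 2L) next
    pairs <- utils::combn(s, 2L)
    adjacency[cbind(pairs[1L, ], pairs[2L, ])] <- FALSE
    adjacency[cbind(pairs[2L, ], pairs[1L, ])] <- FALSE
  }
  new_ddi_graph(universe, adjacency, coverage = drugs)
}

#' The bundled headache-abortives reference dataset
#'
#' Loads the curated 44-drug universe of non-opioid, non-barbiturate
#' abortive medications, the published 82-line condensed list of
#' interaction-free sets, the interaction graph reconstructed from it via
#' [graph_from_noninteracting_sets()], the 12-drug evidence-based
#' primary-care allow-list, the reference class map (20 NSAIDs, gepant,
#' ditan, 7 triptans, ...), and the reference per-drug inclusion counts.
#'
#' @return A list with elements `universe`, `sets`, `graph`, `allow`,
#'   `classes`, and `reference_counts`.
#' @examples
#' fx <- abortives_fixture()
#' screen_combinations(fx$universe, fx$graph)
#' @export
abortives_fixture <- function() {
  dir <- system.file("extdata", "abortives", package = "ddiscreen",
                     mustWork = TRUE)
  universe <- read_drug_list(file.path(dir, "drugs.txt"))
  sets <- read_maximal_sets(file.path(dir, "maximal_sets.csv"), universe)
  counts <- utils::read.delim(file.path(dir, "inclusion_counts.tsv"),
                              comment.char = "#", stringsAsFactors = FALSE)
  counts$drug <- normalize_drug_name(counts$drug)
  list(universe = universe,
       sets = sets,
       graph = graph_from_noninteracting_sets(sets, universe),
       allow = read_allow_list(file.path(dir, "allowlist.txt"), universe),
       classes = read_class_map(file.path(dir, "classes.tsv"), universe),
       reference_counts = counts)
}

# Run a block with a private RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

synthetic_universe <- function(n) {
  width <- max(2L, nchar(as.character(n)))
  drug_universe(sprintf("d%0*d", width, seq_len(n)))
}

#' Random interaction graph (Erdős–Rényi)
#'
#' Synthetic universe `d01..dNN` (zero-padded so lexicographic order is
#' numeric order) with each unordered pair interacting independently with
#' probability `p`. Identical seeds give identical graphs; the caller's
#' RNG state is left untouched.
#'
#' @param n Number of drugs (at least 2).
#' @param p Interaction probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `universe` and `graph` (coverage = universe).
#' @export
random_interaction_graph <- function(n, p, seed) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    ddi_error("ddi_invalid_parameter", "edge probability p must be in [0, 1]")
  }
  if (!is.numeric(n) || n < 2L) {
    ddi_error("ddi_invalid_parameter", "need at least 2 synthetic drugs")
  }
  universe <- synthetic_universe(n)
  drugs <- as.character(universe)
  adjacency <- matrix(FALSE, n, n, dimnames = list(drugs, drugs))
  upper <- upper.tri(adjacency)
  adjacency[upper] <- with_seed(seed, stats::runif(sum(upper)) < p)
  adjacency[lower.tri(adjacency)] <- t(adjacency)[lower.tri(adjacency)]
  list(universe = universe,
       graph = new_ddi_graph(universe, adjacency, coverage = drugs))
}

#' Interaction graph with planted interaction-free sets
#'
#' Constructs a graph whose non-interacting pairs are exactly those lying
#' within some planted set; all other pairs interact. Screening such a
#' graph and condensing must recover exactly the inclusion-maximal planted
#' sets, which makes this the recovery benchmark for the pipeline.
#'
#' @param n Number of synthetic drugs (`d01..dNN`).
#' @param planted List of drug-name vectors over the synthetic universe.
#' @param seed Accepted for interface symmetry with
#'   [random_interaction_graph()]; the construction is deterministic.
#' @return List with `universe` and `graph`.
#' @export
planted_family_graph <- function(n, planted, seed = NULL) {
  universe <- synthetic_universe(n)
  unknown <- setdiff(unique(normalize_drug_name(unlist(planted))),
                     as.character(universe))
  if (length(unknown)) {
    ddi_error("ddi_unknown_drug",
              sprintf("planted drugs outside the synthetic universe: %s",
                      paste(unknown, collapse = ", ")))
  }
  list(universe = universe,
       graph = graph_from_noninteracting_sets(planted, universe))
}
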