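# Shared builders for small hand-specified universes and graphs.

# Build a ddi_graph over `drugs` whose interacting pairs are the rows of
# `pairs` (list of length-2 character vectors). Coverage defaults to the
# whole universe.
toy_graph <- function(drugs, pairs = list()) {
  universe <- drug_universe(drugs)
  records <- if (length(pairs)) {
    data.frame(drug_a = vapply(pairs, `[[`, character(1), 1L),
               drug_b = vapply(pairs, `[[`, character(1), 2L),
               description = "interacts",
               stringsAsFactors = FALSE)
  } else {
    data.frame(drug_a = character(), drug_b = character(),
               description = character(), stringsAsFactors = FALSE)
  }
  g <- interaction_graph(records, universe)
  g$coverage <- as.character(universe)
  g
}

# Canonical set-of-sets comparison for families.
expect_same_family <- function(a, b) {
  expect_setequal(family_keys(a), family_keys(b))
}

# The bundled reference dataset, loaded once per test run.
fixture_cache <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- abortives_fixture()
    fx
  }
})
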