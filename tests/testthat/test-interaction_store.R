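test_that("graph construction collapses symmetric duplicates and honours 'None'", {
  u <- drug_universe(c("a", "b", "c", "d"))
  records <- data.frame(
    drug_a = c("a", "b", "a", "c"),
    drug_b = c("b", "a", "c", "d"),
    description = c("interacts", "interacts", "None", "none"),
    stringsAsFactors = FALSE)
  g <- interaction_graph(records, u)
  expect_identical(edge_count(g), 1)
  expect_true(drugs_interact(g, "a", "b"))
  expect_false(drugs_interact(g, "a", "c"))
  # 'None' rows still establish coverage
  expect_setequal(g$coverage, c("a", "b", "c", "d"))

  empty <- interaction_graph(records[0, ], u)
  expect_identical(edge_count(empty), 0)
  expect_length(empty$coverage, 0L)
})

test_that("graph construction is insensitive to record order and duplication", {
  u <- drug_universe(letters[1:5])
  records <- data.frame(
    drug_a = c("a", "b", "c", "d"),
    drug_b = c("b", "c", "d", "e"),
    description = "x", stringsAsFactors = FALSE)
  g1 <- interaction_graph(records, u)
  g2 <- interaction_graph(records[c(4, 1, 3, 2, 1, 1), ], u)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("graph construction rejects unknown drugs, self-pairs, and conflicts", {
  u <- drug_universe(c("a", "b"))
  expect_error(
    interaction_graph(data.frame(drug_a = "a", drug_b = "z",
                                 description = "x"), u),
    class = "ddi_unknown_drug")
  expect_error(
    interaction_graph(data.frame(drug_a = "a", drug_b = "A",
                                 description = "x"), u),
    class = "ddi_self_pair")
  conflicting <- data.frame(drug_a = c("a", "b"), drug_b = c("b", "a"),
                            description = c("interacts", "None"),
                            stringsAsFactors = FALSE)
  expect_error(interaction_graph(conflicting, u), class = "ddi_conflict")
})

test_that("interaction queries are symmetric, irreflexive, and validated", {
  g <- toy_graph(c("a", "b", "c"), list(c("a", "b")))
  drugs <- c("a", "b", "c")
  for (x in drugs) for (y in setdiff(drugs, x)) {
    expect_identical(drugs_interact(g, x, y), drugs_interact(g, y, x))
  }
  expect_error(drugs_interact(g, "a", "a"), class = "ddi_self_pair")
  expect_error(drugs_interact(g, "a", "z"), class = "ddi_unknown_drug")
})

test_that("the bundled single-drug interaction table parses to the expected partners", {
  fx <- fixture_cache()
  path <- system.file("extdata", "abortives", "sumatriptan_interactions.tsv",
                      package = "ddiscreen")
  records <- read_interactions(path)
  expect_identical(nrow(records), 43L)
  g <- interaction_graph(records, fx$universe)
  partners <- setdiff(g$coverage, "sumatriptan")
  free <- partners[!vapply(partners, function(p)
    drugs_interact(g, "sumatriptan", p), logical(1))]
  expect_setequal(free, c("ubrogepant", "naproxen"))
  # full coverage: every universe drug was looked up against sumatriptan
  expect_setequal(g$coverage, as.character(fx$universe))
})

test_that("pruning removes exactly the drugs without source coverage", {
  u <- drug_universe(c("a", "b", "c", "d"))
  records <- data.frame(drug_a = c("a", "a"), drug_b = c("b", "c"),
                        description = c("x", "None"),
                        stringsAsFactors = FALSE)
  g <- interaction_graph(records, u)
  pruned <- prune_uncovered(g)
  expect_identical(as.character(pruned$universe), c("a", "b", "c"))
  expect_identical(pruned$removed, "d")
  expect_identical(dim(pruned$graph$adjacency), c(3L, 3L))

  # full coverage: identity with empty removal list
  full <- toy_graph(c("a", "b"), list(c("a", "b")))
  res <- prune_uncovered(full)
  expect_identical(res$removed, character())
  expect_identical(res$graph$adjacency, full$adjacency)

  # degenerate: nothing covered
  none <- interaction_graph(records[0, ], u)
  expect_warning(res0 <- prune_uncovered(none),
                 class = "ddi_empty_after_prune")
  expect_length(res0$universe, 0L)
  expect_setequal(res0$removed, c("a", "b", "c", "d"))
})

test_that("mock-source fetch reproduces an encoded graph bit-for-bit", {
  fx <- fixture_cache()
  src <- mock_interaction_source(fx$graph)
  records <- fetch_pairwise(src, fx$universe)
  expect_identical(nrow(records), 946L)
  g <- interaction_graph(records, fx$universe)
  expect_identical(g$adjacency, fx$graph$adjacency)
  expect_setequal(g$coverage, as.character(fx$universe))
  # deterministic: a second fetch yields identical records
  expect_identical(fetch_pairwise(mock_interaction_source(fx$graph),
                                  fx$universe),
                   records)
})

test_that("drugs unknown to the source drop out of coverage and get pruned", {
  g <- toy_graph(c("a", "b", "c", "rimegepant"), list(c("a", "b")))
  src <- mock_interaction_source(g, unknown = "rimegepant")
  records <- fetch_pairwise(src, g$universe)
  built <- interaction_graph(records, g$universe)
  expect_false("rimegepant" %in% built$coverage)
  pruned <- prune_uncovered(built)
  expect_identical(pruned$removed, "rimegepant")
  expect_identical(as.character(pruned$universe), c("a", "b", "c"))
})

test_that("a warm cache serves a fetch with zero remote lookups", {
  g <- toy_graph(letters[1:6],
                 list(c("a", "b"), c("b", "c"), c("e", "f")))
  cache_path <- withr::local_tempfile(fileext = ".json")
  src1 <- mock_interaction_source(g)
  cache <- interaction_cache(cache_path)
  records1 <- fetch_pairwise(src1, g$universe, cache)
  expect_identical(src1$calls(), 6L)
  cache_save(cache)

  src2 <- mock_interaction_source(g)
  warm <- interaction_cache(cache_path)
  records2 <- fetch_pairwise(src2, g$universe, warm)
  expect_identical(src2$calls(), 0L)
  g1 <- interaction_graph(records1, g$universe)
  g2 <- interaction_graph(records2, g$universe)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("transient lookup failures are retried, persistent ones surface", {
  u <- drug_universe(c("a", "b"))
  attempts <- 0L
  flaky <- interaction_source(function(drug) {
    attempts <<- attempts + 1L
    if (attempts < 3L) stop("transport glitch")
    list(known = TRUE,
         interactions = data.frame(partner = character(),
                                   description = character()))
  })
  records <- fetch_pairwise(flaky, u, max_retries = 3L)
  expect_identical(nrow(records), 1L)  # single covered pair, 'None'
  expect_identical(tolower(records$description), "none")

  dead <- interaction_source(function(drug) stop("down"))
  expect_error(fetch_pairwise(dead, u, max_retries = 2L),
               class = "ddi_source_error")

  malformed <- interaction_source(function(drug) list(foo = 1))
  expect_error(fetch_pairwise(malformed, u),
               class = "ddi_source_format")
})
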