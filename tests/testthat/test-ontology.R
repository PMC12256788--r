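test_that("parse_obo reads a minimal well-formed file", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: X:1", "name: root", "",
    "[Term]", "id: X:2", "name: A", "is_a: X:1 ! root", "",
    "[Term]", "id: X:3", "name: B", "is_a: X:2"
  ), f)
  ont <- parse_obo(f)
  expect_s3_class(ont, "ontology")
  expect_length(ont$ids, 3L)
  expect_equal(ont$root, "X:1")
  expect_equal(ont$parents[["X:1"]], character(0))
  expect_equal(ont$parents[["X:3"]], "X:2")
})

test_that("parse_obo rejects cyclic and ambiguous graphs and malformed lines", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: X:1", "name: A", "is_a: X:2", "",
    "[Term]", "id: X:2", "name: B", "is_a: X:1"
  ), f)
  expect_error(parse_obo(f), "cycle|parentless|root")

  writeLines(c(
    "[Term]", "id: X:1", "name: r1", "",
    "[Term]", "id: X:2", "name: r2", "",
    "[Term]", "id: X:3", "name: A", "is_a: X:1"
  ), f)
  expect_error(parse_obo(f), "multiple parentless")
  # configured root resolves the ambiguity only if the graph is consistent
  expect_error(parse_obo(f, root = "X:1"), "path to root")

  writeLines(c("[Term]", "id: X:1", "name: root", "not a tag line"), f)
  expect_error(parse_obo(f), "malformed OBO line 4")
})

test_that("obsolete terms keep replaced_by and stay out of the graph", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: X:1", "name: root", "",
    "[Term]", "id: X:2", "name: A", "is_a: X:1", "",
    "[Term]", "id: X:9", "name: old", "is_obsolete: true", "replaced_by: X:2"
  ), f)
  ont <- parse_obo(f)
  expect_true(ont$obsolete[["X:9"]])
  expect_equal(ont$replaced_by[["X:9"]], "X:2")
  expect_error(ancestors(ont, "X:9"), "unknown or obsolete")
})

test_that("ancestors is the reflexive transitive closure", {
  chain <- chain_ontology()
  expect_equal(ancestors(chain, "root"), "root")
  expect_setequal(ancestors(chain, "B"), c("B", "A", "root"))
  diamond <- diamond_ontology()
  expect_setequal(ancestors(diamond, "C"), c("C", "A", "B", "root"))
  expect_error(ancestors(diamond, "nope"), "unknown")
})

test_that("ancestors matches a breadth-first oracle and is monotone on random DAGs", {
  for (s in 1:50) {
    ont <- generate_random_ontology(sample(5:30, 1L), max_parents = 3, seed = s)
    for (t in sample(names(ont$ancestors), 5L)) {
      expect_setequal(ancestors(ont, t), bfs_ancestors(ont, t))
    }
    # monotone: t in anc(s) => anc(t) subset of anc(s)
    s_term <- sample(names(ont$ancestors), 1L)
    for (t in ancestors(ont, s_term)) {
      expect_true(all(ancestors(ont, t) %in% ancestors(ont, s_term)))
    }
  }
})

test_that("validate_profile deduplicates, maps replaced_by, and rejects empties", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: X:1", "name: root", "",
    "[Term]", "id: X:2", "name: A", "is_a: X:1", "",
    "[Term]", "id: X:3", "name: B", "is_a: X:1", "",
    "[Term]", "id: X:9", "name: old", "is_obsolete: true", "replaced_by: X:2", "",
    "[Term]", "id: X:8", "name: dead", "is_obsolete: true"
  ), f)
  ont <- parse_obo(f)
  expect_setequal(validate_profile(ont, c("X:2", "X:2", "X:3")), c("X:2", "X:3"))
  expect_equal(suppressWarnings(validate_profile(ont, "X:9")), "X:2")
  expect_warning(validate_profile(ont, c("X:2", "X:8")), "dropped")
  expect_warning(validate_profile(ont, c("X:2", "nope")), "nope")
  expect_error(suppressWarnings(validate_profile(ont, "unknown")), "empty")
})

test_that("reduce_nonredundant keeps only most-specific terms and is idempotent", {
  chain <- chain_ontology()
  expect_equal(reduce_nonredundant(chain, c("A", "B")), "B")
  diamond <- diamond_ontology()
  expect_setequal(reduce_nonredundant(diamond, c("A", "B")), c("A", "B"))
  expect_equal(reduce_nonredundant(diamond, c("A", "B", "C")), "C")

  for (s in 1:30) {
    ont <- generate_random_ontology(sample(5:30, 1L), max_parents = 2, seed = 100 + s)
    terms <- sample(names(ont$ancestors), sample(2:6, 1L))
    red <- reduce_nonredundant(ont, terms)
    expect_equal(reduce_nonredundant(ont, red), red)
    for (i in seq_along(red)) {
      for (j in seq_along(red)) {
        if (i != j) expect_false(red[[i]] %in% setdiff(ancestors(ont, red[[j]]), red[[j]]))
      }
    }
  }
})

test_that("compute_ic propagates annotations to ancestors and smooths zeros", {
  diamond <- diamond_ontology()
  ic <- diamond_ic(diamond)
  # A implied by profiles {C} and {A}: freq 2 of 4
  expect_equal(ic$ic[["A"]], log(2), tolerance = 1e-12)
  expect_equal(ic$ic[["B"]], log(2), tolerance = 1e-12)
  expect_equal(ic$ic[["C"]], log(4), tolerance = 1e-12)
  expect_identical(ic$ic[["root"]], 0)

  # never-annotated term in a corpus of 9: smoothed to -log(1/10)
  ont <- chain_ontology()
  corpus <- rep(list("A"), 9L)
  ic9 <- compute_ic(ont, corpus)
  expect_equal(ic9$ic[["B"]], log(10), tolerance = 1e-12)
  expect_identical(ic9$ic[["A"]], 0)  # present in every profile

  expect_error(compute_ic(ont, list()), "non-empty")
})

test_that("IC is anti-monotone along every edge of generated corpora", {
  for (s in 1:20) {
    ont <- generate_random_ontology(sample(8:30, 1L), max_parents = 2, seed = 200 + s)
    nonroot <- setdiff(names(ont$ancestors), ont$root)
    corpus <- replicate(
      sample(3:10, 1L),
      sample(nonroot, sample(1:4, 1L)),
      simplify = FALSE
    )
    ic <- compute_ic(ont, corpus)
    expect_identical(ic$ic[[ont$root]], 0)
    for (t in names(ont$parents)) {
      if (ont$obsolete[[t]]) next
      for (p in ont$parents[[t]]) {
        expect_lte(ic$ic[[p]], ic$ic[[t]] + 1e-12)
      }
    }
  }
})

test_that("profile TSV round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  profs <- list(P1 = c("X:1", "X:2"), P2 = "X:3")
  write_profiles_tsv(profs, f)
  expect_identical(read_profiles_tsv(f), profs)
})
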