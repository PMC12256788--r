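test_that("lin_sim handles self, root, and the diamond MICA case", {
  ont <- diamond_ontology()
  ic <- diamond_ic(ont)
  expect_equal(lin_sim(ic, ont, "C", "C"), 1.0)
  expect_equal(lin_sim(ic, ont, "root", "C"), 0.0)
  expect_equal(lin_sim(ic, ont, "root", "root"), 0.0)  # 0/0 case
  # MICA of (A, C) is A: 2 log2 / (log2 + log4) = 2/3
  expect_equal(lin_sim(ic, ont, "A", "C"), 2 / 3, tolerance = 1e-12)
  expect_equal(lin_sim(ic, ont, "A", "C"), lin_sim(ic, ont, "C", "A"))
  # A and B share only the root
  expect_equal(lin_sim(ic, ont, "A", "B"), 0.0)
  expect_error(lin_sim(ic, ont, "A", "nope"), "unknown")
})

test_that("profile_sim is the symmetric best-match average", {
  ont <- diamond_ontology()
  ic <- diamond_ic(ont)
  expect_equal(profile_sim(ic, ont, c("A", "C"), c("A", "C")), 1.0)
  expect_equal(profile_sim(ic, ont, "A", "B"), 0.0)
  # A={A}, B={A,C}: 0.5 * (1 + (1 + 2/3)/2) = 11/12
  expect_equal(profile_sim(ic, ont, "A", c("A", "C")), 11 / 12, tolerance = 1e-12)
  expect_error(profile_sim(ic, ont, character(0), "A"), "empty")
})

test_that("similarity matches brute-force enumeration on random draws", {
  for (s in 1:30) {
    withr::local_seed(300 + s)
    ont <- generate_random_ontology(sample(5:30, 1L), max_parents = 2, seed = 300 + s)
    nonroot <- setdiff(names(ont$ancestors), ont$root)
    corpus <- replicate(sample(3:8, 1L), sample(nonroot, sample(1:4, 1L)), simplify = FALSE)
    ic <- compute_ic(ont, corpus)
    terms <- names(ont$ancestors)
    for (k in 1:5) {
      t1 <- sample(terms, 1L)
      t2 <- sample(terms, 1L)
      expect_equal(
        lin_sim(ic, ont, t1, t2), oracle_lin(ont, ic$ic, t1, t2),
        tolerance = 1e-12
      )
    }
    a <- sample(nonroot, min(sample(2:5, 1L), length(nonroot)))
    b <- sample(nonroot, min(sample(2:5, 1L), length(nonroot)))
    expect_equal(
      profile_sim(ic, ont, a, b), oracle_profile_sim(ont, ic$ic, a, b),
      tolerance = 1e-12
    )
    expect_equal(profile_sim(ic, ont, a, b), profile_sim(ic, ont, b, a), tolerance = 1e-12)
  }
})

test_that("term_sim_matrix agrees with elementwise lin_sim", {
  ont <- fixture_ontology()
  refs <- fixture_references()
  ic <- compute_ic(ont, refs$profiles)
  terms <- sample(names(ont$ancestors), 8L)
  m <- term_sim_matrix(ic, ont, terms)
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      expect_equal(m[i, j], lin_sim(ic, ont, terms[[i]], terms[[j]]), tolerance = 1e-12)
    }
  }
})

test_that("score_patient takes the max over references with first-match ties", {
  ont <- diamond_ontology()
  ic <- diamond_ic(ont)
  refs <- reference_table(list(R1 = "B", R2 = c("A", "C"), R3 = "B"))
  # patient {A, C}: oracle sims decide both score and argmax
  sims <- vapply(
    refs$profiles,
    function(r) oracle_profile_sim(ont, ic$ic, c("A", "C"), r),
    numeric(1)
  )
  got <- score_patient(ic, ont, c("A", "C"), refs, subject_id = "P")
  expect_equal(got$score, max(sims), tolerance = 1e-12)
  expect_equal(got$best_match_id, names(refs$profiles)[[which.max(sims)]])
  expect_equal(got$best_match_id, "R2")

  # identical to a reference with positive ICs: perfect score
  got2 <- score_patient(ic, ont, c("A", "C"), reference_table(list(R = c("A", "C"))))
  expect_equal(got2$score, 1.0)

  # ties go to the first reference in table order
  tied <- score_patient(ic, ont, "B", reference_table(list(R1 = "B", R2 = "B")))
  expect_equal(tied$best_match_id, "R1")

  # sharing only root-level structure: zero
  expect_equal(score_patient(ic, ont, "A", reference_table(list(R = "B")))$score, 0)
})

test_that("n_terms and mean_ic are reported on the non-redundant set", {
  chain <- chain_ontology()
  ic <- compute_ic(chain, list("B", "A"))
  refs <- reference_table(list(R = "B"))
  # patient {A, B}: A is a redundant ancestor of B
  got <- score_patient(ic, chain, c("A", "B"), refs)
  expect_equal(got$n_terms, 1L)
  expect_equal(got$mean_ic, ic$ic[["B"]])
})

test_that("adding a reference never decreases a patient score", {
  for (s in 1:20) {
    withr::local_seed(400 + s)
    ont <- generate_random_ontology(20, max_parents = 2, seed = 400 + s)
    nonroot <- setdiff(names(ont$ancestors), ont$root)
    refs_small <- reference_table(list(R1 = sample(nonroot, 3L)))
    refs_big <- reference_table(c(refs_small$profiles, list(R2 = sample(nonroot, 3L))))
    ic <- compute_ic(ont, refs_big$profiles)
    patient <- sample(nonroot, 3L)
    expect_gte(
      score_patient(ic, ont, patient, refs_big)$score,
      score_patient(ic, ont, patient, refs_small)$score - 1e-12
    )
  }
})

test_that("terms related only through the root never raise profile similarity", {
  # two disjoint branches under the root: noise from the far branch cannot help
  terms <- data.frame(
    id = c("root", "L1", "L2", "R1", "R2"),
    name = c("root", "L1", "L2", "R1", "R2"),
    stringsAsFactors = FALSE
  )
  terms$parents <- I(list(character(0), "root", "L1", "root", "R1"))
  ont <- build_ontology(terms)
  ic <- compute_ic(ont, list("L2", "L1", "R2", "R1"))
  ref <- c("L1", "L2")
  base <- profile_sim(ic, ont, "L2", ref)
  noisy <- profile_sim(ic, ont, c("L2", "R2"), ref)
  expect_lt(noisy, base)
})

test_that("score_cohort equals per-patient scoring", {
  ont <- fixture_ontology()
  refs <- fixture_references()
  ic <- compute_ic(ont, refs$profiles)
  patients <- list(
    P1 = c("SP:0000105", "SP:0000501"),
    P2 = c("SP:0000602", "SP:0000204"),
    P3 = "SP:0000402"
  )
  bulk <- score_cohort(ic, ont, patients, refs)
  for (i in seq_along(patients)) {
    one <- score_patient(ic, ont, patients[[i]], refs, subject_id = names(patients)[[i]])
    expect_equal(bulk$score[[i]], one$score, tolerance = 1e-12)
    expect_equal(bulk$best_match_id[[i]], one$best_match_id)
  }
})

test_that("reference TSV round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  refs <- fixture_references()
  write_reference_tsv(refs, f)
  back <- read_reference_tsv(f)
  expect_identical(back$profiles, refs$profiles)
  expect_identical(unname(back$labels), unname(refs$labels))
})
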