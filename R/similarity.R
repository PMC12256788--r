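#' Lin similarity between two terms
#'
#' `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))` where the MICA is the
#' common ancestor (reflexively: a term is its own ancestor) with maximal
#' information content. Returns 0 when both terms carry zero IC (the 0/0
#' case, e.g. comparing the root with itself), so the score is always a
#' finite number in [0, 1].
#'
#' @param ic an `ic_table` from [compute_ic()].
#' @param ont the `ontology` the IC table was computed on.
#' @param t1,t2 term ids.
#' @return A number in `[0, 1]`; symmetric in `t1`, `t2`.
#' @export
lin_sim <- function(ic, ont, t1, t2) {
  stopifnot(inherits(ic, "ic_table"), inherits(ont, "ontology"))
  a1 <- ancestors(ont, t1)
  a2 <- ancestors(ont, t2)
  common <- intersect(a1, a2)
  denom <- ic$ic[[t1]] + ic$ic[[t2]]
  if (denom <= 0) return(0)
  mica_ic <- max(ic$ic[common])
  min(1, 2 * mica_ic / denom)
}

#' Pairwise Lin similarity matrix
#'
#' Bulk form of [lin_sim()] used to score many profiles against the same
#' ontology without recomputing ancestor intersections per pair.
#'
#' @param ic an `ic_table`.
#' @param ont an `ontology`.
#' @param terms_a,terms_b term-id vectors; `terms_b` defaults to `terms_a`.
#' @return Numeric matrix of dimension `length(terms_a)` x `length(terms_b)`
#'   with dimnames set to the term ids.
#' @export
term_sim_matrix <- function(ic, ont, terms_a, terms_b = terms_a) {
  stopifnot(inherits(ic, "ic_table"), inherits(ont, "ontology"))
  terms_a <- as.character(terms_a)
  terms_b <- as.character(terms_b)
  m <- matrix(
    0, nrow = length(terms_a), ncol = length(terms_b),
    dimnames = list(terms_a, terms_b)
  )
  anc_a <- ont$ancestors[terms_a]
  anc_b <- ont$ancestors[terms_b]
  icv <- ic$ic
  for (i in seq_along(terms_a)) {
    ai <- anc_a[[i]]
    ic_i <- icv[[terms_a[[i]]]]
    for (j in seq_along(terms_b)) {
      denom <- ic_i + icv[[terms_b[[j]]]]
      if (denom <= 0) next
      common <- intersect(ai, anc_b[[j]])
      m[i, j] <- min(1, 2 * max(icv[common]) / denom)
    }
  }
  m
}

#' Profile-to-profile semantic similarity
#'
#' Symmetric best-match average over Lin term similarities:
#' `0.5 * ( mean_a max_b sim(a, b) + mean_b max_a sim(a, b) )`.
#' An asymmetric variant (patient terms matched against the reference only)
#' is available via `direction = "asymmetric"`, where the first profile is
#' the query.
#'
#' @param ic an `ic_table`.
#' @param ont an `ontology`.
#' @param a,b non-empty character vectors of validated term ids.
#' @param direction `"symmetric"` (default) or `"asymmetric"`.
#' @param simmat optional precomputed [term_sim_matrix()] covering all terms
#'   of both profiles (rows and columns indexed by term id).
#' @return A number in `[0, 1]`.
#' @export
profile_sim <- function(ic, ont, a, b,
                        direction = c("symmetric", "asymmetric"),
                        simmat = NULL) {
  direction <- match.arg(direction)
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) == 0L || length(b) == 0L) stop("profile_sim is undefined on empty profiles")
  if (is.null(simmat)) {
    m <- term_sim_matrix(ic, ont, a, b)
  } else {
    m <- simmat[a, b, drop = FALSE]
  }
  fwd <- mean(apply(m, 1L, max))        # each query term's best match in b
  if (direction == "asymmetric") return(fwd)
  rev <- mean(apply(m, 2L, max))
  0.5 * (fwd + rev)
}

#' Reference profile table
#'
#' Bundles reference proband profiles (published mtDNA disease cases in HPO
#' form) with their disease/variant labels.
#'
#' @param profiles named list of non-empty term-id vectors; names are unique
#'   reference subject ids.
#' @param labels named character vector of free-text labels, aligned with
#'   `profiles`; defaults to the subject ids.
#' @return Object of class `reference_table`.
#' @export
reference_table <- function(profiles, labels = NULL) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("reference profiles need unique non-empty subject ids")
  }
  if (any(vapply(profiles, length, integer(1)) == 0L)) {
    stop("reference profiles must be non-empty")
  }
  if (is.null(labels)) labels <- stats::setNames(ids, ids)
  structure(list(profiles = profiles, labels = labels[ids]), class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("reference_table: ", length(x$profiles), " reference profiles\n", sep = "")
  invisible(x)
}

#' Read a reference profile table from TSV
#'
#' Columns: `subject_id`, `label`, semicolon-separated HPO ids (header
#' required).
#'
#' @param path TSV path.
#' @return A [reference_table()].
#' @export
read_reference_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("reference TSV needs >= 3 columns: ", path)
  profs <- lapply(strsplit(as.character(df[[3L]]), ";", fixed = TRUE), trimws)
  names(profs) <- as.character(df[[1L]])
  reference_table(profs, stats::setNames(as.character(df[[2L]]), names(profs)))
}

#' Write a reference table to TSV
#' @param refs a [reference_table()].
#' @param path output path.
#' @export
write_reference_tsv <- function(refs, path) {
  df <- data.frame(
    subject_id = names(refs$profiles),
    label = unname(refs$labels[names(refs$profiles)]),
    hpo_terms = vapply(refs$profiles, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score one patient against a reference table
#'
#' The patient's phenotype similarity score is the maximum [profile_sim()]
#' over all reference profiles (configurable to the mean); the best-matching
#' reference is reported, ties broken toward the first reference in table
#' order. Scoring uses the validated (not non-redundantly reduced) term set;
#' `n_terms` and `mean_ic` are reported on the reduced set, where redundancy
#' would inflate both.
#'
#' @param ic an `ic_table`.
#' @param ont an `ontology`.
#' @param terms the patient's validated, non-empty term-id vector.
#' @param refs a [reference_table()].
#' @param subject_id patient label carried into the result.
#' @param aggregate `"max"` (default) or `"mean"` over reference profiles.
#' @param direction passed to [profile_sim()].
#' @param simmat optional precomputed similarity matrix covering the patient
#'   and all reference terms.
#' @return One-row data.frame: `subject_id`, `score`, `best_match_id`,
#'   `n_terms`, `mean_ic`.
#' @export
score_patient <- function(ic, ont, terms, refs, subject_id = "<unnamed>",
                          aggregate = c("max", "mean"),
                          direction = c("symmetric", "asymmetric"),
                          simmat = NULL) {
  aggregate <- match.arg(aggregate)
  direction <- match.arg(direction)
  stopifnot(inherits(refs, "reference_table"))
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("cannot score an empty profile")
  sims <- vapply(
    refs$profiles,
    function(r) profile_sim(ic, ont, terms, r, direction = direction, simmat = simmat),
    numeric(1)
  )
  score <- if (aggregate == "max") max(sims) else mean(sims)
  best <- names(refs$profiles)[[which.max(sims)]]  # first index on ties
  red <- reduce_nonredundant(ont, terms)
  data.frame(
    subject_id = subject_id,
    score = score,
    best_match_id = best,
    n_terms = length(red),
    mean_ic = mean(ic$ic[red]),
    stringsAsFactors = FALSE
  )
}

#' Score a whole cohort of patients
#'
#' Precomputes one Lin term-similarity matrix over the union of all terms
#' involved, then applies [score_patient()] per subject.
#'
#' @param ic an `ic_table`.
#' @param ont an `ontology`.
#' @param patients named list of validated term-id vectors.
#' @param refs a [reference_table()].
#' @inheritParams score_patient
#' @return data.frame with one row per patient (columns as
#'   [score_patient()]).
#' @export
score_cohort <- function(ic, ont, patients, refs,
                         aggregate = c("max", "mean"),
                         direction = c("symmetric", "asymmetric")) {
  aggregate <- match.arg(aggregate)
  direction <- match.arg(direction)
  all_terms <- unique(c(
    unlist(patients, use.names = FALSE),
    unlist(refs$profiles, use.names = FALSE)
  ))
  simmat <- term_sim_matrix(ic, ont, all_terms)
  rows <- lapply(names(patients), function(sid) {
    score_patient(
      ic, ont, patients[[sid]], refs, subject_id = sid,
      aggregate = aggregate, direction = direction, simmat = simmat
    )
  })
  do.call(rbind, rows)
}
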