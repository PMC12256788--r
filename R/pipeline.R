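#' Pipeline configuration
#'
#' One flat list of every tunable threshold, with the screening defaults:
#' QC at 50% assembly / 5x depth, heteroplasmy floor 1%, allele-frequency
#' ceiling 0.2%, tier boundaries 0.3 and 0.5. The action map sends high
#' similarity to expert review, medium to an information request, low to no
#' action; LHON/SNHL-class (`actionable`) alleles escalate any tier to
#' report-back, since they are reportable regardless of phenotype match.
#'
#' @param min_fraction,min_depth sample QC gates.
#' @param min_het,max_af prioritization gates.
#' @param min_marker_het haplogroup-marker match floor.
#' @param low_cut,high_cut tier boundaries (0 < low < high < 1).
#' @param aggregate,direction similarity aggregation, see [score_patient()].
#' @param action_map named character: tier -> action.
#' @param seed seed for any stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(min_fraction = 0.5, min_depth = 5,
                            min_het = 0.01, max_af = 0.002,
                            min_marker_het = 0.9,
                            low_cut = 0.3, high_cut = 0.5,
                            aggregate = "max", direction = "symmetric",
                            action_map = c(
                              high = "review", medium = "more_info",
                              low = "no_action"
                            ),
                            seed = 1) {
  stopifnot(low_cut > 0, high_cut > low_cut, high_cut < 1)
  stopifnot(all(c("high", "medium", "low") %in% names(action_map)))
  structure(
    list(
      min_fraction = min_fraction, min_depth = min_depth,
      min_het = min_het, max_af = max_af, min_marker_het = min_marker_het,
      low_cut = low_cut, high_cut = high_cut,
      aggregate = aggregate, direction = direction,
      action_map = action_map, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a flat key = value config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Unknown keys error; values are coerced to the type of the corresponding
#' [pipeline_config()] default. Action-map entries use keys
#' `action_high`, `action_medium`, `action_low`.
#'
#' @param path config file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- pipeline_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[[1L]])
    val <- trimws(kv[[2L]])
    if (key %in% c("action_high", "action_medium", "action_low")) {
      cfg$action_map[[sub("^action_", "", key)]] <- val
    } else if (key %in% names(cfg)) {
      cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
    } else {
      stop("unknown config key: ", key)
    }
  }
  cfg
}

tier_action <- function(tier, actionable, action_map) {
  ifelse(
    is.na(tier), NA_character_,
    ifelse(actionable, "report_back", unname(action_map[tier]))
  )
}

#' Run the full triage pipeline on in-memory tables
#'
#' Executes the end-to-end pathway: profile validation, sample QC,
#' haplogroup-marker exclusion, four-criterion variant prioritization,
#' per-patient phenotype similarity scoring against the reference table,
#' and tier/action assignment. Patients whose phenotype profile is empty
#' after validation are retained with missing score and tier (flagged, not
#' dropped): sparse HPO data is exactly the situation where silent
#' exclusion would hide true diagnoses.
#'
#' @param ontology an `ontology`.
#' @param references a [reference_table()] (also the default IC corpus).
#' @param patients named list of raw term-id vectors (one per subject).
#' @param variants,annotation,qc,markers variant-side tables, see
#'   [filter_cohort()].
#' @param config a [pipeline_config()].
#' @param ic optional precomputed `ic_table`; default: IC from the
#'   reference profiles.
#' @return List of class `pipeline_result`: `candidates` (one row per
#'   surviving variant-sample pair with score, tier, action), `scores`
#'   (per-patient score table incl. unscored patients), `funnel` (named
#'   stage counts), `config`.
#' @export
run_pipeline <- function(ontology, references, patients, variants,
                         annotation, qc, markers,
                         config = pipeline_config(), ic = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  # phenotype side: validate, score; empty-after-validation kept as NA
  validated <- vector("list", length(patients))
  names(validated) <- names(patients)
  empty_flag <- logical(length(patients))
  names(empty_flag) <- names(patients)
  for (sid in names(patients)) {
    validated[[sid]] <- tryCatch(
      suppressWarnings(validate_profile(ontology, patients[[sid]], sid)),
      error = function(e) character(0)
    )
    empty_flag[[sid]] <- length(validated[[sid]]) == 0L
  }
  if (is.null(ic)) ic <- compute_ic(ontology, references$profiles)

  scorable <- validated[!empty_flag]
  scores <- if (length(scorable)) {
    score_cohort(
      ic, ontology, scorable, references,
      aggregate = config$aggregate, direction = config$direction
    )
  } else {
    data.frame(
      subject_id = character(0), score = numeric(0),
      best_match_id = character(0), n_terms = integer(0), mean_ic = numeric(0)
    )
  }
  if (any(empty_flag)) {
    scores <- rbind(scores, data.frame(
      subject_id = names(patients)[empty_flag], score = NA_real_,
      best_match_id = NA_character_, n_terms = 0L, mean_ic = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  scores <- scores[match(names(patients), scores$subject_id), , drop = FALSE]
  rownames(scores) <- NULL
  scores$no_phenotype <- unname(empty_flag[scores$subject_id])
  scores$tier <- classify_tier(scores$score, config$low_cut, config$high_cut)

  # variant side
  filt <- filter_cohort(
    qc, variants, annotation, markers,
    min_fraction = config$min_fraction, min_depth = config$min_depth,
    min_het = config$min_het, max_af = config$max_af,
    min_marker_het = config$min_marker_het
  )
  cand <- filt$candidates
  si <- match(cand$sample_id, scores$subject_id)
  cand$score <- scores$score[si]
  cand$best_match_id <- scores$best_match_id[si]
  cand$n_hpo_terms <- scores$n_terms[si]
  cand$mean_ic <- scores$mean_ic[si]
  cand$tier <- scores$tier[si]
  cand$action <- tier_action(cand$tier, cand$actionable, config$action_map)

  funnel <- c(
    filt$funnel,
    scored = sum(!is.na(cand$score)),
    tier_high = sum(cand$tier == "high", na.rm = TRUE),
    tier_medium = sum(cand$tier == "medium", na.rm = TRUE),
    tier_low = sum(cand$tier == "low", na.rm = TRUE),
    tier_missing = sum(is.na(cand$tier))
  )

  structure(
    list(candidates = cand, scores = scores, funnel = funnel, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result funnel:\n")
  for (nm in names(x$funnel)) cat(sprintf("  %-12s %d\n", nm, x$funnel[[nm]]))
  invisible(x)
}

#' Run the pipeline from files on disk
#'
#' Thin file-based wrapper over [run_pipeline()]: reads the ontology (OBO),
#' reference table, patient profiles and the four variant-side TSVs, runs
#' the pipeline, and (when `out_dir` is given) writes `candidates.tsv`,
#' `scores.tsv` and `run_summary.json` (funnel counts and thresholds).
#'
#' @param ontology_path OBO file.
#' @param references_path reference TSV (subject_id, label, terms).
#' @param patients_path profile TSV (subject_id, terms).
#' @param variants_path,annotation_path,qc_path,markers_path variant-side
#'   TSVs.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return The `pipeline_result`, invisibly when writing files.
#' @export
run_pipeline_files <- function(ontology_path, references_path, patients_path,
                               variants_path, annotation_path, qc_path,
                               markers_path, config = pipeline_config(),
                               out_dir = NULL) {
  ontology <- parse_obo(ontology_path)
  references <- read_reference_tsv(references_path)
  patients <- read_profiles_tsv(patients_path)
  variants <- read_variants_tsv(variants_path)
  annotation <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  qc <- utils::read.delim(qc_path, stringsAsFactors = FALSE)
  markers <- utils::read.delim(markers_path, stringsAsFactors = FALSE)
  res <- run_pipeline(
    ontology, references, patients, variants, annotation, qc, markers,
    config = config
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    num <- vapply(res$candidates, is.numeric, logical(1))
    cand_out <- res$candidates
    cand_out[num] <- lapply(cand_out[num], function(x) round(x, 6))
    utils::write.table(
      cand_out, file.path(out_dir, "candidates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    sc <- res$scores
    sc$score <- round(sc$score, 6)
    sc$mean_ic <- round(sc$mean_ic, 6)
    utils::write.table(
      sc, file.path(out_dir, "scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      list(
        funnel = as.list(res$funnel),
        thresholds = res$config[c(
          "min_fraction", "min_depth", "min_het", "max_af",
          "min_marker_het", "low_cut", "high_cut"
        )]
      ),
      file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    return(invisible(res))
  }
  res
}

#' Calibrate phenotype-similarity thresholds on a labeled cohort
#'
#' Wraps the ROC analysis, Youden's optimum, fixed-threshold operating
#' points and the three-group rank comparison into one summary, mirroring
#' how the score thresholds were established on a genetically diagnosed
#' phenotype test cohort.
#'
#' @param scores data.frame with `subject_id`, `score`, `group` (groups
#'   `mtDNA` / `nuclear_mito` / `nuclear_other`).
#' @param at thresholds at which to report sensitivity/specificity
#'   (defaults: the sensitive floor 0.3, the Youden-derived 0.48, and the
#'   rounded 0.5).
#' @param ci_method passed to [roc()].
#' @return List: `auc`, `auc_ci`, `youden` (threshold/sens/spec/j),
#'   `at_thresholds` (data.frame threshold/sens/spec), `groups`
#'   (`group_comparison`, `NULL` when fewer than two labeled groups have
#'   two observations).
#' @export
calibrate_thresholds <- function(scores, at = c(0.3, 0.48, 0.5),
                                 ci_method = "delong") {
  keep <- !is.na(scores$score)
  scores <- scores[keep, , drop = FALSE]
  r <- roc(scores, ci_method = ci_method)
  yo <- youden_optimal(r)
  at_tab <- do.call(rbind, lapply(at, function(th) {
    ss <- sens_spec_at(scores, th)
    data.frame(threshold = th, sens = ss$sens, spec = ss$spec)
  }))
  glist <- split(scores$score, scores$group)
  glist <- glist[vapply(glist, length, integer(1)) >= 2L]
  cmp <- if (length(glist) >= 2L) kruskal_dunn(glist) else NULL
  list(
    auc = r$auc, auc_ci = r$auc_ci, youden = yo,
    at_thresholds = at_tab, groups = cmp, roc = r
  )
}
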