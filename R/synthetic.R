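#' Generate a random rooted DAG ontology
#'
#' Terms are added one at a time; each new term attaches by is_a edges to
#' between 1 and `max_parents` uniformly chosen existing terms, so the
#' graph is acyclic by construction and every term reaches the root.
#' Used as the property-test substrate for the ontology and similarity
#' operations.
#'
#' @param n_terms number of terms including the root (>= 2).
#' @param max_parents maximum is_a out-degree of a new term.
#' @param seed RNG seed; the result is a pure function of the arguments.
#' @return An `ontology` with ids `T001 ... T<n>` (root `T001`).
#' @export
generate_random_ontology <- function(n_terms, max_parents = 2, seed = 1) {
  if (n_terms < 2L) stop("n_terms must be >= 2")
  withr::with_seed(seed, {
    ids <- sprintf("T%03d", seq_len(n_terms))
    parents <- vector("list", n_terms)
    parents[[1L]] <- character(0)
    for (i in 2:n_terms) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[i]] <- ids[sample.int(i - 1L, k)]
    }
    terms <- data.frame(
      id = ids, name = paste("term", ids), stringsAsFactors = FALSE
    )
    terms$parents <- I(parents)
    build_ontology(terms)
  })
}

#' Generate reference disease profiles on an ontology
#'
#' Each profile draws distinct non-root terms with probability proportional
#' to term depth (deeper = more specific), mirroring how curated disease
#' annotations skew toward specific clinical findings. Profiles are
#' mutually distinct as term sets.
#'
#' @param ont an `ontology`.
#' @param n_profiles number of reference profiles.
#' @param terms_per_profile length-2 integer range (inclusive) for profile
#'   size.
#' @param seed RNG seed.
#' @param prefix subject-id prefix.
#' @return A [reference_table()]; empty list when `n_profiles = 0`.
#' @export
generate_reference_profiles <- function(ont, n_profiles,
                                        terms_per_profile = c(5, 10),
                                        seed = 1, prefix = "REF") {
  stopifnot(inherits(ont, "ontology"), length(terms_per_profile) == 2L)
  nonroot <- setdiff(names(ont$ancestors), ont$root)
  if (length(nonroot) < 2L * max(terms_per_profile)) {
    stop("ontology too small for the requested profile sizes")
  }
  if (n_profiles == 0L) {
    return(structure(
      list(profiles = stats::setNames(list(), character(0)), labels = character(0)),
      class = "reference_table"
    ))
  }
  withr::with_seed(seed, {
    w <- ont$depth[nonroot]
    profiles <- list()
    seen <- character(0)
    attempts <- 0L
    while (length(profiles) < n_profiles) {
      attempts <- attempts + 1L
      if (attempts > 50L * n_profiles) {
        stop("could not generate ", n_profiles, " mutually distinct profiles")
      }
      k <- sample(seq(terms_per_profile[[1L]], terms_per_profile[[2L]]), 1L)
      prof <- sample(nonroot, k, prob = w)
      key <- paste(sort(prof), collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      profiles[[length(profiles) + 1L]] <- prof
    }
    names(profiles) <- sprintf("%s%03d", prefix, seq_len(n_profiles))
    reference_table(
      profiles,
      stats::setNames(sprintf("synthetic disease %03d", seq_len(n_profiles)), names(profiles))
    )
  })
}

#' Sample a noisy patient profile from a reference
#'
#' Models the two annotation-quality failure modes that depress phenotype
#' similarity in practice: term loss (each reference term independently
#' dropped with probability `dropout`) and loss of specificity (each
#' surviving term replaced, with probability `imprecision`, by a uniformly
#' chosen strict ancestor other than the root; terms whose only strict
#' ancestor is the root are kept). `noise_terms` unrelated uniform random
#' terms are then appended. If dropout removes everything, one reference
#' term is retained: scoring is undefined on empty profiles, so the
#' generator never emits them.
#'
#' @param ont an `ontology`.
#' @param ref non-empty character vector: the source reference profile.
#' @param dropout,imprecision probabilities in `[0, 1]`.
#' @param noise_terms non-negative count of random terms to append.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (so cohort generation stays a single reproducible stream).
#' @return Character vector of term ids (deduplicated, never empty).
#' @export
sample_patient <- function(ont, ref, dropout = 0.3, imprecision = 0.2,
                           noise_terms = 2, seed = NULL) {
  stopifnot(length(ref) > 0L)
  run <- function() {
    keep <- stats::runif(length(ref)) >= dropout
    if (!any(keep)) keep[sample.int(length(ref), 1L)] <- TRUE
    terms <- ref[keep]
    terms <- vapply(terms, function(t) {
      if (stats::runif(1) < imprecision) {
        anc <- setdiff(ont$ancestors[[t]], c(t, ont$root))
        if (length(anc)) return(anc[[sample.int(length(anc), 1L)]])
      }
      t
    }, character(1), USE.NAMES = FALSE)
    if (noise_terms > 0L) {
      pool <- setdiff(names(ont$ancestors), ont$root)
      terms <- c(terms, sample(pool, min(noise_terms, length(pool))))
    }
    unique(terms)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Cohort generator settings
#'
#' Defaults reproduce the structure of a phenotype test cohort of 47
#' mtDNA-disease patients against 1,460 nuclear-diagnosis patients (122
#' nuclear-mitochondrial, 1,338 nuclear-other), with 10% of samples
#' failing mtDNA QC and spiked causal variants at heteroplasmies spanning
#' 1-100%.
#'
#' @param n_mtdna,n_nuclear_mito,n_nuclear_other group sizes.
#' @param dropout,imprecision,noise_terms phenotype noise model, see
#'   [sample_patient()].
#' @param terms_per_reference profile-size range for generated references.
#' @param n_references number of reference profiles when generating them
#'   (ignored when the packaged reference table is used).
#' @param terms_per_patient profile-size range for nuclear patients' fresh
#'   random term sets.
#' @param qc_fail_fraction fraction of samples failing mtDNA QC.
#' @param het_range heteroplasmy range (uniform) for spiked causal variants.
#' @param background_rate mean number of benign background variants per
#'   sample (Poisson).
#' @param seed master RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mtdna = 47, n_nuclear_mito = 122,
                        n_nuclear_other = 1338,
                        dropout = 0.3, imprecision = 0.2, noise_terms = 2,
                        terms_per_reference = c(5, 10), n_references = 15,
                        terms_per_patient = c(3, 10),
                        qc_fail_fraction = 0.1, het_range = c(0.01, 1),
                        background_rate = 1.5, seed = 1) {
  spec <- list(
    n_mtdna = n_mtdna, n_nuclear_mito = n_nuclear_mito,
    n_nuclear_other = n_nuclear_other, dropout = dropout,
    imprecision = imprecision, noise_terms = noise_terms,
    terms_per_reference = terms_per_reference, n_references = n_references,
    terms_per_patient = terms_per_patient,
    qc_fail_fraction = qc_fail_fraction, het_range = het_range,
    background_rate = background_rate, seed = seed
  )
  stopifnot(
    n_mtdna >= 0, n_nuclear_mito >= 0, n_nuclear_other >= 0,
    dropout >= 0, dropout <= 1, imprecision >= 0, imprecision <= 1,
    noise_terms >= 0, qc_fail_fraction >= 0, qc_fail_fraction <= 1,
    het_range[[1L]] >= 0, het_range[[2L]] <= 1
  )
  structure(spec, class = "cohort_spec")
}

# Synthetic MITOMAP-style catalog of well-described pathogenic mtDNA
# alleles (status/AF values are stand-ins, not database content).
# `actionable` flags LHON/SNHL-class variably penetrant alleles.
pathogenic_catalog <- function() {
  data.frame(
    position = c(3243L, 8344L, 13513L, 8993L, 9176L, 11778L, 14484L, 3460L, 1555L, 5698L, 9032L),
    ref = c("A", "A", "G", "T", "T", "G", "T", "G", "A", "G", "T"),
    alt = c("G", "G", "A", "G", "C", "A", "C", "A", "G", "A", "C"),
    mitomap_status = c(
      "confirmed", "confirmed", "confirmed", "confirmed", "reported",
      "confirmed", "confirmed", "confirmed", "confirmed", "reported", "reported"
    ),
    mitomap_af = c(1e-4, 1e-4, 5e-5, 1e-4, 2e-4, 5e-4, 3e-4, 2e-4, 1e-3, 5e-4, 8e-4),
    in_mitophen = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    gene = c(
      "MT-TL1", "MT-TK", "MT-ND5", "MT-ATP6", "MT-ATP6",
      "MT-ND4", "MT-ND6", "MT-ND1", "MT-RNR1", "MT-TN", "MT-ATP6"
    ),
    actionable = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Benign background alleles: common ("reported" with AF above the rarity
# ceiling) or absent from the annotation entirely.
benign_catalog <- function() {
  data.frame(
    position = c(14696L, 16189L, 152L, 709L, 11914L, 15326L),
    ref = c("A", "T", "T", "G", "G", "A"),
    alt = c("G", "C", "C", "A", "A", "G"),
    mitomap_status = c("reported", "reported", "reported", "absent", "absent", "reported"),
    mitomap_af = c(0.01, 0.05, 0.2, NA, NA, 0.9),
    in_mitophen = FALSE,
    gene = c("MT-ND6", "MT-DLOOP", "MT-DLOOP", "MT-RNR1", "MT-ND4", "MT-CYB"),
    actionable = FALSE,
    stringsAsFactors = FALSE
  )
}

# Synthetic haplogroup-defining marker sets (Phylotree-flavoured stand-in).
haplogroup_markers <- function() {
  mk <- function(hg, pos, ref, alt) {
    data.frame(
      haplogroup = hg, position = as.integer(pos), ref = ref, alt = alt,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    mk("H", c(7028, 2706, 1438), c("C", "A", "A"), c("T", "G", "G")),
    mk("J", c(295, 489, 10398, 12612), c("C", "T", "A", "G"), c("T", "C", "G", "A")),
    mk("K", c(1811, 9055, 14167), c("A", "G", "C"), c("G", "A", "T")),
    mk("T", c(1888, 4917, 13368), c("G", "A", "G"), c("A", "G", "A")),
    mk("U", c(11467, 12308, 12372), c("A", "A", "G"), c("G", "G", "A"))
  )
}

#' Generate a complete synthetic cohort
#'
#' Builds every table the pipeline consumes, with known ground truth:
#' mtDNA-group patients are noisy copies of randomly chosen reference
#' profiles and carry exactly one spiked causal variant (disease-associated
#' in the annotation table) plus haplogroup markers and benign background
#' variants; nuclear-group patients carry fresh random term sets and only
#' background variants; a configured fraction of samples fails QC. Fully
#' deterministic given the spec (which includes the seed).
#'
#' @param spec a [cohort_spec()].
#' @param ontology an `ontology`; default: the packaged fixture ontology.
#' @param references a [reference_table()]; default: `spec$n_references`
#'   profiles generated on the ontology with
#'   [generate_reference_profiles()] (sizes from
#'   `spec$terms_per_reference`, seeded from `spec$seed`). Pass
#'   [fixture_references()] to use the packaged hand-composed table
#'   instead.
#' @return List of class `synthetic_cohort`: `ontology`, `references`,
#'   `patients` (named list of term vectors), `groups` (named character),
#'   `variants`, `annotation`, `qc`, `markers` (data.frames), `truth`
#'   (data.frame `sample_id`, `group`, `is_mtdna_case`, `causal_variant`,
#'   `source_ref`, `qc_fail`).
#' @export
generate_cohort <- function(spec = cohort_spec(), ontology = NULL,
                            references = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(ontology)) ontology <- fixture_ontology()
  if (is.null(references)) {
    references <- generate_reference_profiles(
      ontology, spec$n_references,
      terms_per_profile = spec$terms_per_reference,
      seed = spec$seed + 1000003L
    )
  }
  stopifnot(inherits(ontology, "ontology"), inherits(references, "reference_table"))

  withr::with_seed(spec$seed, {
    path_cat <- pathogenic_catalog()
    ben_cat <- benign_catalog()
    markers <- haplogroup_markers()
    hg_pool <- c("H", "U", "J", "T", "K")
    hg_prob <- c(0.45, 0.20, 0.12, 0.12, 0.11)  # European-ancestry-like mix
    nonroot <- setdiff(names(ontology$ancestors), ontology$root)

    n_total <- spec$n_mtdna + spec$n_nuclear_mito + spec$n_nuclear_other
    groups <- c(
      rep("mtDNA", spec$n_mtdna),
      rep("nuclear_mito", spec$n_nuclear_mito),
      rep("nuclear_other", spec$n_nuclear_other)
    )
    sample_ids <- sprintf("S%05d", seq_len(n_total))
    names(groups) <- sample_ids

    qc_fail <- stats::runif(n_total) < spec$qc_fail_fraction
    names(qc_fail) <- sample_ids

    patients <- vector("list", n_total)
    names(patients) <- sample_ids
    source_ref <- rep(NA_character_, n_total)
    causal <- rep(NA_character_, n_total)

    var_rows <- list()
    add_var <- function(sid, pos, ref, alt, het, depth) {
      var_rows[[length(var_rows) + 1L]] <<- data.frame(
        sample_id = sid, position = as.integer(pos), ref = ref, alt = alt,
        heteroplasmy = het, depth = depth, stringsAsFactors = FALSE
      )
    }

    for (i in seq_len(n_total)) {
      sid <- sample_ids[[i]]
      depth_i <- round(stats::runif(1, 20, 200))
      # haplogroup markers (near-homoplasmic lineage polymorphisms)
      hg_i <- sample(hg_pool, 1L, prob = hg_prob)
      mk <- markers[markers$haplogroup == hg_i, , drop = FALSE]
      for (j in seq_len(nrow(mk))) {
        add_var(sid, mk$position[[j]], mk$ref[[j]], mk$alt[[j]],
                stats::runif(1, 0.97, 1), depth_i)
      }
      # benign background variants
      nb <- stats::rpois(1, spec$background_rate)
      if (nb > 0L) {
        bi <- sample.int(nrow(ben_cat), min(nb, nrow(ben_cat)))
        for (j in bi) {
          add_var(sid, ben_cat$position[[j]], ben_cat$ref[[j]], ben_cat$alt[[j]],
                  stats::runif(1, 0.05, 1), depth_i)
        }
      }
      if (groups[[i]] == "mtDNA") {
        ri <- sample.int(length(references$profiles), 1L)
        source_ref[[i]] <- names(references$profiles)[[ri]]
        patients[[i]] <- sample_patient(
          ontology, references$profiles[[ri]],
          dropout = spec$dropout, imprecision = spec$imprecision,
          noise_terms = spec$noise_terms
        )
        ci <- sample.int(nrow(path_cat), 1L)
        het <- stats::runif(1, spec$het_range[[1L]], spec$het_range[[2L]])
        add_var(sid, path_cat$position[[ci]], path_cat$ref[[ci]],
                path_cat$alt[[ci]], het, depth_i)
        causal[[i]] <- variant_key(
          path_cat$position[[ci]], path_cat$ref[[ci]], path_cat$alt[[ci]]
        )
      } else {
        k <- sample(seq(spec$terms_per_patient[[1L]], spec$terms_per_patient[[2L]]), 1L)
        patients[[i]] <- sample(nonroot, min(k, length(nonroot)))
      }
    }

    variants <- do.call(rbind, var_rows)
    qc <- data.frame(
      sample_id = sample_ids,
      assembled_fraction = ifelse(
        qc_fail,
        stats::runif(n_total, 0.05, 0.49),
        stats::runif(n_total, 0.6, 1)
      ),
      mean_depth = ifelse(
        qc_fail,
        stats::runif(n_total, 0.5, 4.9),
        stats::runif(n_total, 7, 200)
      ),
      assay = sample(c("ES", "GS"), n_total, replace = TRUE, prob = c(0.95, 0.05)),
      tissue = "blood",
      stringsAsFactors = FALSE
    )
    annotation <- rbind(path_cat, ben_cat)
    truth <- data.frame(
      sample_id = sample_ids,
      group = unname(groups),
      is_mtdna_case = unname(groups == "mtDNA"),
      causal_variant = causal,
      source_ref = source_ref,
      qc_fail = unname(qc_fail),
      stringsAsFactors = FALSE
    )
    structure(
      list(
        ontology = ontology, references = references, patients = patients,
        groups = groups, variants = variants, annotation = annotation,
        qc = qc, markers = markers, truth = truth, spec = spec
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "synthetic_cohort: ", length(x$patients), " patients (",
    sum(x$truth$is_mtdna_case), " mtDNA cases), ",
    nrow(x$variants), " variant calls, seed ", x$spec$seed, "\n", sep = ""
  )
  invisible(x)
}

#' Packaged fixture ontology
#'
#' A small hand-written synthetic phenotype ontology (~60 terms, OBO
#' format) shaped like the mitochondrial-disease corner of the HPO, so
#' worked examples and tests have stable term ids.
#'
#' @return An `ontology`.
#' @export
fixture_ontology <- function() {
  parse_obo(system.file("extdata", "synthetic_hpo.obo", package = "mitotriage"))
}

#' Packaged synthetic reference profiles
#'
#' Hand-composed profiles on the fixture ontology emulating classic mtDNA
#' disease presentations (MELAS-like, MERRF-like, LHON-like, ...). These
#' are synthetic stand-ins sharing only the schema of a curated
#' genotype-phenotype database.
#'
#' @return A [reference_table()].
#' @export
fixture_references <- function() {
  read_reference_tsv(
    system.file("extdata", "synthetic_references.tsv", package = "mitotriage")
  )
}

#' Write a synthetic cohort's tables to a directory
#'
#' Materializes every table in the TSV dialects the pipeline reads
#' (variants, QC, annotation, markers, patient profiles, references) plus
#' the truth table; byte-identical across runs for the same cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(
      df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  wt(cohort$variants, "variants.tsv")
  wt(cohort$qc, "qc.tsv")
  wt(cohort$annotation, "annotation.tsv")
  wt(cohort$markers, "markers.tsv")
  wt(cohort$truth, "truth.tsv")
  write_profiles_tsv(cohort$patients, file.path(dir, "patients.tsv"))
  write_reference_tsv(cohort$references, file.path(dir, "references.tsv"))
  invisible(dir)
}
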