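#' Phenotype ontology container
#'
#' An `ontology` object holds a rooted directed acyclic graph of phenotype
#' terms linked by is_a edges, as parsed from an OBO file or built by the
#' synthetic generator. Obsolete terms are retained (with their
#' `replaced_by` pointer when present) but excluded from all graph queries.
#'
#' @param terms data.frame with columns `id`, `name`, `parents`
#'   (list-column of character vectors), `obsolete` (logical),
#'   `replaced_by` (character, `NA` when absent).
#' @param root optional term id to use as root; by default the unique
#'   non-obsolete term without parents.
#' @return An object of class `ontology` with elements `ids`, `name`,
#'   `parents`, `obsolete`, `replaced_by`, `root`, `ancestors` (reflexive
#'   transitive closure per non-obsolete term) and `depth` (longest is_a
#'   path from the root).
#' @export
build_ontology <- function(terms, root = NULL) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "parents") %in% names(terms)))
  ids <- as.character(terms$id)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  obsolete <- if ("obsolete" %in% names(terms)) as.logical(terms$obsolete) else rep(FALSE, length(ids))
  replaced_by <- if ("replaced_by" %in% names(terms)) as.character(terms$replaced_by) else rep(NA_character_, length(ids))
  parents <- lapply(terms$parents, function(p) unique(as.character(p)))
  names(parents) <- ids
  names(obsolete) <- ids
  names(replaced_by) <- ids
  nm <- as.character(terms$name)
  names(nm) <- ids

  active <- ids[!obsolete]
  # parents of active terms must themselves be active terms
  for (t in active) {
    bad <- setdiff(parents[[t]], active)
    if (length(bad)) {
      stop("term ", t, " has unknown or obsolete parent(s): ", paste(bad, collapse = ", "))
    }
  }

  if (is.null(root)) {
    parentless <- active[vapply(parents[active], length, integer(1)) == 0L]
    if (length(parentless) == 0L) {
      stop("no parentless term found; the is_a graph has no root (cyclic?)")
    }
    if (length(parentless) > 1L) {
      stop(
        "multiple parentless terms (", paste(parentless, collapse = ", "),
        "); supply `root` explicitly"
      )
    }
    root <- parentless
  } else {
    if (!root %in% active) stop("configured root ", root, " is not an active term")
    if (length(parents[[root]])) stop("configured root ", root, " has parents")
  }

  ord <- topological_order(active, parents)

  # reflexive transitive closure and longest-path depth, in topological order
  anc <- vector("list", length(active))
  names(anc) <- active
  depth <- stats::setNames(rep(NA_integer_, length(active)), active)
  for (t in ord) {
    ps <- parents[[t]]
    if (length(ps) == 0L) {
      anc[[t]] <- t
      depth[[t]] <- 0L
    } else {
      anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
      depth[[t]] <- max(depth[ps]) + 1L
    }
  }

  unreachable <- active[vapply(anc, function(a) !(root %in% a), logical(1))]
  if (length(unreachable)) {
    stop(
      "term(s) without a path to root ", root, ": ",
      paste(unreachable, collapse = ", ")
    )
  }

  structure(
    list(
      ids = ids, name = nm, parents = parents, obsolete = obsolete,
      replaced_by = replaced_by, root = root, ancestors = anc, depth = depth
    ),
    class = "ontology"
  )
}

# Kahn topological sort over the is_a graph; stops on cycles.
topological_order <- function(active, parents) {
  indeg <- stats::setNames(integer(length(active)), active)
  children <- stats::setNames(vector("list", length(active)), active)
  for (t in active) {
    for (p in parents[[t]]) {
      children[[p]] <- c(children[[p]], t)
      indeg[[t]] <- indeg[[t]] + 1L
    }
  }
  queue <- active[indeg[active] == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(active)) {
    stop("cycle detected in is_a graph involving: ",
         paste(setdiff(active, out), collapse = ", "))
  }
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat(
    "ontology: ", sum(!x$obsolete), " active terms (",
    sum(x$obsolete), " obsolete), root ", x$root, "\n", sep = ""
  )
  invisible(x)
}

#' Parse an OBO-format ontology
#'
#' Reads the OBO v1.2/1.4 subset used for phenotype ontologies: `[Term]`
#' stanzas with `id`, `name`, `is_a`, `is_obsolete` and `replaced_by` tags.
#' Only is_a edges are retained; every other relationship type and tag is
#' ignored. The root is detected as the unique parentless active term unless
#' configured.
#'
#' @param path path to an OBO file.
#' @param root optional root term id, required when the file has several
#'   parentless terms.
#' @return An [build_ontology()] `ontology` object.
#' @export
parse_obo <- function(path, root = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(trimws(lines) == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanza in ", path)

  recs <- list()
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[[k]] + 1L
    to <- if (k < length(stanza_starts)) stanza_starts[[k + 1L]] - 1L else length(lines)
    block <- lines[from:to]
    # a stanza ends at the next header of any kind
    hdr <- grep("^\\[", trimws(block))
    if (length(hdr)) block <- block[seq_len(hdr[[1L]] - 1L)]

    id <- NA_character_; nm <- NA_character_
    parents <- character(0); obs <- FALSE; rep_by <- NA_character_
    for (j in seq_along(block)) {
      ln <- trimws(block[[j]])
      if (ln == "" || startsWith(ln, "!")) next
      m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
      if (length(m) != 3L) {
        stop("malformed OBO line ", from + j - 1L, ": ", ln)
      }
      tag <- m[[2L]]
      val <- sub("\\s*!.*$", "", m[[3L]])  # strip trailing comment
      val <- trimws(val)
      if (tag == "id") id <- val
      else if (tag == "name") nm <- val
      else if (tag == "is_a") parents <- c(parents, sub("\\s.*$", "", val))
      else if (tag == "is_obsolete") obs <- identical(tolower(val), "true")
      else if (tag == "replaced_by") rep_by <- val
      # all other tags ignored
    }
    if (is.na(id)) {
      stop("[Term] stanza starting at line ", stanza_starts[[k]], " has no id")
    }
    recs[[k]] <- list(
      id = id, name = if (is.na(nm)) id else nm,
      parents = parents, obsolete = obs, replaced_by = rep_by
    )
  }

  terms <- data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    name = vapply(recs, `[[`, character(1), "name"),
    obsolete = vapply(recs, `[[`, logical(1), "obsolete"),
    replaced_by = vapply(recs, `[[`, character(1), "replaced_by"),
    stringsAsFactors = FALSE
  )
  terms$parents <- I(lapply(recs, `[[`, "parents"))
  # obsolete terms keep no edges
  terms$parents[terms$obsolete] <- list(character(0))
  build_ontology(terms, root = root)
}

#' Ancestors of a term
#'
#' Reflexive transitive closure over is_a edges: the term itself, all its
#' parents, their parents, and so on up to (and including) the root.
#'
#' @param ont an `ontology`.
#' @param term a single term id.
#' @return Character vector of term ids.
#' @export
ancestors <- function(ont, term) {
  stopifnot(inherits(ont, "ontology"))
  a <- ont$ancestors[[term]]
  if (is.null(a)) stop("unknown or obsolete term: ", term)
  a
}

#' Validate a phenotype profile against an ontology
#'
#' Unknown term ids are dropped with a warning; obsolete terms are mapped
#' through their `replaced_by` pointer when one exists and dropped (with a
#' warning) otherwise; the result is deduplicated.
#'
#' @param ont an `ontology`.
#' @param terms character vector of term ids (one subject's profile).
#' @param subject_id subject label used in messages.
#' @return Character vector of valid, non-obsolete, deduplicated term ids.
#'   Errors if nothing survives: downstream scoring is undefined on empty
#'   profiles.
#' @export
validate_profile <- function(ont, terms, subject_id = "<unnamed>") {
  stopifnot(inherits(ont, "ontology"))
  terms <- unique(as.character(terms))
  terms <- terms[!is.na(terms) & nzchar(terms)]
  out <- character(0)
  dropped <- character(0)
  for (t in terms) {
    if (!t %in% ont$ids) {
      dropped <- c(dropped, t)
    } else if (ont$obsolete[[t]]) {
      rb <- ont$replaced_by[[t]]
      if (!is.na(rb) && rb %in% ont$ids && !ont$obsolete[[rb]]) {
        out <- c(out, rb)
      } else {
        dropped <- c(dropped, t)
      }
    } else {
      out <- c(out, t)
    }
  }
  if (length(dropped)) {
    warning(
      "profile ", subject_id, ": dropped ", length(dropped),
      " unknown/obsolete term(s): ", paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  out <- unique(out)
  if (length(out) == 0L) {
    stop("profile ", subject_id, " is empty after validation")
  }
  out
}

#' Reduce a term set to non-redundant form
#'
#' Removes every term that is a strict ancestor of another term in the set,
#' keeping the most specific terms only. Idempotent.
#'
#' @param ont an `ontology`.
#' @param terms character vector of valid term ids.
#' @return Character vector: the maximal subset with no ancestor-descendant
#'   pair.
#' @export
reduce_nonredundant <- function(ont, terms) {
  stopifnot(inherits(ont, "ontology"))
  terms <- unique(as.character(terms))
  if (length(terms) <= 1L) return(terms)
  is_strict_anc_of_other <- vapply(terms, function(t) {
    any(vapply(terms, function(s) s != t && t %in% ont$ancestors[[s]], logical(1)))
  }, logical(1))
  terms[!is_strict_anc_of_other]
}

#' Information content from an annotation corpus
#'
#' Annotation frequencies propagate to ancestors: a profile annotated with a
#' term implicitly annotates every ancestor of that term. For each active
#' term t, `freq(t)` is the number of corpus profiles whose implied closure
#' contains t, and `IC(t) = -log(freq(t) / N)` in nats. Terms never
#' annotated get the smoothed frequency `N / (N + 1)`-complement, i.e.
#' probability `1 / (N + 1)`, so IC stays finite for rare reference terms.
#' The root is implied by every profile, hence `IC(root) = 0`.
#'
#' @param ont an `ontology`.
#' @param corpus list of character vectors of term ids (validated profiles).
#' @return An object of class `ic_table`: list with `ic` (named numeric over
#'   active terms, nats) and `corpus_size`.
#' @export
compute_ic <- function(ont, corpus) {
  stopifnot(inherits(ont, "ontology"))
  if (!is.list(corpus) || length(corpus) == 0L) stop("corpus must be a non-empty list of profiles")
  n <- length(corpus)
  active <- ont$ids[!ont$obsolete]
  freq <- stats::setNames(integer(length(active)), active)
  for (prof in corpus) {
    if (length(prof) == 0L) stop("corpus contains an empty profile")
    if (!all(prof %in% names(ont$ancestors))) {
      stop("corpus profile contains unknown terms: ",
           paste(setdiff(prof, names(ont$ancestors)), collapse = ", "))
    }
    implied <- unique(unlist(ont$ancestors[prof], use.names = FALSE))
    freq[implied] <- freq[implied] + 1L
  }
  p <- ifelse(freq == 0L, 1 / (n + 1), freq / n)
  ic <- -log(p)
  ic[ic < 0] <- 0  # guard against -0
  structure(list(ic = ic, corpus_size = n), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(
    "ic_table: ", length(x$ic), " terms, corpus of ", x$corpus_size,
    " profiles, max IC ", format(max(x$ic), digits = 4), " nats\n", sep = ""
  )
  invisible(x)
}

#' Read profiles from a two-column TSV
#'
#' Expected columns: `subject_id` and a semicolon-separated term-id list.
#' A header row is required.
#'
#' @param path TSV file path.
#' @return Named list of character vectors (names are subject ids).
#' @export
read_profiles_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("profile TSV needs >= 2 columns: ", path)
  profs <- lapply(strsplit(as.character(df[[2L]]), ";", fixed = TRUE), trimws)
  names(profs) <- as.character(df[[1L]])
  profs
}

#' Write profiles to a two-column TSV
#'
#' @param profiles named list of term-id vectors.
#' @param path output path.
#' @param id_col,terms_col column names.
#' @export
write_profiles_tsv <- function(profiles, path, id_col = "subject_id",
                               terms_col = "hpo_terms") {
  df <- data.frame(
    a = names(profiles),
    b = vapply(profiles, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  names(df) <- c(id_col, terms_col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
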