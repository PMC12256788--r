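# rCRS is the 16,569 bp canonical human mtDNA coordinate system (1-based).
RCRS_LENGTH <- 16569L

#' Sample-level mtDNA quality control
#'
#' A dataset qualifies when at least `min_fraction` of the mitochondrial
#' genome was assembled and mean chrM depth is at least `min_depth`; both
#' thresholds inclusive. Defaults match the screening thresholds chosen to
#' tolerate the high variability of off-capture exome mtDNA coverage.
#'
#' @param assembled_fraction fraction of the mtDNA assembled, in `[0, 1]`.
#' @param mean_depth mean chrM coverage depth (x).
#' @param min_fraction assembly threshold (default 0.5).
#' @param min_depth depth threshold (default 5).
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed gates, among `"assembly"` and `"depth"`).
#' @export
apply_sample_qc <- function(assembled_fraction, mean_depth,
                            min_fraction = 0.5, min_depth = 5) {
  stopifnot(
    is.numeric(assembled_fraction), assembled_fraction >= 0, assembled_fraction <= 1,
    is.numeric(mean_depth), mean_depth >= 0
  )
  reasons <- character(0)
  if (assembled_fraction < min_fraction) reasons <- c(reasons, "assembly")
  if (mean_depth < min_depth) reasons <- c(reasons, "depth")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

variant_key <- function(position, ref, alt) {
  paste0("m.", position, ref, ">", alt)
}

check_variant_records <- function(variants) {
  req <- c("sample_id", "position", "ref", "alt", "heteroplasmy", "depth")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(variants)) {
    stopifnot(
      all(variants$position >= 1L & variants$position <= RCRS_LENGTH),
      all(variants$ref != variants$alt),
      all(variants$heteroplasmy >= 0 & variants$heteroplasmy <= 1),
      all(variants$depth >= 0)
    )
  }
  invisible(variants)
}

#' Assign a haplogroup from marker overlap
#'
#' A deliberately simple best-marker-fraction classifier: the sample is
#' assigned the haplogroup maximizing the fraction of its defining markers
#' present at heteroplasmy >= `min_marker_het` (markers are essentially
#' homoplasmic lineage polymorphisms; the floor keeps low-level artifacts
#' from driving the assignment). Ties break lexicographically by haplogroup
#' id. A pre-computed haplogroup, when supplied upstream, takes precedence
#' over this classifier (see [filter_cohort()]).
#'
#' @param variants data.frame of one sample's variant calls (`position`,
#'   `ref`, `alt`, `heteroplasmy`).
#' @param markers data.frame with columns `haplogroup`, `position`, `ref`,
#'   `alt` listing each haplogroup's defining variants.
#' @param min_marker_het heteroplasmy floor for a call to count as a marker
#'   match (default 0.9).
#' @return List with `haplogroup` and `match_fraction`.
#' @export
assign_haplogroup <- function(variants, markers, min_marker_het = 0.9) {
  if (nrow(markers) == 0L) stop("marker table is empty")
  hgs <- sort(unique(as.character(markers$haplogroup)))
  present <- if (nrow(variants)) {
    variant_key(
      variants$position[variants$heteroplasmy >= min_marker_het],
      variants$ref[variants$heteroplasmy >= min_marker_het],
      variants$alt[variants$heteroplasmy >= min_marker_het]
    )
  } else character(0)
  frac <- vapply(hgs, function(h) {
    mk <- markers[markers$haplogroup == h, , drop = FALSE]
    if (nrow(mk) == 0L) return(0)
    mean(variant_key(mk$position, mk$ref, mk$alt) %in% present)
  }, numeric(1))
  best <- hgs[[which.max(frac)]]  # hgs sorted, so ties pick lexicographic min
  list(haplogroup = best, match_fraction = unname(frac[[which.max(frac)]]))
}

#' Is a variant a defining marker of a haplogroup?
#'
#' @param position,ref,alt the variant key.
#' @param haplogroup haplogroup id (must exist in the marker table).
#' @param markers marker data.frame (`haplogroup`, `position`, `ref`, `alt`).
#' @return TRUE iff `(position, ref, alt)` is among the haplogroup's
#'   defining variants.
#' @export
is_haplogroup_marker <- function(position, ref, alt, haplogroup, markers) {
  if (!haplogroup %in% markers$haplogroup) {
    stop("unknown haplogroup: ", haplogroup)
  }
  mk <- markers[markers$haplogroup == haplogroup, , drop = FALSE]
  variant_key(position, ref, alt) %in% variant_key(mk$position, mk$ref, mk$alt)
}

#' Four-criterion variant prioritization
#'
#' A variant is prioritized when its heteroplasmy is at least `min_het`
#' (mandatory) AND it carries evidence of disease association by any of:
#' "confirmed" status in the MITOMAP-style annotation, presence in the
#' MitoPhen-style reference, or "reported" status with population allele
#' frequency strictly below `max_af`. Unannotated variants are treated as
#' status "absent" and not in MitoPhen. A "reported" variant with missing
#' allele frequency cannot satisfy the frequency clause.
#'
#' @param heteroplasmy variant heteroplasmy fraction in `[0, 1]`.
#' @param mitomap_status one of `"confirmed"`, `"reported"`, `"absent"`.
#' @param mitomap_af population allele frequency, or `NA`.
#' @param in_mitophen logical.
#' @param min_het heteroplasmy floor (default 0.01, inclusive).
#' @param max_af allele-frequency ceiling for "reported" variants
#'   (default 0.002, strict).
#' @return List with `pass` (logical) and `criterion` (the first satisfied
#'   disease-association clause among `"confirmed"`, `"mitophen"`,
#'   `"reported_rare"`, or `NA` when failing).
#' @export
passes_prioritization <- function(heteroplasmy, mitomap_status = "absent",
                                  mitomap_af = NA_real_, in_mitophen = FALSE,
                                  min_het = 0.01, max_af = 0.002) {
  if (is.na(mitomap_status) || !nzchar(mitomap_status)) mitomap_status <- "absent"
  stopifnot(mitomap_status %in% c("confirmed", "reported", "absent"))
  if (is.na(in_mitophen)) in_mitophen <- FALSE
  criterion <- NA_character_
  if (identical(mitomap_status, "confirmed")) {
    criterion <- "confirmed"
  } else if (isTRUE(in_mitophen)) {
    criterion <- "mitophen"
  } else if (identical(mitomap_status, "reported") &&
             !is.na(mitomap_af) && mitomap_af < max_af) {
    criterion <- "reported_rare"
  }
  pass <- heteroplasmy >= min_het && !is.na(criterion)
  list(pass = pass, criterion = if (pass) criterion else NA_character_)
}

join_annotation <- function(variants, annotation) {
  key <- variant_key(variants$position, variants$ref, variants$alt)
  akey <- variant_key(annotation$position, annotation$ref, annotation$alt)
  idx <- match(key, akey)
  out <- variants
  out$mitomap_status <- ifelse(is.na(idx), "absent", as.character(annotation$mitomap_status)[idx])
  out$mitomap_af <- ifelse(is.na(idx), NA_real_, as.numeric(annotation$mitomap_af)[idx])
  out$in_mitophen <- ifelse(is.na(idx), FALSE, as.logical(annotation$in_mitophen)[idx])
  out$gene <- ifelse(is.na(idx), NA_character_, as.character(annotation$gene)[idx])
  if ("actionable" %in% names(annotation)) {
    out$actionable <- ifelse(is.na(idx), FALSE, as.logical(annotation$actionable)[idx])
  } else {
    out$actionable <- FALSE
  }
  out
}

#' Filter a cohort's variant calls through QC, marker, and prioritization gates
#'
#' Applies, per variant-sample pair, three independent gates: (1) sample QC
#' (assembly fraction and depth), (2) exclusion of defining markers of the
#' sample's haplogroup (benign lineage polymorphisms), and (3) the
#' four-criterion prioritization of [passes_prioritization()]. Every gate
#' decision is carried as a provenance flag, so the funnel is auditable and
#' gate order does not affect the survivor set.
#'
#' @param qc data.frame with `sample_id`, `assembled_fraction`, `mean_depth`
#'   (optionally `assay`, `tissue`, and a pre-computed `haplogroup` column,
#'   which then takes precedence over marker-based assignment).
#' @param variants data.frame of calls: `sample_id`, `position`, `ref`,
#'   `alt`, `heteroplasmy`, `depth`.
#' @param annotation data.frame: `position`, `ref`, `alt`, `mitomap_status`,
#'   `mitomap_af`, `in_mitophen`, `gene` (optional logical `actionable` for
#'   LHON/SNHL-class alleles).
#' @param markers marker data.frame (`haplogroup`, `position`, `ref`, `alt`).
#' @param min_fraction,min_depth QC thresholds, see [apply_sample_qc()].
#' @param min_het,max_af prioritization thresholds, see
#'   [passes_prioritization()].
#' @param min_marker_het marker-match floor, see [assign_haplogroup()].
#' @return List with `candidates` (data.frame of surviving variant-sample
#'   pairs with annotation, criterion and provenance columns), `flags` (the
#'   full per-variant gate table) and `funnel` (named counts: input,
#'   qc_pass, marker_pass, prioritized).
#' @export
filter_cohort <- function(qc, variants, annotation, markers,
                          min_fraction = 0.5, min_depth = 5,
                          min_het = 0.01, max_af = 0.002,
                          min_marker_het = 0.9) {
  check_variant_records(variants)
  missing_samples <- setdiff(unique(variants$sample_id), qc$sample_id)
  if (length(missing_samples)) {
    stop(
      "sample(s) in variant calls absent from QC table: ",
      paste(missing_samples, collapse = ", ")
    )
  }

  qc_pass <- vapply(seq_len(nrow(qc)), function(i) {
    apply_sample_qc(
      qc$assembled_fraction[[i]], qc$mean_depth[[i]],
      min_fraction = min_fraction, min_depth = min_depth
    )$pass
  }, logical(1))
  names(qc_pass) <- qc$sample_id

  # haplogroup per sample: pre-computed column wins, else marker classifier
  sample_ids <- unique(variants$sample_id)
  hg <- stats::setNames(character(length(sample_ids)), sample_ids)
  for (sid in sample_ids) {
    pre <- if ("haplogroup" %in% names(qc)) qc$haplogroup[[match(sid, qc$sample_id)]] else NA
    if (!is.null(pre) && !is.na(pre) && nzchar(pre)) {
      hg[[sid]] <- as.character(pre)
    } else {
      hg[[sid]] <- assign_haplogroup(
        variants[variants$sample_id == sid, , drop = FALSE],
        markers, min_marker_het = min_marker_het
      )$haplogroup
    }
  }

  ann <- join_annotation(variants, annotation)
  n <- nrow(ann)
  flag_qc <- qc_pass[ann$sample_id]
  flag_marker <- logical(n)
  flag_prio <- logical(n)
  criterion <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    flag_marker[[i]] <- !is_haplogroup_marker(
      ann$position[[i]], ann$ref[[i]], ann$alt[[i]], hg[[ann$sample_id[[i]]]], markers
    )
    pr <- passes_prioritization(
      ann$heteroplasmy[[i]], ann$mitomap_status[[i]], ann$mitomap_af[[i]],
      ann$in_mitophen[[i]], min_het = min_het, max_af = max_af
    )
    flag_prio[[i]] <- pr$pass
    criterion[[i]] <- pr$criterion
  }

  flags <- ann
  flags$variant <- variant_key(ann$position, ann$ref, ann$alt)
  flags$haplogroup <- unname(hg[ann$sample_id])
  flags$qc_pass <- unname(flag_qc)
  flags$not_marker <- flag_marker
  flags$prioritized <- flag_prio
  flags$criterion <- criterion

  keep <- flags$qc_pass & flags$not_marker & flags$prioritized
  candidates <- flags[keep, , drop = FALSE]
  rownames(candidates) <- NULL

  funnel <- c(
    input = n,
    qc_pass = sum(flags$qc_pass),
    marker_pass = sum(flags$qc_pass & flags$not_marker),
    prioritized = sum(keep)
  )
  list(candidates = candidates, flags = flags, funnel = funnel)
}

#' Read mtDNA variant calls
#'
#' TSV columns: `sample_id`, `position`, `ref`, `alt`, `heteroplasmy`,
#' `depth`.
#'
#' @param path TSV path.
#' @return Validated data.frame of variant records.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  df$heteroplasmy <- as.numeric(df$heteroplasmy)
  df$depth <- as.numeric(df$depth)
  check_variant_records(df)
  df
}

#' Read single-sample chrM variant calls from a minimal VCF
#'
#' Accepts an uncompressed single-sample VCF restricted to contig
#' `chrM`/`MT`/`chrMT`. Heteroplasmy is taken from the `AF` INFO or FORMAT
#' field when present, else computed as `AD[alt] / sum(AD)`; depth from
#' `DP`. Multiallelic rows are split into biallelic records sharing the
#' site's depth.
#'
#' @param path VCF path.
#' @param sample_id sample id to stamp on the records; defaults to the VCF
#'   sample column name.
#' @return Validated data.frame of variant records.
#' @export
read_variants_vcf <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "##")]
  hdr_i <- which(startsWith(body, "#CHROM"))
  if (length(hdr_i) != 1L) stop("missing #CHROM header line in ", path)
  hdr <- strsplit(sub("^#", "", body[[hdr_i]]), "\t", fixed = TRUE)[[1L]]
  rows <- body[-seq_len(hdr_i)]
  rows <- rows[nzchar(rows)]
  if (is.null(sample_id)) {
    sample_id <- if (length(hdr) >= 10L) hdr[[10L]] else basename(path)
  }
  out <- list()
  for (ln in rows) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    chrom <- f[[1L]]
    if (!chrom %in% c("chrM", "MT", "chrMT")) next
    pos <- as.integer(f[[2L]])
    ref <- f[[4L]]
    alts <- strsplit(f[[5L]], ",", fixed = TRUE)[[1L]]
    info <- strsplit(f[[8L]], ";", fixed = TRUE)[[1L]]
    info_kv <- strsplit(info, "=", fixed = TRUE)
    info_map <- stats::setNames(
      vapply(info_kv, function(x) if (length(x) > 1L) x[[2L]] else "", character(1)),
      vapply(info_kv, `[[`, character(1), 1L)
    )
    fmt <- if (length(f) >= 10L) strsplit(f[[9L]], ":", fixed = TRUE)[[1L]] else character(0)
    smp <- if (length(f) >= 10L) strsplit(f[[10L]], ":", fixed = TRUE)[[1L]] else character(0)
    get_fmt <- function(tag) {
      i <- match(tag, fmt)
      if (is.na(i) || i > length(smp)) NA_character_ else smp[[i]]
    }
    dp <- suppressWarnings(as.numeric(if (!is.na(get_fmt("DP"))) get_fmt("DP") else info_map[["DP"]]))
    if (length(dp) == 0L || is.na(dp)) dp <- 0
    af_str <- if (!is.na(get_fmt("AF"))) get_fmt("AF") else
      if ("AF" %in% names(info_map)) info_map[["AF"]] else NA_character_
    afs <- if (!is.na(af_str)) suppressWarnings(as.numeric(strsplit(af_str, ",", fixed = TRUE)[[1L]])) else NULL
    ad_str <- get_fmt("AD")
    ads <- if (!is.na(ad_str)) suppressWarnings(as.numeric(strsplit(ad_str, ",", fixed = TRUE)[[1L]])) else NULL
    for (k in seq_along(alts)) {
      alt <- alts[[k]]
      het <- if (!is.null(afs) && length(afs) >= k) {
        afs[[k]]
      } else if (!is.null(ads) && length(ads) >= k + 1L && sum(ads) > 0) {
        ads[[k + 1L]] / sum(ads)
      } else {
        NA_real_
      }
      if (is.na(het)) stop("cannot determine heteroplasmy at ", chrom, ":", pos, " in ", path)
      nv <- normalize_allele(pos, ref, alt)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, position = nv$position, ref = nv$ref,
        alt = nv$alt, heteroplasmy = het, depth = dp,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(out)) do.call(rbind, out) else data.frame(
    sample_id = character(0), position = integer(0), ref = character(0),
    alt = character(0), heteroplasmy = numeric(0), depth = numeric(0)
  )
  check_variant_records(df)
  df
}

# Trim shared suffix then shared prefix so indels are left-aligned and SNVs
# reduce to single-base ref/alt; no circular-genome wraparound handling.
normalize_allele <- function(position, ref, alt) {
  r <- strsplit(ref, "")[[1L]]
  a <- strsplit(alt, "")[[1L]]
  while (length(r) > 1L && length(a) > 1L && r[[length(r)]] == a[[length(a)]]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[[1L]] == a[[1L]]) {
    r <- r[-1L]
    a <- a[-1L]
    position <- position + 1L
  }
  list(position = as.integer(position), ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}
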