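test_that("sample QC gates are inclusive at both thresholds", {
  expect_false(apply_sample_qc(0.49, 10)$pass)
  expect_equal(apply_sample_qc(0.49, 10)$reasons, "assembly")
  expect_true(apply_sample_qc(0.50, 5.0)$pass)
  expect_false(apply_sample_qc(1.00, 4.9)$pass)
  expect_equal(apply_sample_qc(1.00, 4.9)$reasons, "depth")
  expect_setequal(apply_sample_qc(0.1, 1)$reasons, c("assembly", "depth"))
})

test_that("haplogroup assignment maximizes marker fraction with lexicographic ties", {
  markers <- data.frame(
    haplogroup = c("H", "H", "H", "J", "J", "J", "J"),
    position = c(7028L, 2706L, 1438L, 295L, 489L, 10398L, 12612L),
    ref = c("C", "A", "A", "C", "T", "A", "G"),
    alt = c("T", "G", "G", "T", "C", "G", "A"),
    stringsAsFactors = FALSE
  )
  mkvar <- function(pos, ref, alt, het) {
    data.frame(
      sample_id = "S", position = pos, ref = ref, alt = alt,
      heteroplasmy = het, depth = 50, stringsAsFactors = FALSE
    )
  }
  # all three H markers present
  v <- rbind(mkvar(7028L, "C", "T", 0.99), mkvar(2706L, "A", "G", 0.99),
             mkvar(1438L, "A", "G", 0.98))
  got <- assign_haplogroup(v, markers)
  expect_equal(got$haplogroup, "H")
  expect_equal(got$match_fraction, 1.0)

  # 1/3 of H beats 1/4 of J... use 2/3 H vs 1/4 J to force the comparison
  v2 <- rbind(mkvar(7028L, "C", "T", 0.95), mkvar(2706L, "A", "G", 0.95),
              mkvar(295L, "C", "T", 0.95))
  got2 <- assign_haplogroup(v2, markers)
  expect_equal(got2$haplogroup, "H")
  expect_equal(got2$match_fraction, 2 / 3, tolerance = 1e-12)

  # below the homoplasmy floor markers do not count
  v3 <- mkvar(7028L, "C", "T", 0.5)
  got3 <- assign_haplogroup(v3, markers)
  expect_equal(got3$match_fraction, 0)
  expect_equal(got3$haplogroup, "H")  # lexicographically first on ties

  # no variants at all
  got4 <- assign_haplogroup(v3[0, ], markers)
  expect_equal(got4$haplogroup, "H")
  expect_equal(got4$match_fraction, 0)

  expect_true(is_haplogroup_marker(7028L, "C", "T", "H", markers))
  expect_false(is_haplogroup_marker(7028L, "C", "T", "J", markers))
  expect_false(is_haplogroup_marker(3243L, "A", "G", "H", markers))
  expect_error(is_haplogroup_marker(7028L, "C", "T", "Z", markers), "unknown haplogroup")
})

test_that("prioritization needs the heteroplasmy floor plus one disease clause", {
  # confirmed association at reportable heteroplasmy
  got <- passes_prioritization(0.33, "confirmed")
  expect_true(got$pass)
  expect_equal(got$criterion, "confirmed")

  # the 1% heteroplasmy floor is mandatory, not an alternative
  expect_false(passes_prioritization(0.005, "confirmed")$pass)
  expect_true(passes_prioritization(0.01, "confirmed")$pass)  # inclusive

  # reported needs AF strictly under the ceiling
  expect_false(passes_prioritization(0.50, "reported", 0.003)$pass)
  expect_false(passes_prioritization(0.50, "reported", 0.002)$pass)  # strict
  got2 <- passes_prioritization(0.50, "reported", 0.0005)
  expect_true(got2$pass)
  expect_equal(got2$criterion, "reported_rare")

  # clause order: confirmed, then MitoPhen, then reported-rare
  expect_equal(passes_prioritization(0.5, "confirmed", 1e-4, TRUE)$criterion, "confirmed")
  expect_equal(passes_prioritization(0.5, "reported", 1e-4, TRUE)$criterion, "mitophen")

  # MitoPhen membership alone suffices
  expect_true(passes_prioritization(0.5, "absent", NA, TRUE)$pass)

  # reported with missing AF cannot satisfy the frequency clause
  expect_false(passes_prioritization(0.5, "reported", NA, FALSE)$pass)

  # unannotated variants never pass
  expect_false(passes_prioritization(0.99)$pass)
})

test_that("the packaged 20-row cascade yields exactly the four known survivors", {
  d <- read_demo_tables()
  got <- filter_cohort(d$qc, d$variants, d$annotation, d$markers)
  expect_equal(
    got$funnel,
    c(input = 20L, qc_pass = 18L, marker_pass = 10L, prioritized = 4L)
  )
  survivors <- got$candidates[order(got$candidates$sample_id), ]
  expect_equal(survivors$sample_id, c("S01", "S03", "S04", "S08"))
  expect_equal(
    survivors$variant,
    c("m.3243A>G", "m.9176T>C", "m.5698G>A", "m.1555A>G")
  )
  expect_equal(
    survivors$criterion,
    c("confirmed", "mitophen", "reported_rare", "confirmed")
  )
  # every emitted candidate satisfies all three gates post hoc
  expect_true(all(survivors$qc_pass & survivors$not_marker & survivors$prioritized))
})

test_that("filter_cohort hard-errors on samples missing from the QC table", {
  d <- read_demo_tables()
  d$variants$sample_id[d$variants$sample_id == "S01"] <- "S99"
  expect_error(
    filter_cohort(d$qc, d$variants, d$annotation, d$markers),
    "S99"
  )
})

test_that("all samples failing QC leaves nothing", {
  d <- read_demo_tables()
  d$qc$assembled_fraction <- 0.1
  got <- filter_cohort(d$qc, d$variants, d$annotation, d$markers)
  expect_equal(nrow(got$candidates), 0L)
  expect_equal(unname(got$funnel[["qc_pass"]]), 0L)
})

test_that("gate order does not change the survivor set", {
  d <- read_demo_tables()
  got <- filter_cohort(d$qc, d$variants, d$annotation, d$markers)
  fl <- got$flags
  # the three gates are independent predicates; intersect them in any order
  orders <- list(
    fl$qc_pass & fl$not_marker & fl$prioritized,
    fl$prioritized & fl$qc_pass & fl$not_marker,
    fl$not_marker & fl$prioritized & fl$qc_pass
  )
  key <- paste(fl$sample_id, fl$variant)
  expected <- sort(paste(got$candidates$sample_id, got$candidates$variant))
  for (keep in orders) {
    expect_equal(sort(key[keep]), expected)
  }
})

test_that("a pre-computed haplogroup column overrides marker assignment", {
  d <- read_demo_tables()
  # S08 carries one J marker; forcing haplogroup H keeps m.295C>T as a non-marker,
  # but it is unannotated so the survivor set is unchanged
  d$qc$haplogroup <- NA_character_
  d$qc$haplogroup[d$qc$sample_id == "S08"] <- "H"
  got <- filter_cohort(d$qc, d$variants, d$annotation, d$markers)
  fl <- got$flags
  expect_true(fl$not_marker[fl$sample_id == "S08" & fl$position == 295])
  expect_equal(unname(got$funnel[["prioritized"]]), 4L)
})

test_that("variant readers validate records and parse minimal VCFs", {
  d <- read_demo_tables()
  expect_equal(nrow(d$variants), 20L)
  bad <- d$variants
  bad$position[1] <- 20000L
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variants_tsv(f))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMP1",
    "chrM\t3243\t.\tA\tG\t.\tPASS\t.\tGT:DP:AF\t0/1:80:0.33",
    "chrM\t15990\t.\tC\tT,A\t.\tPASS\t.\tGT:DP:AD\t0/1:60:30,24,6",
    "chrM\t955\t.\tAC\tA\t.\tPASS\t.\tGT:DP:AF\t0/1:50:0.9",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP:AF\t0/1:10:0.5"
  ), vcf)
  v <- read_variants_vcf(vcf)
  expect_equal(nrow(v), 4L)  # chr1 dropped, multiallelic split
  expect_equal(v$sample_id[[1L]], "SAMP1")
  expect_equal(v$heteroplasmy[v$position == 3243], 0.33)
  # AD fallback: alt counts over total
  expect_equal(sort(v$heteroplasmy[v$position == 15990]), c(0.1, 0.4))
  # deletion left-aligned by suffix/prefix trimming
  expect_true(any(v$position == 955 & v$ref == "AC" & v$alt == "A"))
})
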