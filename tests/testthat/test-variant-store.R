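test_that("variant normalization trims to the parsimonious representation", {
  # already minimal: unchanged
  expect_equal(normalize_variant("chr1", 100, "C", "T"),
               data.frame(contig = "chr1", pos1 = 100L, ref = "C", alt = "T"))
  # right-then-left trim, hand-derived and cross-checked against
  # `bcftools norm`: CTT>CT drops the shared trailing T, leaving CT>C;
  # the leading C is not trimmed because the alt is already one base
  expect_equal(normalize_variant("chr1", 100, "CTT", "CT"),
               data.frame(contig = "chr1", pos1 = 100L, ref = "CT", alt = "C"))
  # a representation with shared leading context does advance the position
  expect_equal(normalize_variant("chr1", 100, "ACT", "AGT"),
               data.frame(contig = "chr1", pos1 = 101L, ref = "C", alt = "G"))
  expect_error(normalize_variant("chr1", 100, "C", "C"), "degenerate")
  expect_error(normalize_variant("chr1", 100, "", "T"), "non-empty")
})

test_that("normalization is idempotent on random indel representations", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    core_r <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
    core_a <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
    if (core_r == core_a) next
    pad_l <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    pad_r <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    v1 <- normalize_variant("chr2", 500, paste0(pad_l, core_r, pad_r),
                            paste0(pad_l, core_a, pad_r))
    v2 <- normalize_variant(v1$contig, v1$pos1, v1$ref, v1$alt)
    expect_identical(v1, v2)
  }
})

test_that("read_cohort derives carrier indicators from GT, splitting multi-allelics", {
  samples <- c("S1", "S2", "S3")
  sheet <- make_sheet(samples, c("BD_CANCER", "BD_ONLY", "CONTROL"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, samples, list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "T",
         gts = c("0/1", "0|0", "./.")),
    list(chrom = "chr1", pos = 200, ref = "A", alt = "T,G",
         gts = c("1/2", "0/0", "2/2"))))
  write_test_sheet(tsv, sheet)
  co <- read_cohort(vcf, tsv)
  m <- co$matrix$carrier
  expect_equal(unname(m[, "chr1:100:A:T"]), c(1L, 0L, 0L))  # het 1, missing 0
  # 1/2 carries both split keys; 2/2 carries only the G key
  expect_equal(unname(m[, "chr1:200:A:T"]), c(1L, 0L, 0L))
  expect_equal(unname(m[, "chr1:200:A:G"]), c(1L, 0L, 1L))
  expect_true(all(m %in% c(0L, 1L)))
})

test_that("duplicated keys are merged by logical OR with a warning", {
  samples <- c("S1", "S2")
  sheet <- make_sheet(samples, c("BD_CANCER", "BD_ONLY"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  # two records normalizing to the same key chr1:100:A:T
  write_test_vcf(vcf, samples, list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "T", gts = c("0/1", "0/0")),
    list(chrom = "chr1", pos = 100, ref = "AC", alt = "TC", gts = c("0/0", "1/1"))))
  write_test_sheet(tsv, sheet)
  expect_warning(co <- read_cohort(vcf, tsv), "logical OR")
  expect_equal(nrow(co$matrix$variants), 1L)
  expect_equal(unname(co$matrix$carrier[, "chr1:100:A:T"]), c(1L, 1L))
})

test_that("sample mismatches and malformed sheets are configuration errors", {
  samples <- c("S1", "S2")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf, samples, list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "T", gts = c("0/1", "0/0"))))
  write_test_sheet(tsv, make_sheet(c("S1", "S3"), c("BD_CANCER", "BD_ONLY")))
  expect_error(read_cohort(vcf, tsv), "sample mismatch.*S2.*S3")
  expect_error(make_sheet(c("S1", "S1"), c("BD_CANCER", "BD_ONLY")), "duplicate")
  expect_error(make_sheet("S1", "CONTROL", role = "proband"),
               "parents or siblings")
  expect_error(make_sheet("S1", "HEALTHY"), "group must be")
})

test_that("a VCF without GT is rejected", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chr1\t100\t.\tA\tT\t.\tPASS\t.\tDP\t12"), vcf)
  write_test_sheet(tsv, make_sheet("S1", "BD_CANCER"))
  expect_error(read_cohort(vcf, tsv), "GT")
})

test_that("carrier matrices round-trip through VCF exactly", {
  set.seed(3)
  for (i in 1:5) {
    rc <- random_cohort(100 + i)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    vcf <- withr::local_tempfile(fileext = ".vcf")
    write_test_sheet(tsv, rc$sheet)
    write_carrier_vcf(rc$cm, vcf)
    back <- read_cohort(vcf, tsv)
    expect_identical(back$matrix$carrier, rc$cm$carrier)
    expect_equal(back$matrix$variants, rc$cm$variants)
  }
})
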