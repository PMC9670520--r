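#' Normalize a variant to its minimal (parsimonious) representation
#'
#' Two calls describe the "same" variant when, after trimming shared
#' trailing and then shared leading bases, they land on the same
#' (contig, position, ref, alt). This is the identity rule the
#' case-exclusive recurrence filter operates on: same genomic locus,
#' same alternative allele.
#'
#' @param contig Contig name (e.g. `"chr1"`).
#' @param pos1 1-based position of the first ref base.
#' @param ref,alt Allele strings over `A/C/G/T` (length >= 1).
#' @return A one-row data.frame with columns `contig`, `pos1`, `ref`, `alt`.
#' @examples
#' normalize_variant("chr1", 100, "CTT", "CT")  # -> chr1:101 TT>T
#' @export
normalize_variant <- function(contig, pos1, ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) {
    stop("ref and alt must be non-empty allele strings")
  }
  if (ref == alt) {
    stop("degenerate variant: ref equals alt (", contig, ":", pos1, " ", ref, ")")
  }
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # trim shared trailing bases, keeping at least one base in each allele
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim shared leading bases, advancing pos1
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos1 <- pos1 + 1L
  }
  ref <- paste(r, collapse = "")
  alt <- paste(a, collapse = "")
  if (ref == alt) {
    stop("degenerate variant: ref equals alt after trimming (", contig, ":", pos1, ")")
  }
  data.frame(contig = contig, pos1 = as.integer(pos1), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# fixed VCF columns as a data.frame; tolerates vcfR dropping the matrix
# dimensions for single-record files
vcf_fix_df <- function(vcf) {
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  as.data.frame(fix, stringsAsFactors = FALSE)
}

#' Canonical string form of a variant key
#' @param keys data.frame with contig/pos1/ref/alt columns.
#' @return character vector `contig:pos1:ref:alt`.
#' @export
variant_key_id <- function(keys) {
  paste(keys$contig, keys$pos1, keys$ref, keys$alt, sep = ":")
}

#' Read a sample sheet
#'
#' The sheet is a TSV with header `sample_id family_id group role`.
#' `group` is one of `BD_CANCER` (BD proband with a malignant tumor),
#' `BD_ONLY` (BD proband without cancer) or `CONTROL` (healthy
#' parent/sibling of a proband); `role` is `proband`, `parent` or
#' `sibling`.
#'
#' @param path Path to the TSV file.
#' @return A validated `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_sample_sheet(df)
}

#' Validate (and class) a sample-sheet data.frame
#' @param df data.frame with columns sample_id, family_id, group, role.
#' @return the data.frame with class `sample_sheet` prepended.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "family_id", "group", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$group %in% c("BD_CANCER", "BD_ONLY", "CONTROL"))) {
    stop("group must be one of BD_CANCER, BD_ONLY, CONTROL")
  }
  if (!all(df$role %in% c("proband", "parent", "sibling"))) {
    stop("role must be one of proband, parent, sibling")
  }
  bad <- df$group == "CONTROL" & df$role == "proband"
  if (any(bad)) {
    stop("CONTROL samples must be parents or siblings: ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  if (any(!nzchar(df$family_id))) stop("every sample needs a non-empty family_id")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a multi-sample VCF and sample sheet into a carrier matrix
#'
#' Multi-allelic records are split into one normalized key per
#' alternative allele. A sample is a carrier of a key when its GT
#' contains at least one copy of that allele (dominance coding; zygosity
#' is not retained). Missing genotypes (`./.`) count as non-carrier.
#' Identical keys arising from different records are merged by logical
#' OR with a warning.
#'
#' @param vcf_path Path to a VCF (v4.2) with GT genotypes.
#' @param sheet_path Path to the sample-sheet TSV (see [read_sample_sheet()]).
#' @param pass_only If `TRUE`, keep only records with FILTER `PASS` or `.`.
#' @return list with elements `matrix` (a `carrier_matrix`) and `sheet`.
#' @export
read_cohort <- function(vcf_path, sheet_path, pass_only = FALSE) {
  sheet <- read_sample_sheet(sheet_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf_fix_df(vcf)
  fmt <- vcf@gt[, "FORMAT", drop = TRUE]
  if (nrow(fix) > 0 && !all(vapply(strsplit(fmt, ":", fixed = TRUE),
                                   function(f) "GT" %in% f, logical(1)))) {
    stop("VCF format error: GT field missing from FORMAT")
  }
  vcf_samples <- colnames(vcf@gt)[-1L]
  only_vcf <- setdiff(vcf_samples, sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, vcf_samples)
  if (length(only_vcf) || length(only_sheet)) {
    stop("sample mismatch between VCF and sheet;",
         if (length(only_vcf)) paste0(" VCF-only: ", paste(only_vcf, collapse = ", ")),
         if (length(only_sheet)) paste0(" sheet-only: ", paste(only_sheet, collapse = ", ")))
  }
  if (pass_only && nrow(fix) > 0) {
    keep <- fix$FILTER %in% c("PASS", ".") | is.na(fix$FILTER)
    fix <- fix[keep, , drop = FALSE]
    vcf@gt <- vcf@gt[keep, , drop = FALSE]
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, vcf_samples))
  }
  n_rec <- nrow(fix)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keys <- vector("list", n_rec)
  carrier_rows <- vector("list", n_rec)
  # biallelic records (the bulk): vectorized allele-token match
  if (any(!multi)) {
    bi <- which(!multi)
    carr_bi <- grepl("(^|[/|])1([/|]|$)", gt[bi, , drop = FALSE]) * 1L
    carr_bi <- matrix(carr_bi, nrow = length(bi))
    for (k in seq_along(bi)) {
      i <- bi[k]
      keys[[i]] <- normalize_variant(fix$CHROM[i], as.integer(fix$POS[i]),
                                     fix$REF[i], fix$ALT[i])
      carrier_rows[[i]] <- carr_bi[k, , drop = FALSE]
    }
  }
  for (i in which(multi)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt[i, vcf_samples]
    alleles <- strsplit(ifelse(is.na(gts), ".", gts), "[/|]")
    reci <- lapply(seq_along(alts), function(j) {
      key <- normalize_variant(fix$CHROM[i], as.integer(fix$POS[i]), fix$REF[i], alts[j])
      carr <- vapply(alleles, function(a) any(a == as.character(j)), logical(1))
      list(key = key, carr = as.integer(carr))
    })
    keys[[i]] <- do.call(rbind, lapply(reci, `[[`, "key"))
    carrier_rows[[i]] <- do.call(rbind, lapply(reci, `[[`, "carr"))
  }
  keys <- do.call(rbind, keys)
  carr <- do.call(rbind, carrier_rows)  # variants x samples
  if (is.null(keys)) {
    keys <- data.frame(contig = character(), pos1 = integer(),
                       ref = character(), alt = character())
    carr <- matrix(0L, 0L, length(vcf_samples))
  }
  ids <- variant_key_id(keys)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("merging duplicated variant key(s) by logical OR: ",
            paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) " ...")
    first <- !duplicated(ids)
    merged <- rowsum(carr, ids)[unique(ids), , drop = FALSE]
    carr <- (merged > 0L) * 1L
    keys <- keys[first, , drop = FALSE]
    # rowsum sorts by group name; restore first-seen order
    carr <- carr[variant_key_id(keys), , drop = FALSE]
  }
  ord <- order(keys$contig, keys$pos1, keys$ref, keys$alt, method = "radix")
  keys <- keys[ord, , drop = FALSE]
  carr <- carr[ord, , drop = FALSE]
  rownames(keys) <- NULL
  # carrier matrix stored samples x variants, in sheet order
  m <- t(carr)
  storage.mode(m) <- "integer"
  rownames(m) <- vcf_samples
  m <- m[sheet$sample_id, , drop = FALSE]
  colnames(m) <- variant_key_id(keys)
  cm <- structure(list(variants = keys, samples = sheet$sample_id, carrier = m),
                  class = "carrier_matrix")
  list(matrix = cm, sheet = sheet)
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat("carrier_matrix:", length(x$samples), "samples x", nrow(x$variants),
      "variants;", sum(x$carrier), "carrier calls\n")
  invisible(x)
}

#' Write a carrier matrix back to a (biallelic, plain-text) VCF
#'
#' Genotypes are emitted as `0/1` for carriers and `0/0` otherwise, so a
#' round trip through [read_cohort()] reproduces the matrix exactly.
#'
#' @param cm A `carrier_matrix`.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_carrier_vcf <- function(cm, path) {
  write_vcf_rows(path, cm$variants, cm$samples,
                 gt_rows = t(ifelse(cm$carrier == 1L, "0/1", "0/0")))
}

# shared plain-text VCF writer: keys (variants df), samples, and a
# variants x samples character matrix of GT strings
write_vcf_rows <- function(path, keys, samples, gt_rows) {
  con <- file(path, open = "wb")  # binary: byte-identical output across platforms
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  writeLines(hdr, con, sep = "\n")
  if (nrow(keys)) {
    body <- paste(keys$contig, keys$pos1, ".", keys$ref, keys$alt, ".", "PASS", ".",
                  "GT", sep = "\t")
    gts <- apply(gt_rows, 1L, paste, collapse = "\t")
    writeLines(paste(body, gts, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}
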