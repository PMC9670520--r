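#' Select case-exclusive recurrent variants of interest
#'
#' The selection rule is set-theoretic: a variant is a "variant of
#' interest" when it is carried by at least `min_cases` BD+cancer
#' probands — counted at most once per family when
#' `require_unrelated = TRUE` — and by zero BD-only probands and zero
#' healthy family controls. Only probands are eligible as cases;
#' relatives can never contribute to the case count.
#'
#' @param cm A `carrier_matrix` from [read_cohort()].
#' @param sheet A `sample_sheet` covering the same samples.
#' @param min_cases Minimum number of (unrelated) case carriers; default 3.
#' @param require_unrelated Count case carriers at most once per
#'   `family_id` (default `TRUE`, the stricter reading of recurrence in
#'   unrelated patients).
#' @return A `selection` data.frame with columns `contig`, `pos1`,
#'   `ref`, `alt`, `case_carriers`, sorted genomically.
#' @export
select_variants <- function(cm, sheet, min_cases = 3L, require_unrelated = TRUE) {
  stopifnot(min_cases >= 1L)
  if (!all(cm$samples %in% sheet$sample_id)) {
    stop("carrier matrix contains samples absent from the sheet")
  }
  sheet <- sheet[match(cm$samples, sheet$sample_id), , drop = FALSE]
  is_case <- sheet$group == "BD_CANCER" & sheet$role == "proband"
  if (!any(is_case)) stop("cohort has no BD_CANCER probands; filter undefined")
  is_excl <- sheet$group %in% c("BD_ONLY", "CONTROL")
  carr <- cm$carrier
  if (require_unrelated) {
    fam <- rowsum(carr[is_case, , drop = FALSE], sheet$family_id[is_case]) > 0L
    case_count <- colSums(fam)
  } else {
    case_count <- colSums(carr[is_case, , drop = FALSE])
  }
  excl_count <- colSums(carr[is_excl, , drop = FALSE])
  keep <- case_count >= min_cases & excl_count == 0L
  out <- cm$variants[keep, , drop = FALSE]
  out$case_carriers <- as.integer(case_count[keep])
  ord <- order(out$contig, out$pos1, out$ref, out$alt, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_cases") <- as.integer(min_cases)
  attr(out, "require_unrelated") <- require_unrelated
  class(out) <- c("selection", "data.frame")
  out
}

#' Annotate a selection with region classes and mapped genes
#'
#' Adds the region class, stratum and mapped gene(s) for every selected
#' variant; the three strata (coding / noncoding / intergenic) form a
#' disjoint cover of the selection.
#'
#' @param sel A `selection` from [select_variants()].
#' @param model A `gene_model`.
#' @return The selection with `region_class`, `stratum`, `gene_ids`
#'   (comma-joined) and a `genes` list column added.
#' @export
annotate_selection <- function(sel, model) {
  if (!nrow(sel)) {
    sel$region_class <- character(0)
    sel$stratum <- character(0)
    sel$genes <- list()
    sel$gene_ids <- character(0)
    return(sel)
  }
  ann <- classify_positions(model, sel$contig, sel$pos1)
  sel$region_class <- ann$region_class
  sel$stratum <- ann$stratum
  sel$genes <- ann$genes
  sel$gene_ids <- vapply(ann$genes, paste, character(1), collapse = ",")
  sel
}

#' Write an annotated selection as TSV
#' @param sel annotated `selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  df <- data.frame(contig = sel$contig, pos = sel$pos1, ref = sel$ref, alt = sel$alt,
                   case_carriers = sel$case_carriers,
                   region_class = sel$region_class, stratum = sel$stratum,
                   gene_ids = sel$gene_ids, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
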