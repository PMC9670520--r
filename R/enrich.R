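#' Build a gene-set collection against a universe
#'
#' Set members outside the universe are dropped with a warning; set
#' names must be unique.
#'
#' @param sets Named list of character vectors of gene ids (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of gene ids (typically every gene
#'   in the gene model).
#' @return A `gene_set_collection` list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  universe <- unique(universe)
  clipped <- lapply(sets, function(s) intersect(unique(s), universe))
  n_drop <- sum(lengths(sets) - lengths(lapply(sets, unique))) +
    sum(lengths(lapply(sets, unique)) - lengths(clipped))
  if (any(lengths(lapply(sets, unique)) > lengths(clipped))) {
    warning("dropped gene-set members outside the universe")
  }
  structure(list(sets = clipped, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#' @param path Path to a GMT file (set name, description, members per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

# one-sided (upper-tail) hypergeometric p for an overlap of k between a
# query of size n and a set of size K in a universe of size N
hyper_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each set, tests over-representation of the query genes with a
#' one-sided hypergeometric (equivalently, one-sided Fisher) test, then
#' adjusts across all sets by Benjamini-Hochberg. Query genes outside
#' the universe are dropped with a warning.
#'
#' @param query Character vector of gene ids (e.g. genes retained by
#'   the feature reduction).
#' @param coll A [gene_set_collection()].
#' @return data.frame with one row per set — `set_name`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `fdr` — sorted by p.
#' @export
hypergeom_enrich <- function(query, coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  query <- unique(query)
  outside <- setdiff(query, coll$universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the universe")
    query <- intersect(query, coll$universe)
  }
  if (!length(query)) stop("query is empty (after intersecting with the universe)")
  if (!length(coll$sets)) stop("gene-set collection is empty")
  N <- length(coll$universe)
  n <- length(query)
  rows <- lapply(names(coll$sets), function(nm) {
    members <- coll$sets[[nm]]
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = hyper_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact-key overlap against a somatic-variant catalogue
#'
#' Intersects the selection with a catalogue of variant keys using the
#' same identity rule as the recurrence filter (same locus, same
#' alternative allele, after normalization). Unnormalized catalogue
#' records are normalized on the fly with a message.
#'
#' @param sel A `selection`.
#' @param catalogue data.frame with `contig`, `pos1`, `ref`, `alt`
#'   columns (see [read_catalogue()]).
#' @return list with `overlap` (data.frame of shared keys) and `n_overlap`.
#' @export
catalogue_overlap <- function(sel, catalogue) {
  need <- c("contig", "pos1", "ref", "alt")
  stopifnot(all(need %in% names(catalogue)))
  norm <- do.call(rbind, lapply(seq_len(nrow(catalogue)), function(i) {
    normalize_variant(catalogue$contig[i], catalogue$pos1[i],
                      catalogue$ref[i], catalogue$alt[i])
  }))
  if (is.null(norm)) norm <- catalogue[0, need]
  changed <- !is.null(norm) && nrow(norm) &&
    !identical(variant_key_id(norm), variant_key_id(catalogue[, need]))
  if (changed) message("catalogue records normalized on the fly")
  sel_ids <- variant_key_id(sel)
  cat_ids <- unique(variant_key_id(norm))
  hit <- sel_ids %in% cat_ids
  list(overlap = sel[hit, c("contig", "pos1", "ref", "alt"), drop = FALSE],
       n_overlap = sum(hit))
}

#' Read a variant catalogue from VCF or a 4-column TSV
#'
#' @param path Path to a VCF (CHROM/POS/REF/ALT are used; multi-allelic
#'   records are split) or a TSV with header `contig pos ref alt`.
#' @return data.frame with `contig`, `pos1`, `ref`, `alt`.
#' @export
read_catalogue <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf_fix_df(vcf)
    rows <- lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      data.frame(contig = fix$CHROM[i], pos1 = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    names(df)[names(df) == "pos"] <- "pos1"
    df <- df[, c("contig", "pos1", "ref", "alt")]
    df$pos1 <- as.integer(df$pos1)
    df
  }
}
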