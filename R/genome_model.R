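#' Load a simplified gene model from GFF3
#'
#' Accepts a GFF3 subset with `gene`, `exon`, `CDS`, `five_prime_UTR`
#' and `three_prime_UTR` features, each carrying a `gene_id` attribute
#' (genes also carry `biotype`, defaulting to `protein_coding`).
#' Coordinates are converted to 0-based half-open internally; all
#' external formats stay 1-based inclusive.
#'
#' @param path Path to the GFF3 file.
#' @return A `gene_model` object: `genes` (one row per gene, sorted by
#'   contig, start, gene_id) and `parts` (exon/cds/utr intervals).
#' @export
load_gene_model <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    stop("malformed GFF3 line ", body[which(nf != 9L)[1L]], " in ", path,
         ": expected 9 tab-separated fields, found ", nf[which(nf != 9L)[1L]])
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  if (is.null(gr$gene_id)) stop("GFF3 features must carry a gene_id attribute")
  df <- data.frame(
    contig = as.character(gr$seqnames),
    start = gr$start - 1L,  # 0-based half-open
    end = gr$end,
    strand = as.character(gr$strand),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    stringsAsFactors = FALSE
  )
  df$biotype <- if (is.null(gr$biotype)) NA_character_ else as.character(gr$biotype)
  genes <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("gene model contains no gene features")
  genes$biotype[is.na(genes$biotype)] <- "protein_coding"
  if (!all(genes$biotype %in% c("protein_coding", "ncRNA"))) {
    stop("gene biotype must be protein_coding or ncRNA")
  }
  parts <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
              drop = FALSE]
  parts$type <- c(exon = "exon", CDS = "cds", five_prime_UTR = "utr",
                  three_prime_UTR = "utr")[parts$type]
  orphan <- setdiff(parts$gene_id, genes$gene_id)
  if (length(orphan)) stop("feature(s) reference unknown gene_id: ",
                           paste(orphan, collapse = ", "))
  # model-consistency checks per gene
  for (g in genes$gene_id) {
    p <- parts[parts$gene_id == g, , drop = FALSE]
    gene <- genes[genes$gene_id == g, ]
    if (any(p$contig != gene$contig)) stop("gene ", g, ": features on multiple contigs")
    ex <- p[p$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("gene ", g, ": overlapping exons")
    }
    for (ty in c("cds", "utr")) {
      sub <- p[p$type == ty, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        inside <- any(ex$start <= sub$start[k] & sub$end[k] <= ex$end)
        if (!inside) {
          stop("gene ", g, ": ", toupper(ty), " interval [", sub$start[k] + 1L, ",",
               sub$end[k], "] not contained in any exon (model-consistency error)")
        }
      }
    }
    if (gene$biotype == "ncRNA" && any(p$type == "cds")) {
      stop("gene ", g, ": ncRNA gene must not have CDS features")
    }
  }
  genes <- genes[order(genes$contig, genes$start, genes$gene_id, method = "radix"), ,
                 drop = FALSE]
  rownames(genes) <- rownames(parts) <- NULL
  structure(list(genes = genes[, c("gene_id", "contig", "start", "end", "strand",
                                   "biotype")],
                 parts = parts[, c("gene_id", "contig", "start", "end", "type")]),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "protein_coding"), "coding,",
      sum(x$genes$biotype == "ncRNA"), "ncRNA ) on",
      length(unique(x$genes$contig)), "contig(s)\n")
  invisible(x)
}

# region classes and the three strata used throughout the analysis
region_stratum <- function(region) {
  c(CODING = "coding", UTR = "noncoding", NCRNA = "noncoding",
    INTRONIC = "noncoding", INTERGENIC = "intergenic")[region]
}

#' Classify genomic positions into region classes
#'
#' Each position gets exactly one class with precedence
#' CODING > UTR > NCRNA > INTRONIC > INTERGENIC, and the gene(s) that
#' justify it: containing genes for the first four classes, nearest
#' gene(s) by distance to gene span (both on an exact tie) for
#' INTERGENIC. Classification ignores strand.
#'
#' @param model A `gene_model`.
#' @param contig Character vector of contig names.
#' @param pos1 Integer vector of 1-based positions (recycled with contig).
#' @return data.frame with columns `contig`, `pos1`, `region_class`,
#'   `stratum`, and list column `genes` (sorted gene ids).
#' @export
classify_positions <- function(model, contig, pos1) {
  if (!nrow(model$genes)) stop("gene model must contain at least one gene")
  n <- max(length(contig), length(pos1))
  contig <- rep_len(contig, n)
  pos1 <- rep_len(as.integer(pos1), n)
  if (any(pos1 < 1L)) stop("positions must be >= 1")
  absent <- setdiff(unique(contig), unique(model$genes$contig))
  if (length(absent)) {
    stop("contig(s) absent from gene model: ", paste(absent, collapse = ", "))
  }
  region <- character(n)
  genes_out <- vector("list", n)

  coding_genes <- model$genes$gene_id[model$genes$biotype == "protein_coding"]
  ncrna_genes <- model$genes$gene_id[model$genes$biotype == "ncRNA"]
  p <- model$parts
  layers <- list(
    CODING = p[p$type == "cds", , drop = FALSE],
    UTR = p[p$type == "utr", , drop = FALSE],
    NCRNA = p[p$type == "exon" & p$gene_id %in% ncrna_genes, , drop = FALSE],
    INTRONIC = data.frame(gene_id = model$genes$gene_id, contig = model$genes$contig,
                          start = model$genes$start, end = model$genes$end)
  )
  qry <- IRanges::IRanges(start = pos1, width = 1L)
  unassigned <- rep(TRUE, n)
  for (cls in names(layers)) {
    lay <- layers[[cls]]
    if (!nrow(lay)) next
    sub <- IRanges::IRanges(start = lay$start + 1L, end = lay$end)
    hits <- IRanges::findOverlaps(qry, sub)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same <- contig[qh] == lay$contig[sh]
    qh <- qh[same]; sh <- sh[same]
    take <- unassigned[qh]
    qh <- qh[take]; sh <- sh[take]
    if (!length(qh)) next
    by_pos <- split(lay$gene_id[sh], qh)
    idx <- as.integer(names(by_pos))
    region[idx] <- cls
    genes_out[idx] <- lapply(by_pos, function(g) sort(unique(g)))
    unassigned[idx] <- FALSE
  }
  # intergenic: nearest gene span(s) on the same contig, ties kept
  for (i in which(unassigned)) {
    g <- model$genes[model$genes$contig == contig[i], , drop = FALSE]
    d <- pmax(g$start + 1L - pos1[i], pos1[i] - g$end, 0L)
    region[i] <- "INTERGENIC"
    genes_out[[i]] <- sort(g$gene_id[d == min(d)])
  }
  out <- data.frame(contig = contig, pos1 = pos1, region_class = region,
                    stratum = unname(region_stratum(region)),
                    stringsAsFactors = FALSE)
  out$genes <- genes_out
  out
}

#' Classify a single position
#'
#' Scalar convenience wrapper around [classify_positions()].
#' @inheritParams classify_positions
#' @param pos1 A single 1-based position.
#' @return list with `region_class`, `stratum` and `genes`.
#' @export
classify_position <- function(model, contig, pos1) {
  r <- classify_positions(model, contig, pos1)
  list(region_class = r$region_class[1L], stratum = r$stratum[1L],
       genes = r$genes[[1L]])
}
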