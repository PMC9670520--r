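# Shared fixtures and independent oracles, all built in code.

# --- toy gene model -------------------------------------------------------
# GA: coding, chr1:101-1000, 3 exons with UTR5/CDS/UTR3
# GB: ncRNA, chr1:2000-2500, 2 exons (span start chosen so position 1500
#     is exactly equidistant from GA and GB)
# GC: coding, chr1:4001-4600, 2 exons
toy_gff_lines <- function() {
  c("##gff-version 3",
    "##sequence-region chr1 1 10000",
    "chr1\ttoy\tgene\t101\t1000\t.\t+\t.\tID=GA;gene_id=GA;biotype=protein_coding",
    "chr1\ttoy\texon\t101\t300\t.\t+\t.\tID=GA.e1;Parent=GA;gene_id=GA",
    "chr1\ttoy\texon\t501\t700\t.\t+\t.\tID=GA.e2;Parent=GA;gene_id=GA",
    "chr1\ttoy\texon\t901\t1000\t.\t+\t.\tID=GA.e3;Parent=GA;gene_id=GA",
    "chr1\ttoy\tfive_prime_UTR\t101\t150\t.\t+\t.\tID=GA.u5;Parent=GA;gene_id=GA",
    "chr1\ttoy\tCDS\t151\t300\t.\t+\t.\tID=GA.c1;Parent=GA;gene_id=GA",
    "chr1\ttoy\tCDS\t501\t700\t.\t+\t.\tID=GA.c2;Parent=GA;gene_id=GA",
    "chr1\ttoy\tCDS\t901\t950\t.\t+\t.\tID=GA.c3;Parent=GA;gene_id=GA",
    "chr1\ttoy\tthree_prime_UTR\t951\t1000\t.\t+\t.\tID=GA.u3;Parent=GA;gene_id=GA",
    "chr1\ttoy\tgene\t2000\t2500\t.\t-\t.\tID=GB;gene_id=GB;biotype=ncRNA",
    "chr1\ttoy\texon\t2000\t2100\t.\t-\t.\tID=GB.e1;Parent=GB;gene_id=GB",
    "chr1\ttoy\texon\t2301\t2500\t.\t-\t.\tID=GB.e2;Parent=GB;gene_id=GB",
    "chr1\ttoy\tgene\t4001\t4600\t.\t+\t.\tID=GC;gene_id=GC;biotype=protein_coding",
    "chr1\ttoy\texon\t4001\t4200\t.\t+\t.\tID=GC.e1;Parent=GC;gene_id=GC",
    "chr1\ttoy\texon\t4401\t4600\t.\t+\t.\tID=GC.e2;Parent=GC;gene_id=GC",
    "chr1\ttoy\tfive_prime_UTR\t4001\t4050\t.\t+\t.\tID=GC.u5;Parent=GC;gene_id=GC",
    "chr1\ttoy\tCDS\t4051\t4200\t.\t+\t.\tID=GC.c1;Parent=GC;gene_id=GC",
    "chr1\ttoy\tCDS\t4401\t4550\t.\t+\t.\tID=GC.c2;Parent=GC;gene_id=GC",
    "chr1\ttoy\tthree_prime_UTR\t4551\t4600\t.\t+\t.\tID=GC.u3;Parent=GC;gene_id=GC")
}

toy_gene_model <- function() {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(toy_gff_lines(), path)
  load_gene_model(path)
}

# --- carrier-matrix construction -----------------------------------------
make_keys <- function(n, contig = "chr1") {
  data.frame(contig = contig, pos1 = seq_len(n) * 10L,
             ref = rep("A", n), alt = rep("T", n), stringsAsFactors = FALSE)
}

make_cm <- function(carrier, keys = make_keys(ncol(carrier)),
                    samples = rownames(carrier)) {
  storage.mode(carrier) <- "integer"
  rownames(carrier) <- samples
  colnames(carrier) <- variant_key_id(keys)
  structure(list(variants = keys, samples = samples, carrier = carrier),
            class = "carrier_matrix")
}

make_sheet <- function(sample_id, group, family_id = sample_id,
                       role = ifelse(group == "CONTROL", "parent", "proband")) {
  validate_sample_sheet(data.frame(sample_id = sample_id, family_id = family_id,
                                   group = group, role = role,
                                   stringsAsFactors = FALSE))
}

# random toy cohort for the filter oracle checks
random_cohort <- function(seed) {
  set.seed(seed)
  n_s <- sample(6:30, 1)
  n_v <- sample(10:200, 1)
  group <- sample(c("BD_CANCER", "BD_ONLY", "CONTROL"), n_s, replace = TRUE)
  group[1] <- "BD_CANCER"  # filter requires >= 1 case
  ids <- sprintf("S%02d", seq_len(n_s))
  fam <- sprintf("F%02d", sample(ceiling(n_s / 2), n_s, replace = TRUE))
  role <- ifelse(group == "CONTROL",
                 sample(c("parent", "sibling"), n_s, replace = TRUE),
                 sample(c("proband", "proband", "sibling"), n_s, replace = TRUE))
  role[1] <- "proband"  # guarantee at least one eligible case
  sheet <- make_sheet(ids, group, fam, role)
  carrier <- matrix(rbinom(n_s * n_v, 1, 0.15), n_s, n_v, dimnames = list(ids, NULL))
  list(cm = make_cm(carrier, make_keys(n_v)), sheet = sheet)
}

# --- independent oracles --------------------------------------------------
# brute-force triple loop over variants x samples x groups
brute_force_select <- function(cm, sheet, min_cases = 3, require_unrelated = TRUE) {
  sheet <- sheet[match(cm$samples, sheet$sample_id), ]
  sel <- logical(nrow(cm$variants))
  counts <- integer(nrow(cm$variants))
  for (v in seq_len(nrow(cm$variants))) {
    fams <- character(0)
    n_case <- 0L
    excluded <- FALSE
    for (s in seq_along(cm$samples)) {
      if (cm$carrier[s, v] == 1L) {
        if (sheet$group[s] == "BD_CANCER" && sheet$role[s] == "proband") {
          if (require_unrelated) {
            if (!sheet$family_id[s] %in% fams) {
              fams <- c(fams, sheet$family_id[s])
              n_case <- n_case + 1L
            }
          } else {
            n_case <- n_case + 1L
          }
        } else if (sheet$group[s] %in% c("BD_ONLY", "CONTROL")) {
          excluded <- TRUE
        }
      }
    }
    counts[v] <- n_case
    sel[v] <- !excluded && n_case >= min_cases
  }
  out <- cm$variants[sel, , drop = FALSE]
  out$case_carriers <- counts[sel]
  out <- out[order(out$contig, out$pos1, out$ref, out$alt, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# per-base brute-force region classification over all feature intervals
brute_force_classify <- function(model, contig, pos1) {
  g <- model$genes[model$genes$contig == contig, ]
  p <- model$parts[model$parts$contig == contig, ]
  inside <- function(df) df$start + 1 <= pos1 & pos1 <= df$end
  coding <- g$gene_id[g$biotype == "protein_coding"]
  hit_cds <- unique(p$gene_id[p$type == "cds" & inside(p)])
  if (length(hit_cds)) return(list(region = "CODING", genes = sort(hit_cds)))
  hit_utr <- unique(p$gene_id[p$type == "utr" & inside(p)])
  if (length(hit_utr)) return(list(region = "UTR", genes = sort(hit_utr)))
  hit_nc <- unique(p$gene_id[p$type == "exon" & !p$gene_id %in% coding & inside(p)])
  if (length(hit_nc)) return(list(region = "NCRNA", genes = sort(hit_nc)))
  hit_span <- g$gene_id[inside(g)]
  if (length(hit_span)) return(list(region = "INTRONIC", genes = sort(hit_span)))
  d <- pmax(g$start + 1 - pos1, pos1 - g$end, 0)
  list(region = "INTERGENIC", genes = sort(g$gene_id[d == min(d)]))
}

# --- VCF text fixture writer ---------------------------------------------
write_test_vcf <- function(path, samples, records) {
  # records: list of lists(chrom, pos, ref, alt, gts = character vector)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (r in records) {
    lines <- c(lines, paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
                              ".", "GT", r$gts), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

write_test_sheet <- function(path, sheet) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
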