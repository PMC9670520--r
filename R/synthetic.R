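#' Configuration for the synthetic cohort simulator
#'
#' The simulator emulates the statistical structure the selection
#' pipeline assumes: a three-group cohort (BD probands with cancer, BD
#' probands without cancer, healthy family controls who are parents or
#' siblings of probands), shared background variation, approximate
#' Mendelian sharing between probands and their relatives, and planted
#' case-exclusive recurrent signal variants in each region stratum.
#'
#' The `"default"` scale (60 / 80 / 40 with a 25 / 15 validation split
#' and 30 signal variants among 2,000 background variants) keeps full
#' pipeline runs in the minutes range; `scale = "full"` switches the
#' group sizes to the 541 / 767 / 345 discovery and 25 / 15 validation
#' shape of a full-size birth-defect cohort.
#'
#' @param n_case,n_bd_only,n_control Discovery group sizes.
#' @param contig,contig_length Simulated contig name and length (bp).
#' @param n_genes Number of non-overlapping genes on the contig.
#' @param ncrna_fraction Fraction of genes simulated as non-coding RNAs.
#' @param exon_range Integer range of exons per gene.
#' @param n_background Number of background variants, carried i.i.d.
#'   across all groups at a per-variant frequency drawn log-uniformly
#'   from `freq_range`.
#' @param freq_range Carrier-frequency range for background variants.
#' @param n_signal Named vector: planted signal variants per stratum.
#' @param signal_carriers Candidate case-carrier counts for each signal
#'   variant (all >= the recurrence threshold by default).
#' @param n_adversarial Number of decoy variants that recur in cases
#'   but also have one BD-only carrier (and so must be filtered out).
#' @param n_val_case,n_val_bd_only Validation group sizes.
#' @param replant_rate Probability that a validation case carries each
#'   signal variant.
#' @param transmission_rate Probability that a family control inherits
#'   each background carrier allele of its proband.
#' @param seed Base RNG seed for all simulation stages.
#' @param scale `"default"` or `"full"` (overrides the group sizes).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 60L, n_bd_only = 80L, n_control = 40L,
                       contig = "chr1", contig_length = 1000000L,
                       n_genes = 100L, ncrna_fraction = 0.2,
                       exon_range = c(2L, 4L),
                       n_background = 2000L, freq_range = c(0.005, 0.2),
                       n_signal = c(coding = 10L, noncoding = 10L,
                                    intergenic = 10L),
                       signal_carriers = 3:6, n_adversarial = 0L,
                       n_val_case = 25L, n_val_bd_only = 15L,
                       replant_rate = 0.5, transmission_rate = 0.5,
                       seed = 1L, scale = c("default", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    n_case <- 541L; n_bd_only <- 767L; n_control <- 345L
    n_val_case <- 25L; n_val_bd_only <- 15L
  }
  cfg <- list(n_case = as.integer(n_case), n_bd_only = as.integer(n_bd_only),
              n_control = as.integer(n_control), contig = contig,
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes), ncrna_fraction = ncrna_fraction,
              exon_range = as.integer(exon_range),
              n_background = as.integer(n_background), freq_range = freq_range,
              n_signal = n_signal, signal_carriers = as.integer(signal_carriers),
              n_adversarial = as.integer(n_adversarial),
              n_val_case = as.integer(n_val_case),
              n_val_bd_only = as.integer(n_val_bd_only),
              replant_rate = replant_rate, transmission_rate = transmission_rate,
              seed = as.integer(seed), scale = scale)
  stopifnot(cfg$n_case >= 1L, cfg$n_bd_only >= 0L, cfg$n_control >= 0L,
            cfg$n_genes >= 2L, all(cfg$n_signal >= 0L),
            all(cfg$signal_carriers >= 1L),
            cfg$n_control <= cfg$n_case + cfg$n_bd_only)
  if (min(cfg$signal_carriers) > cfg$n_case) {
    stop("signal carrier counts exceed the number of cases")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Cohort shape summary (group sizes and totals)
#' @param cfg A [sim_config()].
#' @return list of group sizes, proband count, and cohort totals.
#' @export
cohort_shape <- function(cfg) {
  list(n_case = cfg$n_case, n_bd_only = cfg$n_bd_only, n_control = cfg$n_control,
       n_probands = cfg$n_case + cfg$n_bd_only,
       n_total = cfg$n_case + cfg$n_bd_only + cfg$n_control,
       n_val_case = cfg$n_val_case, n_val_bd_only = cfg$n_val_bd_only,
       n_val_total = cfg$n_val_case + cfg$n_val_bd_only)
}

#' Simulate a gene model and write it as GFF3
#'
#' Places `n_genes` non-overlapping genes on the contig, each with
#' exon/intron structure; protein-coding genes get 5'/3' UTR portions
#' in their terminal exons with CDS in between, ncRNA genes get exons
#' only. Output is byte-identical for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
simulate_gene_model <- function(cfg, path) {
  set.seed(cfg$seed)
  slot <- cfg$contig_length %/% cfg$n_genes
  if (slot < 200L) stop("contig too short for the requested number of genes")
  n_nc <- round(cfg$n_genes * cfg$ncrna_fraction)
  is_nc <- seq_len(cfg$n_genes) %in% sample(cfg$n_genes, n_nc)
  lines <- c("##gff-version 3",
             paste0("##sequence-region ", cfg$contig, " 1 ", cfg$contig_length))
  for (i in seq_len(cfg$n_genes)) {
    s0 <- (i - 1L) * slot
    glen <- as.integer(floor(slot * 0.5))
    gstart <- s0 + as.integer(floor(slot * 0.25))  # 0-based
    gend <- gstart + glen
    gid <- sprintf("G%03d", i)
    biotype <- if (is_nc[i]) "ncRNA" else "protein_coding"
    k <- sample(seq(cfg$exon_range[1], cfg$exon_range[2]), 1L)
    n_chunk <- 2L * k - 1L
    wts <- stats::runif(n_chunk, 0.5, 1.5)
    lens <- floor(glen * wts / sum(wts))
    if (any(lens < 12L)) lens <- rep(glen %/% n_chunk, n_chunk)
    bounds <- gstart + cumsum(c(0L, lens))
    exons <- data.frame(start = bounds[seq(1L, n_chunk, 2L)],
                        end = bounds[seq(1L, n_chunk, 2L) + 1L])
    strand <- sample(c("+", "-"), 1L)
    g1 <- function(s) s + 1L  # 0-based -> 1-based inclusive start
    lines <- c(lines, paste(cfg$contig, "bdvoi_sim", "gene", g1(gstart), gend, ".",
                            strand, ".", paste0("ID=", gid, ";gene_id=", gid,
                                                ";biotype=", biotype),
                            sep = "\t"))
    feat <- function(type, s, e, tag) {
      paste(cfg$contig, "bdvoi_sim", type, g1(s), e, ".", strand, ".",
            paste0("ID=", gid, ".", tag, ";Parent=", gid, ";gene_id=", gid),
            sep = "\t")
    }
    for (j in seq_len(nrow(exons))) {
      lines <- c(lines, feat("exon", exons$start[j], exons$end[j],
                             paste0("exon", j)))
    }
    if (!is_nc[i]) {
      first <- exons[1L, ]; last <- exons[nrow(exons), ]
      u5 <- max(1L, as.integer(floor(0.3 * (first$end - first$start))))
      u3 <- max(1L, as.integer(floor(0.3 * (last$end - last$start))))
      lines <- c(lines,
                 feat("five_prime_UTR", first$start, first$start + u5, "utr5"))
      cds <- if (nrow(exons) == 1L) {
        data.frame(start = first$start + u5, end = first$end - u3)
      } else {
        rbind(data.frame(start = first$start + u5, end = first$end),
              if (nrow(exons) > 2L)
                data.frame(start = exons$start[2:(nrow(exons) - 1L)],
                           end = exons$end[2:(nrow(exons) - 1L)]),
              data.frame(start = last$start, end = last$end - u3))
      }
      for (j in seq_len(nrow(cds))) {
        lines <- c(lines, feat("CDS", cds$start[j], cds$end[j], paste0("cds", j)))
      }
      lines <- c(lines, feat("three_prime_UTR", last$end - u3, last$end, "utr3"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# draw a random base / a random different base
draw_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

# candidate 1-based positions for each region stratum of the model
stratum_position_pool <- function(model, per_stratum = 2000L) {
  parts <- model$parts
  genes <- model$genes
  cds <- parts[parts$type == "cds", , drop = FALSE]
  utr <- parts[parts$type == "utr", , drop = FALSE]
  nc_ex <- parts[parts$type == "exon" &
                   parts$gene_id %in% genes$gene_id[genes$biotype == "ncRNA"], ,
                 drop = FALSE]
  pick <- function(df) {
    if (!nrow(df)) return(integer(0))
    i <- sample(nrow(df), per_stratum, replace = TRUE)
    as.integer(floor(stats::runif(per_stratum, df$start[i], df$end[i]))) + 1L
  }
  # introns: gene span minus exons, first intron of multi-exon genes
  introns <- do.call(rbind, lapply(split(parts[parts$type == "exon", ],
                                         parts$gene_id[parts$type == "exon"]),
                                   function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
  }))
  gaps <- do.call(rbind, lapply(split(genes, genes$contig), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    data.frame(start = g$end[-nrow(g)] + 5L, end = g$start[-1L] - 5L)
  }))
  noncoding <- rbind(utr[, c("start", "end")], nc_ex[, c("start", "end")],
                     introns)
  list(coding = pick(cds), noncoding = pick(noncoding),
       intergenic = pick(gaps[gaps$end > gaps$start, , drop = FALSE]))
}

#' Simulate a discovery cohort (VCF + sample sheet + truth)
#'
#' Background variants are carried i.i.d. across all probands at their
#' drawn frequency; each family control inherits its proband's
#' background carrier alleles at `transmission_rate` and adds its own
#' independent background. Signal variants are carried only by their
#' designated unrelated cases (never by controls or BD-only probands),
#' so each satisfies the recurrence/exclusivity rule by construction.
#'
#' @param cfg A [sim_config()].
#' @param model A `gene_model` (from [simulate_gene_model()] +
#'   [load_gene_model()]).
#' @param dir Output directory; writes `discovery.vcf`,
#'   `discovery_sheet.tsv`, `truth.json`.
#' @return list with `vcf`, `sheet` (paths) and `truth` (list).
#' @export
simulate_cohort <- function(cfg, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)
  # --- samples -------------------------------------------------------------
  case_ids <- sprintf("CA%04d", seq_len(cfg$n_case))
  bd_ids <- sprintf("BD%04d", seq_len(cfg$n_bd_only))
  probands <- c(case_ids, bd_ids)
  fam <- c(sprintf("F_CA%04d", seq_len(cfg$n_case)),
           sprintf("F_BD%04d", seq_len(cfg$n_bd_only)))
  names(fam) <- probands
  ctrl_ids <- sprintf("CT%04d", seq_len(cfg$n_control))
  ctrl_of <- if (cfg$n_control) sample(probands, cfg$n_control) else character(0)
  sheet <- data.frame(
    sample_id = c(probands, ctrl_ids),
    family_id = c(fam, fam[ctrl_of]),
    group = c(rep("BD_CANCER", cfg$n_case), rep("BD_ONLY", cfg$n_bd_only),
              rep("CONTROL", cfg$n_control)),
    role = c(rep("proband", length(probands)),
             if (cfg$n_control) sample(c("parent", "sibling"), cfg$n_control,
                                       replace = TRUE)),
    stringsAsFactors = FALSE)

  # --- signal positions per stratum ---------------------------------------
  pool <- stratum_position_pool(model)
  used <- integer(0)
  signal <- NULL
  for (st in names(cfg$n_signal)) {
    ns <- cfg$n_signal[[st]]
    if (!ns) next
    cand <- setdiff(unique(pool[[st]]), used)
    if (length(cand) < ns) stop("not enough candidate positions in stratum ", st)
    pos <- sample(cand, ns)
    used <- c(used, pos)
    signal <- rbind(signal, data.frame(pos1 = pos, stratum = st,
                                       stringsAsFactors = FALSE))
  }
  n_sig <- if (is.null(signal)) 0L else nrow(signal)
  # adversarial decoys recur in cases but leak into one BD-only proband
  n_dec <- cfg$n_adversarial
  dec_pos <- integer(0)
  if (n_dec) {
    cand <- setdiff(unique(pool$noncoding), used)
    dec_pos <- sample(cand, n_dec)
    used <- c(used, dec_pos)
  }
  # --- background variants -------------------------------------------------
  bg_pos <- sample(setdiff(seq_len(cfg$contig_length), used), cfg$n_background)
  freqs <- exp(stats::runif(cfg$n_background, log(cfg$freq_range[1]),
                            log(cfg$freq_range[2])))

  all_pos <- c(if (n_sig) signal$pos1, dec_pos, bg_pos)
  ra <- draw_ref_alt(length(all_pos))
  keys <- data.frame(contig = cfg$contig, pos1 = as.integer(all_pos),
                     ref = ra$ref, alt = ra$alt, stringsAsFactors = FALSE)
  kind <- c(rep("signal", n_sig), rep("decoy", n_dec),
            rep("background", cfg$n_background))

  # --- carriers ------------------------------------------------------------
  n_samp <- nrow(sheet)
  carr <- matrix(0L, n_samp, nrow(keys),
                 dimnames = list(sheet$sample_id, variant_key_id(keys)))
  sig_carriers <- vector("list", n_sig)
  for (j in seq_len(n_sig)) {
    m <- sample(cfg$signal_carriers, 1L)
    who <- sample(case_ids, m)
    carr[who, j] <- 1L
    sig_carriers[[j]] <- sort(who)
  }
  if (n_dec) {
    for (j in seq_len(n_dec)) {
      m <- sample(cfg$signal_carriers, 1L)
      carr[sample(case_ids, m), n_sig + j] <- 1L
      carr[sample(bd_ids, 1L), n_sig + j] <- 1L
    }
  }
  bg_cols <- n_sig + n_dec + seq_len(cfg$n_background)
  pb <- matrix(stats::rbinom(length(probands) * cfg$n_background, 1L,
                             rep(freqs, each = length(probands))),
               length(probands), cfg$n_background)
  carr[probands, bg_cols] <- pb
  if (cfg$n_control) {
    inherit <- pb[match(ctrl_of, probands), , drop = FALSE] *
      matrix(stats::rbinom(cfg$n_control * cfg$n_background, 1L,
                           cfg$transmission_rate),
             cfg$n_control, cfg$n_background)
    own <- matrix(stats::rbinom(cfg$n_control * cfg$n_background, 1L,
                                rep(freqs, each = cfg$n_control)),
                  cfg$n_control, cfg$n_background)
    carr[ctrl_ids, bg_cols] <- ((inherit + own) > 0L) * 1L
  }

  # --- write ---------------------------------------------------------------
  ord <- order(keys$pos1, keys$ref, keys$alt, method = "radix")
  keys_o <- keys[ord, , drop = FALSE]
  carr_o <- carr[, ord, drop = FALSE]
  vcf_path <- file.path(dir, "discovery.vcf")
  write_vcf_rows(vcf_path, keys_o, sheet$sample_id,
                 gt_rows = t(ifelse(carr_o == 1L, "0/1", "0/0")))
  sheet_path <- file.path(dir, "discovery_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    signal = if (n_sig) data.frame(keys[seq_len(n_sig), , drop = FALSE],
                                   stratum = signal$stratum,
                                   n_case_carriers = lengths(sig_carriers),
                                   stringsAsFactors = FALSE) else NULL,
    signal_carriers = sig_carriers,
    decoys = if (n_dec) keys[n_sig + seq_len(n_dec), , drop = FALSE] else NULL,
    background = keys[bg_cols, , drop = FALSE],
    freqs = freqs,
    n_case_with_control = sum(ctrl_of %in% case_ids),
    n_bd_with_control = sum(ctrl_of %in% bd_ids),
    ctrl_of = stats::setNames(ctrl_of, ctrl_ids))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(vcf = vcf_path, sheet = sheet_path, truth = truth,
       truth_path = truth_path)
}

#' Simulate an independent validation cohort
#'
#' Validation probands are new individuals (no family overlap with the
#' discovery cohort). All of them draw the discovery background
#' variants i.i.d. at the same frequencies; validation cases
#' additionally carry each planted signal variant with probability
#' `replant_rate`, validation BD-only probands carry background only.
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` list from [simulate_cohort()].
#' @param dir Output directory; writes `validation.vcf`,
#'   `validation_sheet.tsv`.
#' @return list with `vcf` and `sheet` paths.
#' @export
simulate_validation <- function(cfg, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2L)
  vc <- sprintf("VC%04d", seq_len(cfg$n_val_case))
  vb <- sprintf("VB%04d", seq_len(cfg$n_val_bd_only))
  ids <- c(vc, vb)
  sheet <- data.frame(sample_id = ids,
                      family_id = paste0("F_", ids),
                      group = c(rep("BD_CANCER", cfg$n_val_case),
                                rep("BD_ONLY", cfg$n_val_bd_only)),
                      role = "proband", stringsAsFactors = FALSE)
  sig <- truth$signal
  n_sig <- if (is.null(sig)) 0L else nrow(sig)
  bg <- truth$background
  keys <- rbind(if (n_sig) sig[, c("contig", "pos1", "ref", "alt")], bg)
  carr <- matrix(0L, length(ids), nrow(keys),
                 dimnames = list(ids, variant_key_id(keys)))
  if (n_sig) {
    carr[vc, seq_len(n_sig)] <-
      matrix(stats::rbinom(length(vc) * n_sig, 1L, cfg$replant_rate),
             length(vc), n_sig)
  }
  bg_cols <- n_sig + seq_len(nrow(bg))
  carr[ids, bg_cols] <- matrix(stats::rbinom(length(ids) * nrow(bg), 1L,
                                             rep(truth$freqs, each = length(ids))),
                               length(ids), nrow(bg))
  ord <- order(keys$pos1, keys$ref, keys$alt, method = "radix")
  vcf_path <- file.path(dir, "validation.vcf")
  write_vcf_rows(vcf_path, keys[ord, , drop = FALSE], ids,
                 gt_rows = t(ifelse(carr[, ord, drop = FALSE] == 1L, "0/1", "0/0")))
  sheet_path <- file.path(dir, "validation_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcf_path, sheet = sheet_path)
}

#' Analytic expectation of spurious selections under the null
#'
#' Closed-form probability, per background variant, that i.i.d.
#' background carriage alone passes the recurrence/exclusivity filter:
#' at least `min_cases` case carriers, zero BD-only carriers, zero
#' control carriers, accounting for family controls who inherit a
#' proband's carrier allele at `transmission_rate`. Used as the
#' independent oracle for null calibration of [select_variants()].
#'
#' @param freqs Per-variant carrier frequencies.
#' @param n_case,n_bd Number of case / BD-only probands.
#' @param k_case_ctrl,k_bd_ctrl How many of each have a family control.
#' @param min_cases Recurrence threshold.
#' @param transmission_rate Control inheritance probability.
#' @return list with `per_variant` pass probabilities, `expected` total
#'   and `variance` of the spurious-selection count.
#' @export
expected_spurious_selections <- function(freqs, n_case, n_bd,
                                         k_case_ctrl = 0L, k_bd_ctrl = 0L,
                                         min_cases = 3L,
                                         transmission_rate = 0.5) {
  t <- transmission_rate
  per <- vapply(freqs, function(f) {
    # BD-only side: proband non-carrier; its control non-carrier given that
    p_bd <- (1 - f)^(n_bd - k_bd_ctrl) * ((1 - f)^2)^k_bd_ctrl
    # case side: generating polynomial of (carrier count, no control carrier)
    n_free <- n_case - k_case_ctrl
    poly <- stats::dbinom(0:n_free, n_free, f)
    if (k_case_ctrl > 0L) {
      q1 <- f * (1 - t) * (1 - f)        # case carries, control clean
      q0 <- (1 - f) * (1 - f)            # case clean, control clean
      poly2 <- choose(k_case_ctrl, 0:k_case_ctrl) *
        q1^(0:k_case_ctrl) * q0^(k_case_ctrl:0)
      poly <- stats::convolve(poly, rev(poly2), type = "open")
    }
    p_case <- sum(poly[(min_cases + 1L):length(poly)])
    max(0, p_case * p_bd)
  }, numeric(1))
  list(per_variant = per, expected = sum(per), variance = sum(per * (1 - per)))
}
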