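#' Default synthetic fixture specification
#'
#' Builds the specification of a synthetic 34-gene AML panel cohort:
#' a fictitious genome with one contig per gene, seven diagnostic
#' tumour samples carrying the dominant-clone mutation catalogue (20
#' exonic events plus one intronic NF1 event, split 11 substitutions
#' / 9 indels, at 45% VAF), subclonal substitutions (two co-occurring
#' near 4.4%/4.1% of reads in one sample, one near 3% in another, one
#' frameshift at 8% in the relapse sample), one remission sample with
#' no mutant reads, one remission sample carrying its diagnostic
#' trio of mutations at 1.5-2.4% of reads, and a copy-number cohort
#' of 10 samples: one globally aberrant (QC-fail) sample, a CYP2D6
#' loss in one sample, PTEN losses in two, and an MLL exon 2-9 gain
#' in one.
#'
#' @param depth Target sequencing depth (default 5000).
#' @param dominant_vaf VAF of dominant-clone plants (default 0.45, a
#'   typical heterozygous mutation at high blast fraction).
#' @param seed Seed stored in the spec (used by the generators unless
#'   overridden).
#' @return A `fixture_spec` list with `panel`, `samples`, `variants`,
#'   `cnvs`, `qc_fail_sample`, `x_genes`, `depth`, `seed`.
#' @export
build_default_spec <- function(depth = 5000L, dominant_vaf = 0.45, seed = 1L) {
  panel <- data.frame(
    gene = c("NRAS", "DNMT3A", "SF3B1", "IDH1", "KIT", "TET2", "CSF1R",
             "NPM1", "EZH2", "JAK2", "PTEN", "WT1", "MLL", "CBL", "KRAS",
             "PTPN11", "FLT3", "IDH2", "TP53", "NF1", "CEBPA", "ASXL1",
             "RUNX1", "KDM6A", "UGT1A1", "PIK3CA", "IKZF1", "EGFR", "BRAF",
             "XRCC2", "PAX5", "TLR4", "CYP2D6", "HPRT1"),
    n_exons = c(5L, 23L, 25L, 8L, 21L, 11L, 21L,
                11L, 20L, 25L, 9L, 10L, 16L, 16L, 5L,
                15L, 24L, 11L, 11L, 12L, 1L, 12L,
                8L, 10L, 5L, 20L, 8L, 28L, 18L,
                3L, 10L, 3L, 9L, 9L),
    stringsAsFactors = FALSE
  )
  panel$x_linked <- panel$gene %in% c("KDM6A", "HPRT1")

  samples <- data.frame(
    id = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P1CR", "P2CR", "P4Rel"),
    role = c(rep("tumour", 7), "remission", "remission", "relapse"),
    sex = c("F", "M", "M", "F", "M", "M", "F", "F", "M", "F"),
    stringsAsFactors = FALSE
  )

  # position of a variant placed in exon k at 1-based offset within the
  # exon (exon i is [1000 + (i-1)*500, ... + 150) on the gene's contig)
  vpos <- function(exon, offset) 1000L + (exon - 1L) * 500L + offset

  v <- function(sample, gene, exon, offset, ref, alt, type, vaf,
                region = "exonic", label = "") {
    data.frame(
      sample = sample, gene = gene, chrom = gene,
      pos = vpos(exon, offset), ref = ref, alt = alt, type = type,
      vaf = vaf,
      clonality = if (vaf > 0.20) "dominant" else "subclonal",
      region = region, label = label, stringsAsFactors = FALSE
    )
  }
  d <- dominant_vaf
  variants <- rbind(
    # -- dominant clone, diagnostic samples --
    v("P1", "NPM1",   11L,  75L, "C", "TCTG", "insertion",   d, label = "NPM1 L287fs"),
    v("P1", "DNMT3A", 23L,  40L, "C", "T",    "substitution", d, label = "DNMT3A R882C"),
    v("P1", "FLT3",   20L,  60L, "G", "T",    "substitution", d, label = "FLT3 D835Y"),
    v("P2", "ASXL1",  12L,  40L, "G", "G",    "deletion",     d, label = "ASXL1 G642fs"),
    v("P2", "TET2",   11L,  55L, "T", "A",    "substitution", d, label = "TET2 L1119*"),
    v("P2", "KRAS",    4L,  45L, "G", "T",    "substitution", d, label = "KRAS K117N"),
    v("P3", "CEBPA",   1L,  30L, "C", "G",    "deletion",     d, label = "CEBPA A111fs"),
    v("P3", "CEBPA",   1L, 120L, "A", "AAC",  "insertion",    d, label = "CEBPA T310NT"),
    v("P3", "WT1",     2L,  50L, "A", "CT",   "deletion",     d, label = "WT1 R145fs"),
    v("P3", "NRAS",    2L,  40L, "G", "A",    "substitution", d, label = "NRAS G12D"),
    v("P4", "NPM1",   11L,  75L, "C", "TCTG", "insertion",    d, label = "NPM1 L287fs"),
    v("P4", "IDH2",    4L,  40L, "G", "A",    "substitution", d, label = "IDH2 R140Q"),
    v("P5", "NPM1",   11L,  75L, "C", "TCTG", "insertion",    d, label = "NPM1 L287fs"),
    v("P5", "IDH1",    4L,  70L, "G", "A",    "substitution", d, label = "IDH1 R132H"),
    v("P5", "FLT3",   20L,  60L, "G", "T",    "substitution", d, label = "FLT3 D835Y"),
    v("P6", "ASXL1",  12L,  90L, "T", "A",    "substitution", d, label = "ASXL1 C594*"),
    v("P6", "TET2",    6L,  35L, "C", "C",    "deletion",     d, label = "TET2 P612fs"),
    v("P6", "KRAS",    2L,  45L, "G", "T",    "substitution", d, label = "KRAS G12V"),
    v("P7", "DNMT3A", 15L,  65L, "G", "G",    "deletion",     d, label = "DNMT3A G590fs"),
    v("P7", "IDH2",    4L,  90L, "G", "A",    "substitution", d, label = "IDH2 R172K"),
    # -- the intronic NF1 event (captured intronic control stretch) --
    data.frame(
      sample = "P2", gene = "NF1", chrom = "NF1",
      pos = vpos(2L, 0L) + 250L, ref = "C", alt = "T",
      type = "substitution", vaf = d, clonality = "dominant",
      region = "intronic", label = "NF1 intron 2", stringsAsFactors = FALSE
    ),
    # -- subclones --
    v("P5", "NRAS",    2L,  39L, "G", "A", "substitution", 0.044, label = "NRAS G12S"),
    v("P5", "PTPN11", 13L,  50L, "A", "C", "substitution", 0.041, label = "PTPN11 Q506P"),
    v("P4", "FLT3",   16L,  55L, "C", "A", "substitution", 0.030, label = "FLT3 N676K"),
    v("P4Rel", "TP53", 11L, 45L, "G", "G", "deletion",     0.080, label = "TP53 G374fs"),
    # -- relapse dominant clone --
    v("P4Rel", "NPM1", 11L, 75L, "C", "TCTG", "insertion",   d, label = "NPM1c (TCTG)"),
    v("P4Rel", "IDH2",  4L, 40L, "G", "A",    "substitution", d, label = "IDH2 R140Q"),
    # -- residual disease in remission sample P2CR (P2's exonic trio) --
    v("P2CR", "ASXL1", 12L, 40L, "G", "G", "deletion",     0.020, label = "ASXL1 G642fs"),
    v("P2CR", "TET2",  11L, 55L, "T", "A", "substitution", 0.015, label = "TET2 L1119*"),
    v("P2CR", "KRAS",   4L, 45L, "G", "T", "substitution", 0.024, label = "KRAS K117N")
  )

  cnvs <- data.frame(
    sample = c("P3", "P2", "P6", "P6"),
    gene = c("CYP2D6", "PTEN", "PTEN", "MLL"),
    first_exon = c(1L, 1L, 1L, 2L),
    last_exon = c(9L, 9L, 9L, 9L),
    ratio = c(0.5, 0.5, 0.5, 1.5),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      panel = panel, samples = samples, variants = variants, cnvs = cnvs,
      qc_fail_sample = "P5",
      x_genes = panel$gene[panel$x_linked],
      depth = as.integer(depth), dominant_vaf = dominant_vaf,
      seed = as.integer(seed),
      exon_size = 150L, exon_spacing = 500L, exon_origin = 1000L
    ),
    class = "fixture_spec"
  )
}

#' Target regions of a fixture panel
#'
#' One BED4(+kind) row per exon of every panel gene, plus the NF1
#' intron-2 captured control stretch.  Coordinates 0-based half-open.
#'
#' @param spec A [build_default_spec()] fixture spec.
#' @return data.frame `chrom`, `start`, `end`, `gene`, `kind`.
#' @export
panel_targets <- function(spec) {
  rows <- lapply(seq_len(nrow(spec$panel)), function(i) {
    g <- spec$panel$gene[[i]]
    k <- seq_len(spec$panel$n_exons[[i]])
    start <- spec$exon_origin + (k - 1L) * spec$exon_spacing
    data.frame(
      chrom = g, start = start, end = start + spec$exon_size,
      gene = g, kind = "exonic", stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  nf1_i2 <- spec$exon_origin + 1L * spec$exon_spacing   # between exons 2 and 3
  out <- rbind(out, data.frame(
    chrom = "NF1", start = nf1_i2 + 200L, end = nf1_i2 + 300L,
    gene = "NF1", kind = "intronic-control", stringsAsFactors = FALSE
  ))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write a fixture panel BED file
#'
#' @param spec A fixture spec.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(spec, path) {
  tg <- panel_targets(spec)
  utils::write.table(tg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# One pileup line: n_alt reads carrying the event, rest reference.
.pileup_line <- function(chrom, pos, ref, depth, n_alt = 0L,
                         alt = NULL, type = "substitution",
                         bq = 35L, mq = 60L) {
  if (n_alt > 0L) {
    alt_tok <- switch(
      type,
      substitution = alt,
      insertion = paste0(".+", nchar(alt), alt),
      deletion = paste0(".-", nchar(alt), alt)
    )
    bases <- paste0(strrep(alt_tok, n_alt), strrep(".", depth - n_alt))
  } else {
    bases <- strrep(".", depth)
  }
  paste(chrom, pos, ref, depth,
        bases,
        strrep(intToUtf8(bq + 33L), depth),
        strrep(intToUtf8(mq + 33L), depth),
        sep = "\t")
}

#' Generate per-sample pileup fixtures and their truth table
#'
#' Every sample's pileup covers the union of all planted positions
#' plus one flanking reference-only position on each side, so any
#' sample can serve as a control for any other.  In `deterministic`
#' mode the planted event gets exactly `round(vaf * depth)` mutant
#' reads at constant depth; in `sampled` mode depth is Poisson around
#' the spec depth and mutant reads binomial at the planted VAF, under
#' the given seed.  Planted reads carry base quality 35 and mapping
#' quality 60 so the quality filters are not the variable under test.
#'
#' @param spec A fixture spec.
#' @param dir Output directory (created if needed).
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed Seed for `sampled` mode (defaults to the spec's).
#' @return List with `pileups` (named paths), `truth` (data.frame of
#'   planted events), `bed` (panel BED path).
#' @export
generate_pileups <- function(spec, dir,
                             mode = c("deterministic", "sampled"),
                             seed = spec$seed) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (mode == "sampled") set.seed(seed)

  va <- spec$variants
  site_key <- function(chrom, pos) paste0(chrom, ":", pos)
  planted_sites <- unique(data.frame(
    chrom = va$chrom, pos = va$pos, ref = va$ref, stringsAsFactors = FALSE
  ))
  flanks <- rbind(
    data.frame(chrom = planted_sites$chrom, pos = planted_sites$pos - 1L,
               ref = "A", stringsAsFactors = FALSE),
    data.frame(chrom = planted_sites$chrom, pos = planted_sites$pos + 1L,
               ref = "A", stringsAsFactors = FALSE)
  )
  flanks <- flanks[!site_key(flanks$chrom, flanks$pos) %in%
                     site_key(planted_sites$chrom, planted_sites$pos), ]
  sites <- rbind(planted_sites, flanks)
  sites <- sites[!duplicated(site_key(sites$chrom, sites$pos)), ]
  sites <- sites[order(sites$chrom, sites$pos), ]

  if (mode == "deterministic") {
    bad <- round(va$vaf * spec$depth) < 1
    if (any(bad)) {
      stop("unrepresentable plant: VAF x depth < 1 read for ",
           paste(va$label[bad], collapse = ", "))
    }
  }

  paths <- character(0)
  for (s in spec$samples$id) {
    mine <- va[va$sample == s, , drop = FALSE]
    mine_key <- site_key(mine$chrom, mine$pos)
    lines <- character(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      k <- site_key(sites$chrom[[i]], sites$pos[[i]])
      depth <- if (mode == "deterministic") {
        spec$depth
      } else {
        stats::rpois(1L, spec$depth)
      }
      hit <- match(k, mine_key)
      if (!is.na(hit)) {
        n_alt <- if (mode == "deterministic") {
          as.integer(round(mine$vaf[[hit]] * depth))
        } else {
          stats::rbinom(1L, depth, mine$vaf[[hit]])
        }
        lines[[i]] <- .pileup_line(
          sites$chrom[[i]], sites$pos[[i]], sites$ref[[i]], depth,
          n_alt = n_alt, alt = mine$alt[[hit]], type = mine$type[[hit]]
        )
      } else {
        lines[[i]] <- .pileup_line(
          sites$chrom[[i]], sites$pos[[i]], sites$ref[[i]], depth
        )
      }
    }
    p <- file.path(dir, paste0(s, ".pileup"))
    writeLines(lines, p)
    paths[[s]] <- p
  }

  bed <- file.path(dir, "panel.bed")
  write_panel_bed(spec, bed)
  list(pileups = paths, truth = va, bed = bed)
}

#' Generate a normalised exon count matrix with planted copy events
#'
#' Simulates per-exon mean depths for the whole cohort: a shared
#' per-exon capture factor (lognormal around the spec depth), a
#' bounded per-sample-and-gene capture-efficiency factor (uniform
#' within +/-5%, the dominant between-sample noise in well-behaved
#' capture data), Poisson counting noise, per-sample library-size
#' factors, X-linked genes scaled by sex (2 copies in females, 1 in
#' males), planted CNVs multiplying the mean by their copy ratio,
#' and a globally aberrant QC-fail sample whose per-gene means are
#' distorted by lognormal factors (sd 0.6 on the log2 scale).
#' Values are normalised as mean exon depth / total mapped reads
#' x 1e6.
#'
#' @param spec A fixture spec.
#' @param seed Seed (defaults to the spec's).
#' @return List with `matrix` (an `exon_count_matrix`), `sex` (named
#'   vector), and `truth` (the spec's `cnvs`, `qc_fail_sample`,
#'   `x_genes`).
#' @export
generate_count_matrix <- function(spec, seed = spec$seed) {
  set.seed(seed)
  exons <- amalgamate_exons(panel_targets(spec))
  ids <- spec$samples$id
  sex <- stats::setNames(spec$samples$sex, ids)

  lambda <- spec$depth * exp(stats::rnorm(nrow(exons), 0, 0.2))
  libfac <- stats::setNames(stats::runif(length(ids), 0.8, 1.2), ids)
  total <- stats::setNames(round(libfac * 4e7), ids)
  qc_fac <- 2^stats::rnorm(nrow(spec$panel), 0, 0.6)
  names(qc_fac) <- spec$panel$gene

  vals <- matrix(
    0, nrow = length(ids), ncol = nrow(exons),
    dimnames = list(ids, paste0(exons$gene, ":", exons$exon_index))
  )
  for (s in ids) {
    copy <- rep(1, nrow(exons))
    xg <- exons$gene %in% spec$x_genes
    if (sex[[s]] == "M") copy[xg] <- 0.5
    cn <- spec$cnvs[spec$cnvs$sample == s, , drop = FALSE]
    for (r in seq_len(nrow(cn))) {
      sel <- exons$gene == cn$gene[[r]] &
        exons$exon_index >= cn$first_exon[[r]] &
        exons$exon_index <= cn$last_exon[[r]]
      copy[sel] <- copy[sel] * cn$ratio[[r]]
    }
    gf <- if (s == spec$qc_fail_sample) qc_fac[exons$gene] else 1
    cap <- stats::setNames(stats::runif(nrow(spec$panel), 0.95, 1.05),
                           spec$panel$gene)
    mu <- lambda * copy * gf * cap[exons$gene] * libfac[[s]]
    raw <- stats::rpois(nrow(exons), mu)
    vals[s, ] <- raw / total[[s]] * 1e6
  }

  mat <- structure(
    list(values = vals, exons = exons, samples = ids,
         total_mapped_reads = total),
    class = "exon_count_matrix"
  )
  list(
    matrix = mat, sex = sex,
    truth = list(cnvs = spec$cnvs, qc_fail_sample = spec$qc_fail_sample,
                 x_genes = spec$x_genes)
  )
}
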