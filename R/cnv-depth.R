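#' CNV analysis parameters
#'
#' @param gain_ratio Per-exon fold change (sample vs across-sample
#'   median) at or above which a sample is implicated in a gain.  The
#'   default 1.4 sits below the 1.5x expected for a heterozygous
#'   single-copy gain, leaving a noise margin.
#' @param loss_ratio Fold change at or below which a sample is
#'   implicated in a loss (heterozygous loss expects 0.5x).
#' @param max_outlier_genes A sample outlying in more than this many
#'   genes is excluded by QC.
#' @param het_band Comparator minor-allele-fraction band within which
#'   a SNP counts as heterozygous (informative).
#' @param imbalance_delta Minimum drop in tumour minor-allele
#'   fraction, relative to the comparator, to call a SNP imbalanced.
#' @param alpha Significance level for the exact test on the 2x2
#'   allele-count table.
#' @param min_dup_run Minimum contiguous elevated-exon run length for
#'   a duplication segment.
#' @return A `cnv_config` list.
#' @export
cnv_config <- function(gain_ratio = 1.4, loss_ratio = 0.7,
                       max_outlier_genes = 3L,
                       het_band = c(0.3, 0.7),
                       imbalance_delta = 0.15, alpha = 0.05,
                       min_dup_run = 2L) {
  structure(
    list(
      gain_ratio = gain_ratio, loss_ratio = loss_ratio,
      max_outlier_genes = as.integer(max_outlier_genes),
      het_band = het_band, imbalance_delta = imbalance_delta,
      alpha = alpha, min_dup_run = as.integer(min_dup_run)
    ),
    class = "cnv_config"
  )
}

#' Merge overlapping annotated exons into amalgamated exons
#'
#' Per gene, overlapping annotated exons collapse to non-redundant
#' merged intervals ("amalgamated exons"), re-indexed in genomic
#' order.  Coordinates are 0-based half-open throughout.
#'
#' @param raw_exons data.frame with `chrom`, `start`, `end`, `gene`
#'   (e.g. from [read_targets()]); rows of kind `intronic-control`
#'   are dropped if a `kind` column is present.
#' @return data.frame `chrom`, `start`, `end`, `gene`, `exon_index`.
#' @export
amalgamate_exons <- function(raw_exons) {
  if (!is.null(raw_exons$kind)) {
    raw_exons <- raw_exons[raw_exons$kind == "exonic", , drop = FALSE]
  }
  if (nrow(raw_exons) == 0L) {
    return(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      gene = character(0), exon_index = integer(0), stringsAsFactors = FALSE
    ))
  }
  pieces <- lapply(split(raw_exons, raw_exons$gene), function(g) {
    # IRanges is closed [start, end]; shift BED half-open ends by one
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    data.frame(
      chrom = g$chrom[[1]],
      start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir),
      gene = g$gene[[1]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$gene, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$exon_index <- stats::ave(seq_len(nrow(out)), out$gene, FUN = seq_along)
  out
}

#' Build the normalised exon count matrix
#'
#' For each sample and amalgamated exon, the normalised count is the
#' mean per-base depth over the exon divided by the sample's total
#' mapped reads, times `scale` (default 1e6): depth per exon base per
#' million mapped reads.  Invariant under jointly scaling a sample's
#' depths and total.
#'
#' @param depths Named list (by sample id) of data.frames `chrom`,
#'   `pos` (1-based), `depth`; positions absent from the table count
#'   as depth 0.
#' @param exons Amalgamated exon table from [amalgamate_exons()].
#' @param total_mapped_reads Named numeric vector, per-sample totals
#'   (must be > 0).
#' @param scale Multiplier applied after division (default 1e6).
#' @return An `exon_count_matrix`: list with `values` (samples x
#'   exons matrix, columns named `gene:exon_index`), `exons`,
#'   `samples`, `total_mapped_reads`.
#' @export
normalize_counts <- function(depths, exons, total_mapped_reads, scale = 1e6) {
  samples <- names(depths)
  if (is.null(samples)) stop("'depths' must be a named list of per-sample tables")
  if (any(total_mapped_reads[samples] <= 0)) {
    stop("total_mapped_reads must be positive")
  }
  vals <- matrix(
    0, nrow = length(samples), ncol = nrow(exons),
    dimnames = list(samples, paste0(exons$gene, ":", exons$exon_index))
  )
  for (s in samples) {
    d <- depths[[s]]
    key <- paste0(d$chrom, ":", d$pos)
    depth_at <- stats::setNames(d$depth, key)
    for (j in seq_len(nrow(exons))) {
      posns <- (exons$start[[j]] + 1L):exons$end[[j]]
      k <- paste0(exons$chrom[[j]], ":", posns)
      dv <- depth_at[k]
      dv[is.na(dv)] <- 0
      vals[s, j] <- mean(dv) / total_mapped_reads[[s]] * scale
    }
  }
  structure(
    list(values = vals, exons = exons, samples = samples,
         total_mapped_reads = total_mapped_reads[samples]),
    class = "exon_count_matrix"
  )
}

# Accept either an exon_count_matrix or a bare samples x exons matrix
# whose column names are "gene:exon_index".
.ecm_values <- function(m) {
  if (inherits(m, "exon_count_matrix")) m$values else as.matrix(m)
}

.ecm_genes <- function(m) {
  if (inherits(m, "exon_count_matrix")) {
    m$exons$gene
  } else {
    sub(":[0-9]+$", "", colnames(as.matrix(m)))
  }
}

.ecm_exon_index <- function(m) {
  if (inherits(m, "exon_count_matrix")) {
    m$exons$exon_index
  } else {
    as.integer(sub("^.*:", "", colnames(as.matrix(m))))
  }
}

# Tukey fences on one numeric vector (type-7 quartiles); returns a
# logical outlier mask.  both = lower fence too.
.tukey_mask <- function(x, both = FALSE) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[[2]] - q[[1]]
  up <- x > q[[2]] + 1.5 * iqr
  if (both) up | x < q[[1]] - 1.5 * iqr else up
}

#' Exclude samples with aberrant per-gene coverage profiles
#'
#' For every gene, each sample's mean normalised count across the
#' gene's exons is screened with Tukey fences (both directions)
#' across samples.  A sample outlying in more than
#' `cfg$max_outlier_genes` genes is excluded from downstream
#' copy-number analysis — aberrant capture efficiency (e.g. degraded
#' DNA) distorts counts genome-wide, unlike a real CNV.
#'
#' @param matrix An `exon_count_matrix` (or bare matrix with
#'   `gene:exon_index` column names).
#' @param cfg A [cnv_config()].
#' @return List with `retained` (sample ids), `excluded` (sample
#'   ids), and `outlier_genes` (named integer vector, genes outlying
#'   per sample).
#' @export
qc_samples <- function(matrix, cfg = cnv_config()) {
  vals <- .ecm_values(matrix)
  genes <- .ecm_genes(matrix)
  if (nrow(vals) < 4L) stop("sample QC needs at least 4 samples")
  n_out <- stats::setNames(integer(nrow(vals)), rownames(vals))
  for (g in unique(genes)) {
    gm <- rowMeans(vals[, genes == g, drop = FALSE])
    mask <- .tukey_mask(gm, both = TRUE)
    n_out <- n_out + as.integer(mask)
  }
  excluded <- names(n_out)[n_out > cfg$max_outlier_genes]
  list(
    retained = setdiff(rownames(vals), excluded),
    excluded = excluded,
    outlier_genes = n_out
  )
}

#' Per-exon coefficient of variability
#'
#' CV(exon) = sample standard deviation (n-1 denominator) divided by
#' the mean of the normalised counts across the retained samples.  A
#' zero-mean exon gets CV 0 with a warning.
#'
#' @param matrix An `exon_count_matrix` or bare matrix (rows already
#'   restricted to retained samples).
#' @return Named numeric vector of CVs, one per exon column.
#' @export
exon_cv <- function(matrix) {
  vals <- .ecm_values(matrix)
  if (nrow(vals) < 3L) stop("CV needs at least 3 retained samples")
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  if (any(mu == 0)) {
    warning(sum(mu == 0), " exon(s) with zero mean normalised count; CV set to 0")
  }
  stats::setNames(cv, colnames(vals))
}

#' Flag outlier exons by the Tukey boxplot rule
#'
#' An exon is flagged when its CV strictly exceeds the upper fence
#' Q3 + 1.5 * IQR, quartiles by linear interpolation (quantile
#' type 7).  Only the upper fence is used: elevated variability is
#' the copy-number signature; unusually uniform exons are not of
#' interest.
#'
#' @param cvs Named numeric vector from [exon_cv()].
#' @return Character vector of flagged exon names.
#' @export
tukey_outlier_exons <- function(cvs) {
  if (length(cvs) < 4L) stop("Tukey fences need at least 4 exons")
  names(cvs)[.tukey_mask(unname(cvs))]
}

#' Gene-level copy-number flags
#'
#' A gene is flagged when at least two of its exons are CV-flagged.
#' For each flagged exon, per-sample fold change against the
#' across-sample median identifies implicated samples (fold >=
#' `gain_ratio` for gains, <= `loss_ratio` for losses); the gene's
#' direction is taken per implicated sample.  A warning is raised for
#' flagged genes with under 3 exons, where the absence of flanking
#' coverage makes the evidence weak.
#'
#' @param flagged_exons Character vector from [tukey_outlier_exons()].
#' @param matrix The `exon_count_matrix` restricted to retained
#'   samples.
#' @param cfg A [cnv_config()].
#' @param exclude Genes to drop from gene-level flagging.  In a
#'   mixed-sex cohort the X-linked genes always show elevated CV (two
#'   copies in females vs one in males); that signal is dosage, not a
#'   somatic event, and is assessed by [sex_linked_ratio()] instead.
#' @return data.frame with one row per (gene, implicated sample):
#'   `gene`, `sample`, `direction`, `n_flagged_exons`,
#'   `flagged_exons` (comma-joined indices), `mean_fold`.
#' @export
flag_cnv_genes <- function(flagged_exons, matrix, cfg = cnv_config(),
                           exclude = character(0)) {
  vals <- .ecm_values(matrix)
  genes <- .ecm_genes(matrix)
  exi <- .ecm_exon_index(matrix)
  flag_gene <- genes[match(flagged_exons, colnames(vals))]
  tab <- table(flag_gene)
  hit_genes <- setdiff(names(tab)[tab >= 2L], exclude)
  rows <- list()
  for (g in hit_genes) {
    cols <- which(colnames(vals) %in% flagged_exons & genes == g)
    if (sum(genes == g) < 3L) {
      warning("gene ", g, " flagged on under 3 exons; ",
              "no flanking coverage to corroborate the call")
    }
    med <- apply(vals[, cols, drop = FALSE], 2, stats::median)
    fold <- sweep(vals[, cols, drop = FALSE], 2, med, "/")
    mean_fold <- rowMeans(fold)
    gain <- mean_fold >= cfg$gain_ratio
    loss <- mean_fold <= cfg$loss_ratio
    for (s in rownames(vals)[gain | loss]) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s,
        direction = if (gain[[s]]) "gain" else "loss",
        n_flagged_exons = length(cols),
        flagged_exons = paste(exi[cols], collapse = ","),
        mean_fold = mean_fold[[s]],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      gene = character(0), sample = character(0), direction = character(0),
      n_flagged_exons = integer(0), flagged_exons = character(0),
      mean_fold = numeric(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locate a contiguous duplicated exon segment within a gene
#'
#' Returns the maximal run (length >= `cfg$min_dup_run`) of
#' consecutive exons whose fold change against the across-sample
#' median is at or above `cfg$gain_ratio` for the given sample — the
#' read-depth signature of a partial tandem duplication.
#'
#' @param matrix `exon_count_matrix` restricted to retained samples.
#' @param gene Gene name (needs >= 3 exons).
#' @param sample Sample id to interrogate.
#' @param cfg A [cnv_config()].
#' @return List `first_exon`, `last_exon`, `mean_fold`, or `NULL` if
#'   no qualifying run exists.
#' @export
detect_duplication_segment <- function(matrix, gene, sample, cfg = cnv_config()) {
  vals <- .ecm_values(matrix)
  genes <- .ecm_genes(matrix)
  exi <- .ecm_exon_index(matrix)
  cols <- which(genes == gene)
  if (length(cols) < 3L) stop("gene ", gene, " has under 3 exons")
  cols <- cols[order(exi[cols])]
  med <- apply(vals[, cols, drop = FALSE], 2, stats::median)
  fold <- vals[sample, cols] / med
  elevated <- fold >= cfg$gain_ratio
  runs <- rle(elevated)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= cfg$min_dup_run)
  if (length(ok) == 0L) return(NULL)
  best <- ok[[which.max(runs$lengths[ok])]]
  idx <- starts[[best]]:ends[[best]]
  list(
    first_exon = exi[cols][idx[[1]]],
    last_exon = exi[cols][idx[[length(idx)]]],
    mean_fold = mean(fold[idx])
  )
}

#' Female-to-male ratio of mean normalised counts for a gene
#'
#' For an X-linked gene with sex-appropriate copy number, females
#' (two copies) are expected to show about twice the normalised read
#' count of males (one copy); autosomal genes sit near 1.
#'
#' @param matrix `exon_count_matrix` or bare matrix.
#' @param sex Named character vector (`"F"`/`"M"`) covering the
#'   matrix's samples.
#' @param gene Gene name.
#' @return Numeric ratio (mean over female samples / mean over male
#'   samples of the gene's mean normalised count).
#' @export
sex_linked_ratio <- function(matrix, sex, gene) {
  vals <- .ecm_values(matrix)
  genes <- .ecm_genes(matrix)
  gm <- rowMeans(vals[, genes == gene, drop = FALSE])
  sx <- sex[rownames(vals)]
  if (!any(sx == "F") || !any(sx == "M")) {
    stop("need at least one sample of each sex")
  }
  mean(gm[sx == "F"]) / mean(gm[sx == "M"])
}

#' Allelic-imbalance verdicts at heterozygous SNPs
#'
#' Verifies a suspected copy loss from allele-specific read counts at
#' SNPs inside the locus.  A SNP is informative when the comparator
#' (remission/normal) minor-allele fraction lies within the
#' heterozygosity band; an informative SNP is imbalanced when the
#' tumour minor-allele fraction drops by at least
#' `cfg$imbalance_delta` and a two-sided exact test on the 2x2
#' allele-count table rejects at `cfg$alpha`.  The locus verdict is
#' `deletion-consistent` when at least two informative SNPs are
#' imbalanced, each showing preferential reduction of one of its
#' alleles; `suggestive` with exactly one; otherwise `no-evidence`.
#'
#' @param snps data.frame with columns `snp`, `tumour_a`, `tumour_b`,
#'   `control_a`, `control_b` (read counts for the two alleles).
#' @param cfg A [cnv_config()].
#' @return List with `per_snp` (data.frame: `snp`, `informative`,
#'   `imbalanced`, `direction`, `p_value`, fractions) and `verdict`.
#' @export
allelic_imbalance <- function(snps, cfg = cnv_config()) {
  n <- nrow(snps)
  informative <- logical(n)
  imbalanced <- logical(n)
  direction <- rep(NA_character_, n)
  pval <- rep(NA_real_, n)
  ctrl_minor <- numeric(n)
  tum_minor <- numeric(n)
  for (i in seq_len(n)) {
    ca <- snps$control_a[[i]]; cb <- snps$control_b[[i]]
    ta <- snps$tumour_a[[i]]; tb <- snps$tumour_b[[i]]
    cfrac_a <- ca / (ca + cb)
    minor_is_a <- cfrac_a <= 0.5
    ctrl_minor[[i]] <- min(cfrac_a, 1 - cfrac_a)
    informative[[i]] <- ctrl_minor[[i]] >= cfg$het_band[[1]] &&
      ctrl_minor[[i]] <= cfg$het_band[[2]]
    tfrac_a <- ta / (ta + tb)
    tum_minor[[i]] <- if (minor_is_a) tfrac_a else 1 - tfrac_a
    if (!informative[[i]]) next
    # shift of the allele-A fraction; either allele may be the lost one
    shift <- abs(tfrac_a - cfrac_a)
    tab <- matrix(c(ta, tb, ca, cb), nrow = 2)
    pval[[i]] <- stats::fisher.test(tab)$p.value
    if (shift >= cfg$imbalance_delta && pval[[i]] < cfg$alpha) {
      imbalanced[[i]] <- TRUE
      direction[[i]] <- if (tfrac_a < cfrac_a) "loss-of-A" else "loss-of-B"
    }
  }
  n_imb <- sum(imbalanced)
  verdict <- if (n_imb >= 2L) {
    "deletion-consistent"
  } else if (n_imb == 1L) {
    "suggestive"
  } else {
    "no-evidence"
  }
  list(
    per_snp = data.frame(
      snp = snps$snp, informative = informative, imbalanced = imbalanced,
      direction = direction, p_value = pval,
      control_minor_fraction = ctrl_minor, tumour_minor_fraction = tum_minor,
      stringsAsFactors = FALSE
    ),
    verdict = verdict
  )
}

#' Target coverage summary
#'
#' Fraction of target bases covered at or above each depth threshold,
#' plus the mean depth over the target; bases absent from the depth
#' table count as 0.
#'
#' @param depth data.frame `chrom`, `pos` (1-based), `depth` for one
#'   sample.
#' @param targets Target table ([read_targets()] or amalgamated
#'   exons).
#' @param thresholds Integer vector of depth cutoffs.
#' @return List with `fractions` (named by threshold) and
#'   `mean_depth`.
#' @export
coverage_summary <- function(depth, targets, thresholds = c(1, 10, 100, 1000)) {
  key <- paste0(depth$chrom, ":", depth$pos)
  depth_at <- stats::setNames(depth$depth, key)
  all_d <- numeric(0)
  for (j in seq_len(nrow(targets))) {
    posns <- (targets$start[[j]] + 1L):targets$end[[j]]
    k <- paste0(targets$chrom[[j]], ":", posns)
    dv <- depth_at[k]
    dv[is.na(dv)] <- 0
    all_d <- c(all_d, unname(dv))
  }
  fr <- vapply(thresholds, function(t) mean(all_d >= t), numeric(1))
  list(
    fractions = stats::setNames(fr, as.character(thresholds)),
    mean_depth = mean(all_d)
  )
}
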