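#' Validated pipeline configuration
#'
#' Assembles and validates the configuration of a full analysis run.
#' Unknown keys are rejected.  `caller` / `cnv` entries override
#' individual [caller_config()] / [cnv_config()] defaults.
#'
#' @param tumour_pileups Named character vector of tumour pileup
#'   paths (names are sample ids).
#' @param control_pileup Path to the control pileup (a matched normal
#'   or a designated unrelated remission sample).
#' @param targets_bed Path to the panel BED file.
#' @param counts_tsv Optional path to a normalised count-matrix TSV
#'   (samples x exons) for the copy-number stage.
#' @param sample_sheet Optional path to a sample sheet TSV with
#'   columns `id`, `sex`, `role`, `total_mapped_reads`.
#' @param mrd_pileups Optional named vector of remission pileups to
#'   mine for the diagnostic calls of the corresponding tumour
#'   (names pair remission sample id to tumour id as
#'   `"remission=tumour"` value order: names are remission ids,
#'   values are paths; `mrd_of` maps remission id -> tumour id).
#' @param mrd_of Named character vector mapping remission sample id
#'   to the tumour sample whose calls should be mined.
#' @param x_genes Genes excluded from gene-level CNV flags (sex-
#'   driven dosage; see [flag_cnv_genes()]).
#' @param out_dir Output directory.
#' @param caller,cnv Named lists of threshold overrides.
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(tumour_pileups, control_pileup, targets_bed,
                       counts_tsv = NULL, sample_sheet = NULL,
                       mrd_pileups = NULL, mrd_of = NULL,
                       x_genes = character(0),
                       out_dir = ".", caller = list(), cnv = list(),
                       seed = 1L) {
  if (missing(control_pileup) || is.null(control_pileup)) {
    stop("no control sample designated; pass 'control_pileup' ",
         "(a matched normal, or an unrelated remission sample)")
  }
  if (!is.list(caller)) stop("'caller' must be a list of overrides")
  if (!is.list(cnv)) stop("'cnv' must be a list of overrides")
  bad <- setdiff(names(caller), names(formals(caller_config)))
  if (length(bad)) stop("unknown caller config key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(cnv), names(formals(cnv_config)))
  if (length(bad)) stop("unknown cnv config key(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      tumour_pileups = tumour_pileups, control_pileup = control_pileup,
      targets_bed = targets_bed, counts_tsv = counts_tsv,
      sample_sheet = sample_sheet, mrd_pileups = mrd_pileups,
      mrd_of = mrd_of, x_genes = x_genes, out_dir = out_dir,
      caller = do.call(caller_config, caller),
      cnv = do.call(cnv_config, cnv),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

# Stable hash of the configuration: canonical deparse written to a
# temp file, md5-summed.
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- config[setdiff(names(config), "out_dir")]
  writeLines(deparse(flat, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a normalised count-matrix TSV
#'
#' First column `sample`, remaining columns named `gene:exon_index`.
#'
#' @param path TSV path.
#' @return Numeric matrix, samples in rows.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a normalised count-matrix TSV
#'
#' @param matrix `exon_count_matrix` or bare samples x exons matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  vals <- .ecm_values(matrix)
  d <- data.frame(sample = rownames(vals), vals, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full panel analysis pipeline
#'
#' Somatic calling for every tumour against the designated control,
#' VCF output, optional residual-disease mining, optional copy-number
#' analysis of a count matrix (sample QC, per-exon CV, Tukey flags,
#' gene flags, duplication segments), per-sample coverage summaries,
#' and a run manifest recording the configuration hash and seed.
#' Deterministic stages are bit-identical across reruns with the same
#' inputs.
#'
#' @param config A [run_config()].
#' @return List with `calls`, `vcf`, `mrd`, `cnv`, `coverage`,
#'   `manifest` (invisibly also written under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("'config' must come from run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  targets <- read_targets(config$targets_bed)
  if (nrow(targets) == 0L) stop("target BED is empty")
  control <- read_pileup(config$control_pileup)

  calls <- .empty_calls()
  coverage <- list()
  for (s in names(config$tumour_pileups)) {
    tum <- read_pileup(config$tumour_pileups[[s]])
    calls <- rbind(calls, call_sample(tum, control, targets,
                                      cfg = config$caller, sample_id = s))
    depth_tab <- data.frame(
      chrom = vapply(tum, function(x) x$chrom, character(1)),
      pos = vapply(tum, function(x) x$pos, integer(1)),
      depth = vapply(tum, function(x) nrow(x$reads), integer(1)),
      stringsAsFactors = FALSE
    )
    coverage[[s]] <- coverage_summary(depth_tab, targets)
  }
  calls <- calls[order(calls$chrom, calls$pos, calls$sample_id), , drop = FALSE]
  rownames(calls) <- NULL
  vcf_path <- file.path(config$out_dir, "calls.vcf")
  write_vcf(calls, vcf_path)

  mrd <- NULL
  if (!is.null(config$mrd_pileups)) {
    mrd_rows <- list()
    for (r in names(config$mrd_pileups)) {
      tum_id <- config$mrd_of[[r]]
      qry <- calls[calls$sample_id == tum_id, , drop = FALSE]
      if (nrow(qry) == 0L) next
      res <- mine_known_variants(config$mrd_pileups[[r]], qry, config$caller)
      res$remission_sample <- r
      res$diagnostic_sample <- tum_id
      mrd_rows[[r]] <- res
    }
    if (length(mrd_rows)) {
      mrd <- do.call(rbind, mrd_rows)
      rownames(mrd) <- NULL
      utils::write.table(mrd, file.path(config$out_dir, "mrd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  cnv <- NULL
  if (!is.null(config$counts_tsv)) {
    m <- read_count_matrix(config$counts_tsv)
    qc <- qc_samples(m, config$cnv)
    kept <- m[qc$retained, , drop = FALSE]
    cvs <- exon_cv(kept)
    flagged <- tukey_outlier_exons(cvs)
    gene_flags <- flag_cnv_genes(flagged, kept, config$cnv,
                                 exclude = config$x_genes)
    segments <- list()
    gains <- gene_flags[gene_flags$direction == "gain", , drop = FALSE]
    for (i in seq_len(nrow(gains))) {
      seg <- detect_duplication_segment(kept, gains$gene[[i]],
                                        gains$sample[[i]], config$cnv)
      if (!is.null(seg)) {
        segments[[length(segments) + 1L]] <- data.frame(
          gene = gains$gene[[i]], sample = gains$sample[[i]],
          first_exon = seg$first_exon, last_exon = seg$last_exon,
          mean_fold = seg$mean_fold, stringsAsFactors = FALSE
        )
      }
    }
    cnv <- list(
      qc = qc, cv = cvs, flagged_exons = flagged, genes = gene_flags,
      segments = if (length(segments)) do.call(rbind, segments) else NULL
    )
    utils::write.table(gene_flags, file.path(config$out_dir, "cnv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cov_tab <- do.call(rbind, lapply(names(coverage), function(s) {
    data.frame(sample = s,
               threshold = names(coverage[[s]]$fractions),
               fraction = unname(coverage[[s]]$fractions),
               mean_depth = coverage[[s]]$mean_depth,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(cov_tab, file.path(config$out_dir, "coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- c(
    package = "panelcall",
    version = as.character(utils::packageVersion("panelcall")),
    config_hash = .config_hash(config),
    seed = as.character(config$seed),
    n_calls = as.character(nrow(calls)),
    n_tumours = as.character(length(config$tumour_pileups))
  )
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(config$out_dir, "manifest.tsv"))

  invisible(list(calls = calls, vcf = vcf_path, mrd = mrd, cnv = cnv,
                 coverage = cov_tab, manifest = manifest))
}
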