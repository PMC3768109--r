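#' Caller configuration
#'
#' Thresholds for the tumour/control somatic caller.  Defaults encode
#' a deep-coverage targeted panel: reads enter the evidence only above
#' base quality 25 and mapping quality 15 (strict), sites need
#' filtered coverage of at least 10 in both samples, a substitution
#' needs at least 20 tumour reads on the best non-reference allele
#' with under 5% of control reads on the same allele, and a site is
#' discarded when a second non-reference allele carries at least one
#' third of the best allele's evidence (a signature of misalignment).
#' Indels need at least 10 tumour reads for one exact indel, fewer
#' than 5 control reads for it, at least 10 times more tumour than
#' control reads, and no second indel above 40% of the best indel's
#' evidence.  Calls above 20% variant allele fraction are labelled
#' `dominant`, the rest `subclonal`.  Control tolerances are
#' adjustable, e.g. to use a remission sample (which may carry
#' residual mutant reads) as the control.
#'
#' @param min_base_quality,min_mapping_quality Per-read Phred
#'   thresholds (strict `>`).
#' @param min_coverage_both Minimum filtered depth required in both
#'   samples.
#' @param min_alt_reads_sub Minimum tumour reads on the best
#'   non-reference allele.
#' @param max_control_alt_fraction Maximum control fraction of the
#'   candidate allele (strict `<`).
#' @param third_allele_fraction Discard when the second-best
#'   non-reference allele reaches this fraction of the best
#'   (inclusive `>=`).
#' @param min_indel_reads_tumour Minimum tumour reads for one exact
#'   indel.
#' @param max_indel_reads_control Control reads for the same indel
#'   must be strictly below this.
#' @param min_indel_ratio Tumour indel reads must be at least this
#'   multiple of control indel reads (a clean control passes).
#' @param second_indel_fraction Discard when a second indel exceeds
#'   this fraction of the best indel (strict `>`).
#' @param dominant_vaf Variant allele fraction above which (strict
#'   `>`) a call is labelled dominant-clone.
#' @param mrd_min_reads,mrd_sensitivity Detection floor (reads) and
#'   minimum mutant fraction for residual-disease read mining.
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_base_quality = 25L,
                          min_mapping_quality = 15L,
                          min_coverage_both = 10L,
                          min_alt_reads_sub = 20L,
                          max_control_alt_fraction = 0.05,
                          third_allele_fraction = 1 / 3,
                          min_indel_reads_tumour = 10L,
                          max_indel_reads_control = 5L,
                          min_indel_ratio = 10,
                          second_indel_fraction = 0.40,
                          dominant_vaf = 0.20,
                          mrd_min_reads = 5L,
                          mrd_sensitivity = 0.001) {
  cfg <- list(
    min_base_quality = as.integer(min_base_quality),
    min_mapping_quality = as.integer(min_mapping_quality),
    min_coverage_both = as.integer(min_coverage_both),
    min_alt_reads_sub = as.integer(min_alt_reads_sub),
    max_control_alt_fraction = max_control_alt_fraction,
    third_allele_fraction = third_allele_fraction,
    min_indel_reads_tumour = as.integer(min_indel_reads_tumour),
    max_indel_reads_control = as.integer(max_indel_reads_control),
    min_indel_ratio = min_indel_ratio,
    second_indel_fraction = second_indel_fraction,
    dominant_vaf = dominant_vaf,
    mrd_min_reads = as.integer(mrd_min_reads),
    mrd_sensitivity = mrd_sensitivity
  )
  counts <- cfg[c("min_base_quality", "min_mapping_quality", "min_coverage_both",
                  "min_alt_reads_sub", "min_indel_reads_tumour",
                  "max_indel_reads_control", "mrd_min_reads")]
  if (any(unlist(counts) < 0L)) stop("count thresholds must be >= 0")
  fracs <- unlist(cfg[c("max_control_alt_fraction", "third_allele_fraction",
                        "second_indel_fraction", "dominant_vaf",
                        "mrd_sensitivity")])
  if (any(fracs < 0 | fracs > 1)) stop("fraction thresholds must lie in [0, 1]")
  structure(cfg, class = "caller_config")
}

# Empty call table with the full column contract.
.empty_calls <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), type = character(0),
    tumour_alt_reads = integer(0), tumour_depth = integer(0),
    control_alt_reads = integer(0), control_depth = integer(0),
    vaf = numeric(0), clonality = character(0), region = character(0),
    sample_id = character(0), stringsAsFactors = FALSE
  )
}

.check_same_site <- function(tumour, control) {
  if (!identical(tumour$chrom, control$chrom) || tumour$pos != control$pos) {
    stop("tumour and control evidence refer to different sites (",
         tumour$chrom, ":", tumour$pos, " vs ",
         control$chrom, ":", control$pos, ")")
  }
}

#' Call a somatic substitution at one site
#'
#' Applies the substitution rules to quality-filtered tumour and
#' control allele evidence at the same position.  Returns `NULL`
#' unless every rule passes; see [caller_config()] for the rules.
#'
#' @param tumour,control `allele_evidence` for the same site.
#' @param cfg A [caller_config()].
#' @param sample_id Sample label carried into the call.
#' @return One-row call data.frame, or `NULL`.
#' @export
call_substitution <- function(tumour, control, cfg = caller_config(),
                              sample_id = NA_character_) {
  .check_same_site(tumour, control)
  if (tumour$depth_filtered < cfg$min_coverage_both ||
      control$depth_filtered < cfg$min_coverage_both) {
    return(NULL)
  }
  bc <- tumour$base_counts
  nonref <- bc[names(bc) != tumour$ref & names(bc) != "N"]
  if (length(nonref) == 0L) return(NULL)
  nonref <- sort(nonref, decreasing = TRUE)
  best <- nonref[[1]]
  alt <- names(nonref)[[1]]
  if (best < cfg$min_alt_reads_sub) return(NULL)
  if (length(nonref) >= 2L &&
      nonref[[2]] >= best * cfg$third_allele_fraction) {
    return(NULL)   # likely misaligned region: a third allele shares the evidence
  }
  ctrl_alt <- if (alt %in% names(control$base_counts)) {
    control$base_counts[[alt]]
  } else {
    0L
  }
  if (ctrl_alt / control$depth_filtered >= cfg$max_control_alt_fraction) {
    return(NULL)
  }
  vaf <- best / tumour$depth_filtered
  data.frame(
    chrom = tumour$chrom, pos = tumour$pos, ref = tumour$ref, alt = alt,
    type = "substitution",
    tumour_alt_reads = best, tumour_depth = tumour$depth_filtered,
    control_alt_reads = ctrl_alt, control_depth = control$depth_filtered,
    vaf = vaf,
    clonality = if (vaf > cfg$dominant_vaf) "dominant" else "subclonal",
    region = NA_character_, sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Call a somatic indel at one site
#'
#' Applies the indel rules (exact-match indel identity: kind,
#' sequence, anchoring position) to quality-filtered tumour and
#' control evidence; see [caller_config()].
#'
#' @inheritParams call_substitution
#' @return One-row call data.frame, or `NULL`.
#' @export
call_indel <- function(tumour, control, cfg = caller_config(),
                       sample_id = NA_character_) {
  .check_same_site(tumour, control)
  if (tumour$depth_filtered < cfg$min_coverage_both ||
      control$depth_filtered < cfg$min_coverage_both) {
    return(NULL)
  }
  ic <- tumour$indel_counts
  if (length(ic) == 0L) return(NULL)
  ic <- sort(ic, decreasing = TRUE)
  best <- ic[[1]]
  key <- names(ic)[[1]]
  if (best < cfg$min_indel_reads_tumour) return(NULL)
  if (length(ic) >= 2L && ic[[2]] > cfg$second_indel_fraction * best) {
    return(NULL)
  }
  ctrl <- if (key %in% names(control$indel_counts)) {
    control$indel_counts[[key]]
  } else {
    0L
  }
  if (ctrl >= cfg$max_indel_reads_control) return(NULL)
  if (ctrl > 0L && best < cfg$min_indel_ratio * ctrl) return(NULL)
  kind <- sub(":.*$", "", key)
  seq <- sub("^[a-z]+:", "", key)
  vaf <- best / tumour$depth_filtered
  data.frame(
    chrom = tumour$chrom, pos = tumour$pos, ref = tumour$ref, alt = seq,
    type = if (kind == "ins") "insertion" else "deletion",
    tumour_alt_reads = best, tumour_depth = tumour$depth_filtered,
    control_alt_reads = ctrl, control_depth = control$depth_filtered,
    vaf = vaf,
    clonality = if (vaf > cfg$dominant_vaf) "dominant" else "subclonal",
    region = NA_character_, sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Classify a call as dominant-clone or subclonal
#'
#' Dominant if and only if the variant allele fraction strictly
#' exceeds `cfg$dominant_vaf` (default 20% of reads).
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param cfg A [caller_config()].
#' @return `"dominant"` or `"subclonal"`.
#' @export
classify_clonality <- function(vaf, cfg = caller_config()) {
  ifelse(vaf > cfg$dominant_vaf, "dominant", "subclonal")
}

#' Label call positions as exonic or intronic
#'
#' A position is `exonic` when it falls inside any target region of
#' kind `exonic` (BED intervals are 0-based half-open; a 1-based
#' position p is inside \[start, end) iff start < p <= end).
#' Everything else — including captured intronic control stretches —
#' is `intronic`.
#'
#' @param chrom,pos Vectors of call coordinates (1-based positions).
#' @param targets Target table from [read_targets()].
#' @return Character vector, `"exonic"` or `"intronic"`.
#' @export
label_region <- function(chrom, pos, targets) {
  ex <- targets[targets$kind == "exonic", , drop = FALSE]
  vapply(seq_along(pos), function(i) {
    hit <- ex$chrom == chrom[[i]] & ex$start < pos[[i]] & pos[[i]] <= ex$end
    if (any(hit)) "exonic" else "intronic"
  }, character(1))
}

#' Call somatic variants over a tumour/control pileup pair
#'
#' Parses both pileups, intersects them on shared positions, applies
#' the quality filters, and emits the union of substitution and indel
#' calls, each labelled with clonality and region.  Deterministic
#' given its inputs.  When no matched normal exists, designate an
#' unrelated remission sample as the control.
#'
#' @param tumour_pileup,control_pileup Paths to extended pileup files.
#' @param targets Target table from [read_targets()].
#' @param cfg A [caller_config()].
#' @param sample_id Sample label for the emitted calls.
#' @return data.frame of calls sorted by (chrom, pos); zero rows when
#'   nothing passes.
#' @export
call_sample <- function(tumour_pileup, control_pileup, targets,
                        cfg = caller_config(), sample_id = NA_character_) {
  tum <- if (is.list(tumour_pileup) && !inherits(tumour_pileup, "pileup_site")) {
    tumour_pileup
  } else {
    read_pileup(tumour_pileup)
  }
  ctl <- if (is.list(control_pileup) && !inherits(control_pileup, "pileup_site")) {
    control_pileup
  } else {
    read_pileup(control_pileup)
  }
  shared <- intersect(names(tum), names(ctl))
  if (length(shared) == 0L) {
    stop("tumour and control pileups share no positions")
  }
  calls <- vector("list", 2L * length(shared))
  j <- 0L
  for (key in shared) {
    te <- filter_evidence(tum[[key]], cfg$min_base_quality, cfg$min_mapping_quality)
    ce <- filter_evidence(ctl[[key]], cfg$min_base_quality, cfg$min_mapping_quality)
    sub <- call_substitution(te, ce, cfg, sample_id)
    ind <- call_indel(te, ce, cfg, sample_id)
    if (!is.null(sub)) { j <- j + 1L; calls[[j]] <- sub }
    if (!is.null(ind)) { j <- j + 1L; calls[[j]] <- ind }
  }
  if (j == 0L) return(.empty_calls())
  out <- do.call(rbind, calls[seq_len(j)])
  out$region <- label_region(out$chrom, out$pos, targets)
  out <- out[order(out$chrom, out$pos, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine reads supporting known variants in a remission sample
#'
#' Residual-disease read mining: for each query variant, count the
#' quality-filtered reads supporting it and the filtered depth at its
#' position.  A variant is `detected` when the mutant read count
#' reaches the floor (`cfg$mrd_min_reads`) and the mutant fraction
#' reaches the sensitivity bound (`cfg$mrd_sensitivity`, default
#' 0.1%).
#'
#' @param remission_pileup Path to the remission sample's pileup (or
#'   a pre-parsed site list).
#' @param variants data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `type` (`substitution`/`insertion`/`deletion`).
#' @param cfg A [caller_config()].
#' @return data.frame with one row per query variant: mutant and
#'   total read counts, fraction, and `detected`.
#' @export
mine_known_variants <- function(remission_pileup, variants,
                                cfg = caller_config()) {
  sites <- if (is.list(remission_pileup) &&
               !inherits(remission_pileup, "pileup_site")) {
    remission_pileup
  } else {
    read_pileup(remission_pileup)
  }
  n <- nrow(variants)
  mutant <- integer(n)
  total <- integer(n)
  for (i in seq_len(n)) {
    key <- paste0(variants$chrom[[i]], ":", variants$pos[[i]])
    if (!key %in% names(sites)) next
    ev <- filter_evidence(sites[[key]], cfg$min_base_quality, cfg$min_mapping_quality)
    total[[i]] <- ev$depth_filtered
    if (variants$type[[i]] == "substitution") {
      mutant[[i]] <- if (variants$alt[[i]] %in% names(ev$base_counts)) {
        ev$base_counts[[variants$alt[[i]]]]
      } else 0L
    } else {
      kind <- if (variants$type[[i]] == "insertion") "ins" else "del"
      key2 <- paste0(kind, ":", variants$alt[[i]])
      mutant[[i]] <- if (key2 %in% names(ev$indel_counts)) {
        ev$indel_counts[[key2]]
      } else 0L
    }
  }
  fraction <- ifelse(total > 0L, mutant / total, 0)
  data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt, type = variants$type,
    mutant_reads = mutant, total_reads = total, fraction = fraction,
    detected = mutant >= cfg$mrd_min_reads & fraction >= cfg$mrd_sensitivity,
    stringsAsFactors = FALSE
  )
}

#' Write calls to a VCF 4.2 file
#'
#' Indels are left-anchored on the preceding reference base: an
#' insertion of S observed after position p is written POS=p,
#' REF=ref(p), ALT=ref(p)+S; a deletion of S after p is POS=p,
#' REF=ref(p)+S, ALT=ref(p).  INFO carries tumour/control read
#' counts, depths, VAF, clonality and region.
#'
#' @param calls Call data.frame sorted by (chrom, pos).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (chrom, pos) before writing VCF")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelcall",
    '##INFO=<ID=TAR,Number=1,Type=Integer,Description="Tumour alt read count">',
    '##INFO=<ID=TDP,Number=1,Type=Integer,Description="Tumour filtered depth">',
    '##INFO=<ID=CAR,Number=1,Type=Integer,Description="Control alt read count">',
    '##INFO=<ID=CDP,Number=1,Type=Integer,Description="Control filtered depth">',
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Tumour variant allele fraction">',
    '##INFO=<ID=CLON,Number=1,Type=String,Description="Clonality: dominant or subclonal">',
    '##INFO=<ID=REGION,Number=1,Type=String,Description="Region label: exonic or intronic">',
    '##INFO=<ID=SAMPLE,Number=1,Type=String,Description="Tumour sample id">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$type == "substitution") {
      ref <- cl$ref; alt <- cl$alt
    } else if (cl$type == "insertion") {
      ref <- cl$ref; alt <- paste0(cl$ref, cl$alt)
    } else {
      ref <- paste0(cl$ref, cl$alt); alt <- cl$ref
    }
    info <- sprintf(
      "TAR=%d;TDP=%d;CAR=%d;CDP=%d;VAF=%.6g;CLON=%s;REGION=%s;SAMPLE=%s",
      cl$tumour_alt_reads, cl$tumour_depth, cl$control_alt_reads,
      cl$control_depth, cl$vaf, cl$clonality, cl$region, cl$sample_id
    )
    body[[i]] <- paste(cl$chrom, cl$pos, ".", ref, alt, ".", "PASS", info,
                       sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
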