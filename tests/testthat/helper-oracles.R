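# Independent brute-force oracles.  Each re-derives its quantity from
# first principles, without calling the implementation under test.

# Per-read recount of quality-filtered allele evidence.
oracle_recount <- function(site, min_bq, min_mq) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  indels <- list()
  depth <- 0L
  for (i in seq_len(nrow(site$reads))) {
    r <- site$reads[i, ]
    if (!(r$base_quality > min_bq && r$mapping_quality > min_mq)) next
    depth <- depth + 1L
    b <- toupper(r$call)
    if (b %in% c(".", ",")) b <- site$ref_base
    if (b %in% names(counts)) counts[[b]] <- counts[[b]] + 1L
    if (!is.na(r$indel_kind)) {
      k <- paste0(r$indel_kind, ":", r$indel_seq)
      indels[[k]] <- (if (is.null(indels[[k]])) 0L else indels[[k]]) + 1L
    }
  }
  list(depth = depth, base_counts = counts[counts > 0L],
       indel_counts = unlist(indels))
}

# Interval merge to fixpoint by repeated pairwise merging (0-based
# half-open; overlapping or exactly abutting intervals merge).
oracle_merge <- function(start, end) {
  iv <- cbind(start, end)
  repeat {
    merged <- FALSE
    n <- nrow(iv)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        if (iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# Type-7 quantile by the direct order-statistic interpolation formula.
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_tukey_flags <- function(cvs) {
  q1 <- oracle_quantile7(cvs, 0.25)
  q3 <- oracle_quantile7(cvs, 0.75)
  which(cvs > q3 + 1.5 * (q3 - q1))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric
# enumeration (sum of all tables at most as probable as observed).
oracle_fisher_p <- function(ta, tb, ca, cb) {
  m <- ta + ca          # total allele-A reads
  n <- tb + cb          # total allele-B reads
  k <- ta + tb          # tumour reads
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(ta, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent site caller: re-applies every substitution and indel
# rule by looping over raw reads.
oracle_call_site <- function(tum_site, ctl_site, cfg) {
  te <- oracle_recount(tum_site, cfg$min_base_quality, cfg$min_mapping_quality)
  ce <- oracle_recount(ctl_site, cfg$min_base_quality, cfg$min_mapping_quality)
  out <- list(substitution = NULL, indel = NULL)
  if (te$depth < cfg$min_coverage_both || ce$depth < cfg$min_coverage_both) {
    return(out)
  }
  nonref <- te$base_counts[
    !names(te$base_counts) %in% c(tum_site$ref_base, "N")
  ]
  if (length(nonref) > 0L) {
    nonref <- sort(nonref, decreasing = TRUE)
    best <- nonref[[1]]
    ok <- best >= cfg$min_alt_reads_sub
    if (ok && length(nonref) >= 2L &&
        nonref[[2]] >= best * cfg$third_allele_fraction) ok <- FALSE
    if (ok) {
      alt <- names(nonref)[[1]]
      c_alt <- if (alt %in% names(ce$base_counts)) ce$base_counts[[alt]] else 0L
      if (c_alt / ce$depth < cfg$max_control_alt_fraction) {
        out$substitution <- list(alt = alt, count = best,
                                 vaf = best / te$depth)
      }
    }
  }
  ic <- te$indel_counts
  if (!is.null(ic) && length(ic) > 0L) {
    ic <- sort(ic, decreasing = TRUE)
    best <- ic[[1]]
    ok <- best >= cfg$min_indel_reads_tumour
    if (ok && length(ic) >= 2L &&
        ic[[2]] > cfg$second_indel_fraction * best) ok <- FALSE
    if (ok) {
      key <- names(ic)[[1]]
      c_i <- if (!is.null(ce$indel_counts) && key %in% names(ce$indel_counts)) {
        ce$indel_counts[[key]]
      } else 0L
      if (c_i < cfg$max_indel_reads_control &&
          (c_i == 0L || best >= cfg$min_indel_ratio * c_i)) {
        out$indel <- list(key = key, count = best, vaf = best / te$depth)
      }
    }
  }
  out
}

# Canonical form for count vectors: drop zeros, sort by name.
norm_counts <- function(x) {
  x <- x[x > 0]
  as.list(x[order(names(x))])
}

# Random pileup site around given allele structure, for property tests.
random_site <- function(depth, ref = "G", alt_frac = 0, alt = "A",
                        indel_frac = 0, indel_kind = "ins", indel_seq = "AT",
                        bq_range = c(20L, 40L), mq_range = c(10L, 30L)) {
  n_alt <- rbinom(1L, depth, alt_frac)
  n_ind <- rbinom(1L, depth, indel_frac)
  call <- c(rep(alt, n_alt), rep(".", depth - n_alt))
  ikind <- rep(NA_character_, depth)
  iseq <- rep(NA_character_, depth)
  if (n_ind > 0L) {
    at <- sample.int(depth, n_ind)
    ikind[at] <- indel_kind
    iseq[at] <- indel_seq
  }
  structure(
    list(
      chrom = "chr1", pos = 100L, ref_base = ref,
      reads = data.frame(
        call = call, indel_kind = ikind, indel_seq = iseq,
        base_quality = sample(bq_range[1]:bq_range[2], depth, replace = TRUE),
        mapping_quality = sample(mq_range[1]:mq_range[2], depth, replace = TRUE),
        stringsAsFactors = FALSE
      )
    ),
    class = "pileup_site"
  )
}
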