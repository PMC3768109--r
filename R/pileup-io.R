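#' Parse one line of extended pileup text
#'
#' Reads a single record of the 7-column extended pileup dialect
#' (chrom, 1-based position, reference base, depth, read bases,
#' per-read base qualities, per-read mapping qualities) into a
#' `pileup_site` object holding one entry per aligned read.
#'
#' The read-base string follows the standard samtools dialect:
#' `.`/`,` reference match, `ACGTNacgtn` mismatch, `*` deletion
#' placeholder, `^X` read start (the character after `^` encodes the
#' read's mapping quality and is consumed, not counted), `$` read end,
#' and `+N<seq>`/`-N<seq>` an insertion/deletion observed after the
#' preceding read's call, attached to that read.
#'
#' @param line Character scalar, one tab-separated pileup record.
#' @param quality_encoding ASCII offset of the quality characters
#'   (Phred+33 by default).
#' @param line_number Optional line number used in error messages.
#' @return A `pileup_site`: list with `chrom`, `pos`, `ref_base` and a
#'   data frame `reads` with columns `call` (base, `*`), `indel_kind`
#'   (`NA`, `"ins"` or `"del"`), `indel_seq`, `base_quality`,
#'   `mapping_quality`.
#' @examples
#' s <- parse_pileup_line("chr1\t100\tG\t5\t..AA.\tIIIII\t]]]]]")
#' sum(s$reads$call == "A")
#' @export
parse_pileup_line <- function(line, quality_encoding = 33L, line_number = NA_integer_) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  if (length(fields) < 7L) {
    stop("pileup record has ", length(fields), " columns, need 7", where)
  }
  chrom <- fields[[1]]
  pos <- suppressWarnings(as.integer(fields[[2]]))
  ref_base <- toupper(fields[[3]])
  depth <- suppressWarnings(as.integer(fields[[4]]))
  if (is.na(pos) || pos < 1L) stop("bad position '", fields[[2]], "'", where)
  if (is.na(depth) || depth < 0L) stop("bad depth '", fields[[4]], "'", where)

  calls <- .parse_base_string(fields[[5]], where)
  bq <- utf8ToInt(fields[[6]]) - quality_encoding
  mq <- utf8ToInt(fields[[7]]) - quality_encoding

  n <- nrow(calls)
  if (n != depth) {
    stop("depth column says ", depth, " but read-base string encodes ",
         n, " calls", where)
  }
  if (length(bq) != n) {
    stop("base-quality string length ", length(bq),
         " does not match depth ", depth, where)
  }
  if (length(mq) != n) {
    stop("mapping-quality string length ", length(mq),
         " does not match depth ", depth, where)
  }
  if (any(bq < 0L) || any(mq < 0L)) stop("negative quality value", where)

  reads <- data.frame(
    call = calls$call,
    indel_kind = calls$indel_kind,
    indel_seq = calls$indel_seq,
    base_quality = bq,
    mapping_quality = mq,
    stringsAsFactors = FALSE
  )
  structure(
    list(chrom = chrom, pos = pos, ref_base = ref_base, reads = reads),
    class = "pileup_site"
  )
}

# Tokenise a read-base string into one row per read.  Fast path for
# strings free of ^ $ + - markers; otherwise a pointer loop.
.parse_base_string <- function(s, where = "") {
  simple <- c(".", ",", "A", "C", "G", "T", "N", "a", "c", "g", "t", "n", "*")
  if (!grepl("[\\^$+-]", s)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(ch) && !all(ch %in% simple)) {
      bad <- setdiff(unique(ch), simple)
      stop("unknown pileup token '", bad[[1]], "'", where)
    }
    return(data.frame(
      call = ch,
      indel_kind = rep(NA_character_, length(ch)),
      indel_seq = rep(NA_character_, length(ch)),
      stringsAsFactors = FALSE
    ))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n_max <- length(ch)
  call <- character(n_max)
  ikind <- rep(NA_character_, n_max)
  iseq <- rep(NA_character_, n_max)
  k <- 0L   # reads emitted so far
  i <- 1L
  while (i <= n_max) {
    c0 <- ch[[i]]
    if (c0 == "^") {
      if (i + 1L > n_max) stop("dangling '^' at end of read-base string", where)
      i <- i + 2L            # skip the mapping-quality character
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      if (k == 0L) stop("indel token with no anchoring read", where)
      j <- i + 1L
      while (j <= n_max && ch[[j]] >= "0" && ch[[j]] <= "9") j <- j + 1L
      if (j == i + 1L) stop("indel token lacks a length", where)
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n_max) stop("indel sequence truncated", where)
      seq <- toupper(paste(ch[j:(j + len - 1L)], collapse = ""))
      ikind[[k]] <- if (c0 == "+") "ins" else "del"
      iseq[[k]] <- seq
      i <- j + len
    } else if (c0 %in% simple) {
      k <- k + 1L
      call[[k]] <- c0
      i <- i + 1L
    } else {
      stop("unknown pileup token '", c0, "'", where)
    }
  }
  data.frame(
    call = call[seq_len(k)],
    indel_kind = ikind[seq_len(k)],
    indel_seq = iseq[seq_len(k)],
    stringsAsFactors = FALSE
  )
}

#' Serialise a pileup site back to a pileup text line
#'
#' Inverse of [parse_pileup_line()] up to read-start/read-end markers
#' (which carry no evidence): re-parsing the output yields identical
#' allele and indel counts.
#'
#' @param site A `pileup_site`.
#' @param quality_encoding ASCII offset for quality characters.
#' @return Character scalar, one tab-separated pileup record.
#' @export
format_pileup_site <- function(site, quality_encoding = 33L) {
  r <- site$reads
  tok <- r$call
  has_indel <- !is.na(r$indel_kind)
  if (any(has_indel)) {
    sign <- ifelse(r$indel_kind[has_indel] == "ins", "+", "-")
    tok[has_indel] <- paste0(
      tok[has_indel], sign, nchar(r$indel_seq[has_indel]), r$indel_seq[has_indel]
    )
  }
  paste(
    site$chrom, site$pos, site$ref_base, nrow(r),
    paste(tok, collapse = ""),
    intToUtf8(r$base_quality + quality_encoding),
    intToUtf8(r$mapping_quality + quality_encoding),
    sep = "\t"
  )
}

#' Read an extended pileup file
#'
#' @param path Path to a plain-text (optionally gzipped) 7-column
#'   extended pileup file.
#' @param quality_encoding ASCII offset for quality characters.
#' @return List of `pileup_site`, named `"chrom:pos"`.
#' @export
read_pileup <- function(path, quality_encoding = 33L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sites <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    sites[[i]] <- parse_pileup_line(lines[[i]], quality_encoding, line_number = i)
  }
  names(sites) <- vapply(
    sites, function(s) paste0(s$chrom, ":", s$pos), character(1)
  )
  sites
}

#' Quality-filter the reads at a site and tally allele evidence
#'
#' Only reads with base quality strictly greater than
#' `min_base_quality` and mapping quality strictly greater than
#' `min_mapping_quality` contribute.  Indel observations inherit the
#' anchoring read's qualities.  Deletion placeholders (`*`) count
#' toward the filtered depth but never toward a base allele.
#'
#' @param site A `pileup_site`.
#' @param min_base_quality,min_mapping_quality Phred thresholds
#'   (strict `>`).
#' @return An `allele_evidence`: list with `chrom`, `pos`, `ref`,
#'   `depth_filtered`, `base_counts` (named integer vector over
#'   observed bases, uppercased, reference included) and
#'   `indel_counts` (named integer vector, names `"ins:SEQ"` /
#'   `"del:SEQ"`).
#' @export
filter_evidence <- function(site, min_base_quality = 25L, min_mapping_quality = 15L) {
  r <- site$reads
  keep <- r$base_quality > min_base_quality & r$mapping_quality > min_mapping_quality
  r <- r[keep, , drop = FALSE]

  call <- toupper(r$call)
  call[call == "," ] <- "."
  call[call == "."] <- site$ref_base
  is_base <- call %in% c("A", "C", "G", "T", "N")
  base_counts <- if (any(is_base)) {
    tab <- table(call[is_base])
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }

  has_indel <- !is.na(r$indel_kind)
  indel_counts <- if (any(has_indel)) {
    key <- paste0(r$indel_kind[has_indel], ":", r$indel_seq[has_indel])
    tab <- table(key)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }

  structure(
    list(
      chrom = site$chrom, pos = site$pos, ref = site$ref_base,
      depth_filtered = nrow(r),
      base_counts = base_counts,
      indel_counts = indel_counts
    ),
    class = "allele_evidence"
  )
}

#' Read a BED4 file of target regions
#'
#' Intervals are 0-based half-open with the gene name in column 4.  An
#' optional fifth column carries the region kind (`exonic` or
#' `intronic-control`); absent, every region is `exonic`.  Regions are
#' returned sorted by (chrom, start) with `exon_index` assigned in
#' genomic order within each gene.
#'
#' @param path Path to a BED file (plain text, optionally gzipped).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`,
#'   `kind`, `exon_index`.
#' @export
read_targets <- function(path) {
  empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    gene = character(0), kind = character(0), exon_index = integer(0),
    stringsAsFactors = FALSE
  )
  if (length(readLines(path, n = 1L)) == 0L) return(empty)
  cols <- utils::read.table(
    path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", fill = TRUE, quote = ""
  )
  if (nrow(cols) == 0L) return(empty)
  if (ncol(cols) < 4L) stop("BED file needs at least 4 columns")
  out <- data.frame(
    chrom = cols[[1]],
    start = as.integer(cols[[2]]),
    end = as.integer(cols[[3]]),
    gene = cols[[4]],
    kind = if (ncol(cols) >= 5L && any(nzchar(cols[[5]]))) {
      ifelse(nzchar(cols[[5]]), cols[[5]], "exonic")
    } else {
      "exonic"
    },
    stringsAsFactors = FALSE
  )
  bad <- out$start >= out$end
  if (any(bad)) {
    stop("BED interval with start >= end at row ", which(bad)[[1]])
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$exon_index <- stats::ave(
    seq_len(nrow(out)), out$gene, FUN = seq_along
  )
  out
}
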