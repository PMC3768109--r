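cfg <- caller_config()

test_that("substitution calling enforces each evidence rule at its boundary", {
  ctl <- ev(bases = c(G = 5000L))

  # alt-read floor: at least 20 tumour reads
  expect_null(call_substitution(ev(bases = c(G = 4981L, A = 19L)), ctl, cfg))
  on <- call_substitution(ev(bases = c(G = 4980L, A = 20L)), ctl, cfg)
  expect_equal(on$tumour_alt_reads, 20L)

  # coverage floor of 10 applies to both samples, on filtered depth
  expect_null(call_substitution(ev(depth = 9L, bases = c(A = 9L)), ctl, cfg))
  expect_null(call_substitution(ev(bases = c(G = 4950L, A = 50L)),
                                ev(depth = 9L, bases = c(G = 9L)), cfg))
  expect_false(is.null(call_substitution(ev(depth = 10L, bases = c(A = 10L)),
                                         ctl, caller_config(min_alt_reads_sub = 10L))))

  # control tolerance: strictly under 5% of control reads
  t_alt <- ev(bases = c(G = 4900L, A = 100L))
  expect_false(is.null(call_substitution(t_alt, ev(bases = c(G = 4751L, A = 249L)), cfg)))
  expect_null(call_substitution(t_alt, ev(bases = c(G = 4750L, A = 250L)), cfg))

  # third-allele discard is inclusive at one third of the best evidence
  expect_null(call_substitution(ev(bases = c(G = 4960L, A = 30L, T = 10L)), ctl, cfg))
  expect_false(is.null(call_substitution(ev(bases = c(G = 4961L, A = 30L, T = 9L)),
                                         ctl, cfg)))
})

test_that("indel calling enforces each evidence rule at its boundary", {
  ctl <- ev(bases = c(G = 5000L))

  # tumour indel floor of 10 reads
  expect_null(call_indel(ev(bases = c(G = 5000L), indels = c("ins:AT" = 9L)), ctl, cfg))
  on <- call_indel(ev(bases = c(G = 5000L), indels = c("ins:AT" = 10L)), ctl, cfg)
  expect_equal(on$type, "insertion")
  expect_equal(on$alt, "AT")

  # control must carry strictly fewer than 5 reads of the same indel,
  # and the tumour at least 10 times the control count
  tum <- ev(bases = c(G = 5000L), indels = c("ins:AT" = 40L))
  expect_false(is.null(call_indel(tum, ev(bases = c(G = 5000L),
                                          indels = c("ins:AT" = 4L)), cfg)))
  expect_null(call_indel(tum, ev(bases = c(G = 5000L),
                                 indels = c("ins:AT" = 5L)), cfg))
  expect_null(call_indel(ev(bases = c(G = 5000L), indels = c("ins:AT" = 39L)),
                         ev(bases = c(G = 5000L), indels = c("ins:AT" = 4L)), cfg))

  # a different indel in the control does not count against the candidate
  expect_false(is.null(call_indel(tum, ev(bases = c(G = 5000L),
                                          indels = c("del:C" = 50L)), cfg)))

  # second-indel discard is exclusive at 40% of the best evidence
  expect_null(call_indel(ev(bases = c(G = 5000L),
                            indels = c("ins:AT" = 20L, "del:C" = 9L)), ctl, cfg))
  expect_false(is.null(call_indel(ev(bases = c(G = 5000L),
                                     indels = c("ins:AT" = 20L, "del:C" = 8L)),
                                  ctl, cfg)))
})

test_that("clonality splits strictly above 20% of reads", {
  expect_equal(classify_clonality(0.45), "dominant")
  expect_equal(classify_clonality(0.20), "subclonal")
  expect_equal(classify_clonality(0.044), "subclonal")
  ctl <- ev(bases = c(G = 5000L))
  big <- call_substitution(ev(bases = c(G = 2750L, A = 2250L)), ctl, cfg)
  expect_equal(big$vaf, 0.45)
  expect_equal(big$clonality, "dominant")
  edge <- call_substitution(ev(bases = c(G = 4000L, A = 1000L)), ctl, cfg)
  expect_equal(edge$clonality, "subclonal")   # exactly 20% is not dominant
})

test_that("mismatched tumour/control site identity is an error", {
  expect_error(call_substitution(ev(pos = 100L, bases = c(A = 30L)),
                                 ev(pos = 101L, bases = c(G = 30L))),
               "different sites")
})

test_that("region labels follow half-open BED intervals and intronic stretches", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tGENE\texonic",
               "chr1\t300\t400\tGENE\tintronic-control"), bed)
  tg <- read_targets(bed)
  expect_equal(label_region("chr1", 101L, tg), "exonic")   # first covered base
  expect_equal(label_region("chr1", 200L, tg), "exonic")   # last covered base
  expect_equal(label_region("chr1", 201L, tg), "intronic") # half-open end
  expect_equal(label_region("chr1", 100L, tg), "intronic") # before first base
  expect_equal(label_region("chr1", 350L, tg), "intronic") # captured intron
})

test_that("the NF1 intron fixture event is called and labelled intronic", {
  calls <- get_fixture_calls()
  nf1 <- calls[calls$chrom == "NF1", , drop = FALSE]
  expect_equal(nrow(nf1), 1L)
  expect_equal(nf1$region, "intronic")
  expect_equal(nf1$clonality, "dominant")
  expect_equal(nf1$sample_id, "P2")
})

test_that("calling a control against itself yields no calls", {
  f <- get_fixture()
  expect_equal(nrow(call_sample(f$control, f$control, f$targets,
                                sample_id = "self")), 0L)
  # and a tumour against itself, despite carrying real variants
  p3 <- read_pileup(f$fx$pileups[["P3"]])
  expect_equal(nrow(call_sample(p3, p3, f$targets, sample_id = "self")), 0L)
})

test_that("tightening thresholds never adds a call", {
  f <- get_fixture()
  base <- call_sample(f$fx$pileups[["P5"]], f$control, f$targets,
                      cfg = caller_config(), sample_id = "P5")
  stricter <- list(
    caller_config(min_alt_reads_sub = 300L),
    caller_config(max_control_alt_fraction = 0.001),
    caller_config(min_indel_reads_tumour = 5000L),
    caller_config(min_coverage_both = 6000L)
  )
  key <- function(d) paste(d$chrom, d$pos, d$type, d$alt)
  for (cf in stricter) {
    got <- call_sample(f$fx$pileups[["P5"]], f$control, f$targets,
                       cfg = cf, sample_id = "P5")
    expect_true(all(key(got) %in% key(base)))
    expect_lte(nrow(got), nrow(base))
  }
})

test_that("caller agrees with an independent per-read recount on random sites", {
  set.seed(101)
  for (i in 1:100) {
    depth <- sample(8:200, 1)
    tum <- random_site(depth, alt_frac = runif(1, 0, 0.6),
                       indel_frac = runif(1, 0, 0.4),
                       bq_range = c(20L, 40L), mq_range = c(10L, 30L))
    ctl <- random_site(sample(8:200, 1), alt_frac = runif(1, 0, 0.08),
                       indel_frac = runif(1, 0, 0.05),
                       bq_range = c(20L, 40L), mq_range = c(10L, 30L))
    te <- filter_evidence(tum, cfg$min_base_quality, cfg$min_mapping_quality)
    ce <- filter_evidence(ctl, cfg$min_base_quality, cfg$min_mapping_quality)
    want <- oracle_call_site(tum, ctl, cfg)
    got_sub <- call_substitution(te, ce, cfg)
    got_ind <- call_indel(te, ce, cfg)
    if (is.null(want$substitution)) {
      expect_null(got_sub)
    } else {
      expect_equal(got_sub$alt, want$substitution$alt)
      expect_equal(got_sub$tumour_alt_reads, unname(want$substitution$count))
      expect_equal(got_sub$vaf, unname(want$substitution$vaf))
    }
    if (is.null(want$indel)) {
      expect_null(got_ind)
    } else {
      expect_equal(paste0(substr(got_ind$type, 1, 3), ":", got_ind$alt),
                   sub("^insertion", "ins", want$indel$key))
      expect_equal(got_ind$tumour_alt_reads, unname(want$indel$count))
    }
  }
})

test_that("residual-disease mining counts mutant reads at the stated sensitivity", {
  mk_line <- function(n_alt, depth = 5000L) {
    paste("KRAS", 2545, "G", depth,
          paste0(strrep("T", n_alt), strrep(".", depth - n_alt)),
          strrep("D", depth), strrep("]", depth), sep = "\t")
  }
  qry <- data.frame(chrom = "KRAS", pos = 2545L, ref = "G", alt = "T",
                    type = "substitution", stringsAsFactors = FALSE)
  mine1 <- function(n_alt) {
    p <- tempfile(); writeLines(mk_line(n_alt), p)
    mine_known_variants(p, qry)
  }
  r100 <- mine1(100L)
  expect_equal(r100$fraction, 0.02)
  expect_true(r100$detected)
  r0 <- mine1(0L)
  expect_equal(r0$fraction, 0)
  expect_false(r0$detected)
  r5 <- mine1(5L)          # 0.1% of reads, the design sensitivity
  expect_equal(r5$fraction, 0.001)
  expect_true(r5$detected)
  r4 <- mine1(4L)          # below the read floor
  expect_false(r4$detected)
})

test_that("mutant fraction is invariant under duplicating every read", {
  line <- paste("NPM1", 6075, "C", 1000,
                paste0(strrep(".+4TCTG", 20), strrep(".", 980)),
                strrep("D", 1000), strrep("]", 1000), sep = "\t")
  line2 <- paste("NPM1", 6075, "C", 2000,
                 paste0(strrep(".+4TCTG", 40), strrep(".", 1960)),
                 strrep("D", 2000), strrep("]", 2000), sep = "\t")
  qry <- data.frame(chrom = "NPM1", pos = 6075L, ref = "C", alt = "TCTG",
                    type = "insertion", stringsAsFactors = FALSE)
  p1 <- tempfile(); writeLines(line, p1)
  p2 <- tempfile(); writeLines(line2, p2)
  expect_equal(mine_known_variants(p1, qry)$fraction,
               mine_known_variants(p2, qry)$fraction)
})

test_that("VCF output anchors indels and round-trips through a standard reader", {
  calls <- rbind(
    data.frame(chrom = "NPM1", pos = 6075L, ref = "C", alt = "TCTG",
               type = "insertion", tumour_alt_reads = 2250L, tumour_depth = 5000L,
               control_alt_reads = 0L, control_depth = 5000L, vaf = 0.45,
               clonality = "dominant", region = "exonic", sample_id = "P1",
               stringsAsFactors = FALSE),
    data.frame(chrom = "TET2", pos = 6055L, ref = "T", alt = "A",
               type = "substitution", tumour_alt_reads = 2250L, tumour_depth = 5000L,
               control_alt_reads = 0L, control_depth = 5000L, vaf = 0.45,
               clonality = "dominant", region = "exonic", sample_id = "P2",
               stringsAsFactors = FALSE),
    data.frame(chrom = "WT1", pos = 1550L, ref = "A", alt = "CT",
               type = "deletion", tumour_alt_reads = 2250L, tumour_depth = 5000L,
               control_alt_reads = 0L, control_depth = 5000L, vaf = 0.45,
               clonality = "dominant", region = "exonic", sample_id = "P3",
               stringsAsFactors = FALSE)
  )
  out <- tempfile(fileext = ".vcf")
  write_vcf(calls, out)
  lines <- grep("^[^#]", readLines(out), value = TRUE)
  # manual construction of the expected anchored records
  expect_equal(strsplit(lines[[1]], "\t")[[1]][1:5],
               c("NPM1", "6075", ".", "C", "CTCTG"))
  expect_equal(strsplit(lines[[2]], "\t")[[1]][1:5],
               c("TET2", "6055", ".", "T", "A"))
  expect_equal(strsplit(lines[[3]], "\t")[[1]][1:5],
               c("WT1", "1550", ".", "ACT", "A"))

  vcf <- VariantAnnotation::readVcf(out)
  expect_equal(nrow(vcf), 3L)
  expect_equal(unlist(VariantAnnotation::info(vcf)$CLON),
               rep("dominant", 3L), ignore_attr = TRUE)

  # empty call set gives a parseable header-only file
  empty <- calls[0, ]
  write_vcf(empty, out)
  expect_equal(length(grep("^[^#]", readLines(out))), 0L)

  # unsorted input is rejected
  expect_error(write_vcf(calls[c(2, 1, 3), ], out), "sorted")
})
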