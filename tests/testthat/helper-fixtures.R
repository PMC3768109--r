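# Shared fixtures, generated once per test session.

.fx_cache <- new.env(parent = emptyenv())

# Deterministic pileup fixture cohort (pileups + BED + truth table).
get_fixture <- function() {
  if (is.null(.fx_cache$fx)) {
    spec <- build_default_spec()
    dir <- file.path(tempdir(), "panelcall-fixture")
    .fx_cache$spec <- spec
    .fx_cache$fx <- generate_pileups(spec, dir, mode = "deterministic")
    .fx_cache$targets <- read_targets(.fx_cache$fx$bed)
    .fx_cache$control <- read_pileup(.fx_cache$fx$pileups[["P1CR"]])
  }
  list(spec = .fx_cache$spec, fx = .fx_cache$fx,
       targets = .fx_cache$targets, control = .fx_cache$control)
}

# Calls over the seven diagnostic tumour samples, computed once.
get_fixture_calls <- function() {
  if (is.null(.fx_cache$calls)) {
    f <- get_fixture()
    tumours <- f$spec$samples$id[f$spec$samples$role == "tumour"]
    .fx_cache$calls <- do.call(rbind, lapply(tumours, function(s) {
      call_sample(f$fx$pileups[[s]], f$control, f$targets, sample_id = s)
    }))
  }
  .fx_cache$calls
}

# Hand-built allele evidence for boundary tests.
ev <- function(ref = "G", depth = 5000L, bases = c(), indels = c(),
               chrom = "chr1", pos = 100L) {
  structure(
    list(chrom = chrom, pos = pos, ref = ref,
         depth_filtered = as.integer(depth),
         base_counts = if (length(bases)) {
           stats::setNames(as.integer(bases), names(bases))
         } else stats::setNames(integer(0), character(0)),
         indel_counts = if (length(indels)) {
           stats::setNames(as.integer(indels), names(indels))
         } else stats::setNames(integer(0), character(0))),
    class = "allele_evidence"
  )
}
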