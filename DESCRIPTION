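Package: panelcall
Title: Somatic Variant Calling and Copy-Number Detection for Targeted
    Deep-Sequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tumour-versus-control somatic substitution and indel calling
    from extended pileup files with strict read-quality and evidence
    thresholds, dominant-clone versus subclone classification by variant
    allele fraction, minimal-residual-disease read mining in remission
    samples, and read-depth copy-number detection on targeted capture
    panels (normalised per-exon counts, coefficient-of-variability
    screening with Tukey fences, duplication-segment detection,
    sex-linked ratio validation and allelic-imbalance verification at
    heterozygous SNPs). Includes a deterministic and seeded-stochastic
    fixture generator emulating a 34-gene acute myeloid leukaemia panel
    sequenced to ~5000x.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
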