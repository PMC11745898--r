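Package: svcr
Title: Scalable Variant Call Representation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Scalable Variant Call Representation (SVCR), a
    multi-sample generalization of the GVCF that stores homozygous-reference
    calls as run-length encoded reference blocks and expresses per-sample
    allele-indexed fields (genotype, allele depths, genotype likelihoods)
    over local allele indices.  Supports lossless import and export of
    single-sample GVCFs, incremental N+K combining of datasets with global
    allele unification, bounding of reference-block length by size-threshold
    or fixed-period splitting, densification back to conventional dense
    project-level records, serialization as SVCR-VCF, and a synthetic-cohort
    generator used to verify that stored record counts scale linearly in the
    number of samples while dense representations grow super-linearly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    IRanges,
    S4Vectors,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
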