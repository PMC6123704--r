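Package: metadyn
Title: Dynamic Metabolome Drug Profiling from Flow-Injection Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for high-throughput dynamic metabolome drug
    profiling of adherent mammalian cell lines measured by flow-injection
    time-of-flight mass spectrometry (FIA-TOFMS). Annotates ions by accurate
    mass against a metabolite library (deprotonation in negative mode,
    phenylhydrazone derivatives of alpha-keto acids), estimates per-cell
    metabolite abundances without internal standards via a shared linear
    intensity model across cell lines, computes time-resolved drug-induced
    log2 fold-changes against the model-predicted unperturbed baseline,
    extracts conserved and cell-line-specific drug fingerprints with
    hypergeometric pathway enrichment, estimates growth rates and GI50
    dose-response parameters from confluence time series, and simulates a
    minimal Michaelis-Menten kinetic model of coenzyme A homeostasis that
    links CoA biosynthesis to dichloroacetate toxicity. Includes a synthetic
    data generator reproducing the assumed statistical structure of every
    pipeline stage for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
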