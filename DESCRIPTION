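Package: quartetbind
Title: Cooperative DNA Binding and K-Domain Conservation of MADS-Domain
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies floral-quartet formation by MIKC-type MADS-domain
    transcription factors. Fits an equilibrium model of cooperative dimer
    binding to two-site DNA probes (EMSA titrations) to estimate the
    cooperativity constant k_coop, fits single-site saturation binding
    curves, scores per-column sequence conservation of K-domains with a
    row-maximum-normalized BLOSUM40 similarity, compares interacting versus
    non-interacting sites with exact or tie-corrected Mann-Whitney U tests,
    computes subfamily amino-acid frequency and hydropathy profiles,
    annotates coiled-coil heptad registers and helical wheels, applies
    in-silico substitution and chimera constructs, scans CArG-box motifs on
    the DNA probes, and generates synthetic EMSA titrations and aligned
    K-domain families for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
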