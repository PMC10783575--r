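Package: ksubinfer
Title: Kinase Substrate Inference from Knockout Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers direct kinase substrates from CRISPR-knockout
    TMT phosphoproteomics experiments. Implements reporter-intensity
    quantification of knockout-versus-control log2 effects, a joint
    significance statistic combining a two-sample t-test with the
    Gaussian upper-tail probability of the globally standardized
    effect, exclusion of phosphosites on proteins with significant
    total-abundance changes, position-specific consensus-motif
    matching and chi-square residue enrichment over centralized
    13-mer sequences, dual-criteria direct-substrate calling, Fisher
    exact term enrichment, and a synthetic TMT experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
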