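Package: ramandec
Title: Band Decomposition and Secondary-Structure Quantification for
    FT-Raman Protein Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of FT-Raman spectra of
    proteins and protein-rich plant material: replicate averaging,
    fluorescence baseline correction, reference-band normalization,
    Savitzky-Golay second derivatives, second-derivative-seeded
    pseudo-Voigt band decomposition by bounded Levenberg-Marquardt
    least squares, and area-based quantification of amide I secondary
    structure fractions, disulfide-bridge conformer fractions
    (gauche-gauche-gauche, trans-gauche-gauche, trans-gauche-trans),
    and aromatic marker indices (tyrosine Fermi doublet ratio,
    tryptophan 760 cm-1 intensity). Includes a seeded synthetic-spectrum
    generator with known component truth for recovery experiments,
    CSV/TSV and JCAMP-DX spectrum readers, and an end-to-end
    pipeline producing JSON/CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
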