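Package: unfoldnmr
Title: Chemical Denaturation and 15N Relaxation Analysis of Protein Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for guanidine-hydrochloride unfolding studies of
    small proteins followed by optical spectroscopy and solution NMR. Fits
    two-state chemical-denaturation curves (CD ellipticity or tryptophan
    fluorescence) to extract the transition midpoint and m-value, extracts
    per-residue 15N R1/R2 rates from single-exponential peak-height decays and
    heteronuclear 1H-15N NOEs with first-order error propagation, performs
    reduced spectral density mapping to J(0), J(omegaN) and J(omegaH),
    estimates rotational correlation times from the cubic equation in the
    J-J regression coefficients, screens conformational exchange via R2*R1 and
    R2/R1, and derives residue-level structural-propensity calls (secondary
    chemical shifts, 3J(HN-Ha) classes, amide temperature coefficients,
    average-area-buried-upon-folding profiles, normalized HSQC intensities and
    sequential NOE connectivities). Seeded synthetic-data generators emulate
    each experiment so the whole pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
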