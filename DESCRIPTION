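Package: regnoise
Title: Expression Noise Floors, FACS Selection, and the Evolution of Gene
    Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for studying gene expression noise and
    the evolution of gene regulation in fluctuating environments. Fits the
    minimal-variance (noise floor) curve relating the variance of
    log-fluorescence to mean expression and derives per-promoter excess
    noise; models FACS sorting as a Gaussian selection function and
    simulates rounds of sort-and-mutate evolution on phenotype-level
    promoter populations; provides the closed-form theory of the fitness
    gain from coupling a promoter to a regulator (coupling strength X,
    expression mismatch Y, regulator correlation R and signal-to-noise S),
    its optima and the total-noise phase diagram; attributes promoter
    excess noise to regulators with a ridge (Gaussian-prior) linear model
    with cross-validated prior strength; and reproduces the descriptive
    associations between excess noise, expression plasticity and number of
    regulatory inputs. A synthetic-data module generates every input the
    analyses need, with ground truth, so the pipeline is testable end to
    end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
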