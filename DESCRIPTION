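Package: tetradrive
Title: Simulation and Inference for Spore-Killer Meiotic Drive in Ordered Tetrads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic model of fungal spore killers (Spok-type toxin-antitoxin
    meiotic drive elements) in Podospora anserina and relatives. Simulates
    meiosis in ordered asci with first- and second-division segregation,
    packages nuclei into binucleate tetrads or uninucleate octads, applies a
    distorter/responder spore-killing rule with resistance epistasis and
    trans-activated responders, and classifies asci by surviving-spore count
    and pigmentation. Provides an exact enumeration oracle for ascus-class
    distributions, estimators of second-division segregation frequency with
    exact confidence intervals, a marker transmission-bias scan for locating
    drive loci, a recurrent-backcross introgression simulator, a library of
    reference strains and crosses, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
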