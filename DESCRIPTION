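Package: xyloflux
Title: Kinetic Modeling of Escherichia coli Central Carbon Metabolism on
    Glucose/Xylose Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A kinetic ordinary-differential-equation model of Escherichia
    coli central carbon metabolism (glycolysis, pentose phosphate pathway,
    TCA cycle, anaplerosis, fermentative and respiratory reactions, and the
    xylose assimilation pathway) with enzyme-level and transcription-factor
    regulation (cAMP-Crp, Cra, ArcA, XylR), carbon catabolite repression and
    inducer exclusion through the phosphotransferase system. Growth is
    coupled to the specific ATP production rate. Supports aerobic and
    anaerobic batch and chemostat cultures, gene knockouts (pgi, ptsG, pfl,
    ackA, ...), transcription-factor overexpression, and a heterologous
    mevalonate pathway. Provides NADPH availability and productivity
    accounting for batch cultures and xylose-content design scans for
    NADPH- and mevalonate-overproducing strains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
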