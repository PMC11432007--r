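Package: ecdprofiler
Title: Sequence and Structure Profiling of Cys-Loop Receptor Extracellular
    Domain Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular-domain (ECD) fragments of
    pentameric ligand-gated ion channel subunits, built around the GABA-A
    receptor alpha1/beta2/gamma2 fragments. Provides conserved aromatic motif
    detection (WxD, WxPD, GYD), Cys-loop location and two-domain splits,
    percent-identity matrices from global pairwise alignment, Kyte-Doolittle
    hydropathy profiling, ring-centroid pseudo-atom geometry for Trp-Trp
    pi-stacking and Cys-loop/Tyr S-pi contacts, interface hydrogen-bond
    detection, per-structure distance tables with mean/SEM/max/min
    aggregation, a reduced Kabsch-Sander secondary-structure assigner,
    alignment-guided Kabsch superposition, Gaussian density-map synthesis for
    model-versus-EM shape comparison, and seeded synthetic sequence and
    pentamer generators with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
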