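Package: ktrabtools
Title: Analysis Toolkit for KtrAB Channel Allostery Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated, desk-scale analysis pipeline for studies of
    allosteric gating in the bacterial potassium channel KtrAB and similar
    RCK-regulated systems. Implements molecular-dynamics trajectory
    observables for intrinsically disordered terminal regions (fraction of
    native contacts with logistic smoothing, residue-lipid contact counts,
    membrane z-distance distributions, end-to-end terminus length), a
    simplified inscribed-sphere pore-radius profiler for channel
    constrictions, second-moment shape classification of negative-stain 2D
    class averages (oval versus square ring conformations), biophysical
    curve fitting (differential scanning fluorimetry melting temperatures,
    one-site isothermal titration calorimetry isotherms, Michaelis-Menten
    uptake kinetics), and forward simulation plus non-negative Tikhonov
    inversion of DEER dipolar traces with L-curve regularization selection.
    A synthetic-data module generates every input the pipeline consumes so
    all stages run and verify without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    EBImage,
    pracma,
    signal,
    minpack.lm,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
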