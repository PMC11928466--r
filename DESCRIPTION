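Package: gwcm
Title: Genocchi Wavelet Collocation for Fractional-Order SIR Epidemic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Solves the fractional-order SIR epidemic model under the Caputo
    derivative with a Genocchi wavelet collocation method. Constructs the
    Genocchi polynomial wavelet basis and its operational matrix of
    integration in exact rational/radical arithmetic, reduces the nonlinear
    fractional system to algebraic equations at collocation points, and
    solves them by Newton-Raphson. Includes termwise Caputo differentiation
    and Riemann-Liouville integration of power functions, a classical
    fixed-step RK4 reference for the integer-order system, regression
    fixtures, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
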