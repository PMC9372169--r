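Package: isafilter
Title: Deconvolution-Based Inverse Filtering for Infraslow EEG Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Restores infraslow (< 0.1 Hz) activity that AC-coupled EEG
    acquisition systems attenuate through their high-pass input stage.
    The unit impulse response (UIR) of the recording system is
    characterized non-parametrically from a measured step response or a
    square-wave calibration recording (9th-order polynomial fit followed
    by differentiation), and recordings are then deconvolved by the UIR
    with time-domain long division.  Includes a simulated AC-coupled
    recording chain, synthetic test-signal generators (steps, mixed
    sines, a surrogate seizure with DC shift), zero-phase drift
    correction, spectral and Morlet-wavelet validation tools, and
    EDF/plain-text I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
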