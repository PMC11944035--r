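Package: cervdisc
Title: Cervical Intervertebral Disc Mechanics Under Gravitational Unloading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the mechanical response of the cervical intervertebral
    discs (C2-C3 through C7-T1) to gravitational unloading, as experienced in
    microgravity. Implements a triphasic-theory Donnan swelling model that
    links disc height change to fixed charge density dilution and nucleus
    pulposus / annulus fibrosus water content, a piecewise-linear model of the
    cervical ligaments (ALL, PLL, LF), a transparent quasi-static posture
    load estimator, and a reporting stage that contrasts neutral body posture
    on Earth (NBP 1G) with standing and neutral postures in microgravity
    (SM 0G, NBP 0G). Ships reference disc geometry, ligament stiffness tables,
    posture definitions and per-level load/state tables as plain-text
    fixtures, plus synthetic-data generators and parameter-recovery tools for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
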