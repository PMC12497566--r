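Package: momarm
Title: Instantaneous Muscle Moment Arms and Strains of Hip Extensors from 3D Bone Geometry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates instantaneous muscle moment arms and muscle strains of the five
    principal hip extensors (gluteus medius, gluteus minimus, biceps femoris,
    semimembranosus, semitendinosus) from segmented bone surface geometry. The hip
    joint center is approximated by a least-squares sphere fitted to the femoral
    head, each muscle's line of action is the straight segment joining the centroids
    of its origin and insertion attachment sites, and the moment arm is the distance
    from the joint center to the nearest point on that line, optionally projected
    onto the parasagittal flexion-extension plane. Curves are swept over a hip
    extension range with the knee locked at 90 degrees, strains are classified
    against an optimal length-tension band, and lengths and moment arms are
    normalized by body mass^0.33 for cross-specimen comparison. Includes the three
    standard robustness analyses (repeated attachment placement, body-mass
    perturbation, origin shift along the pelvis) and a parametric hindlimb
    generator with exact geometric ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
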