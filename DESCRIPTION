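Package: fdkrecon
Title: Feldkamp-Davis-Kress Cone-Beam CT Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstruction of three-dimensional volumes from circular-orbit
    cone-beam computed tomography projections with the Feldkamp-Davis-Kress
    (FDK) filtered-backprojection algorithm: per-projection cosine weighting,
    FFT-based ramp filtering of detector rows (with Shepp-Logan, Hamming and
    Hann apodization windows), and distance-weighted voxel-driven
    backprojection with bilinear detector interpolation.  Includes an exact
    analytic forward projector for ellipsoid phantoms so every stage of the
    pipeline can be validated without scanner data, readers and writers for a
    portable raw-binary projection/volume format and MetaImage (.mha)
    volumes, and a command-line front end covering simulation, reconstruction
    and volume comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
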