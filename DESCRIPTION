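Package: isoflight
Title: Light-Level Geolocation and Feather-Isotope Assignment of Oceanic
    Migrants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to infer the non-breeding distribution of pelagic
    seabirds from archival light-level geolocator (GLS) records and to
    assign individuals to oceanic non-breeding regions from the stable
    isotope composition (d15N, d13C) of their feathers. Implements
    threshold light-level geolocation with dark-period, equinox and
    iterative speed filtering; kernel utilization distributions and
    isopleth centroids; k-medoids clustering of non-breeding centroids
    with silhouette-based selection of the number of clusters; linear
    discriminant classification functions with a 70/30 train/test
    protocol; standard ellipse areas for isotopic niches; and ordinary
    kriging of feather isoscapes with a spherical semivariogram. A
    synthetic-data generator produces tracks, twilight, immersion and
    feather-isotope records with the statistical structure the analysis
    assumes, so the whole chain runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    geosphere,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
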