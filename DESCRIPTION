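Package: foxtrot
Title: Segmentation and Range Dynamics of Foxtrot Migration from GPS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse the annual cycle of birds that alternate quick
    directed migration legs with slow, continuous drift across a dynamic
    over-wintering range ("foxtrot migration"). Raw GPS tracking tables are
    reduced to mean daily positions, each bird-season is segmented into
    quick fall, slow winter (south-westward then north-eastward), and quick
    spring phases by an iterative piecewise-regression breakpoint search on
    latitude, and per-phase distance, duration, speed and direction are
    summarised. Monthly 95% minimum convex polygons quantify the moving
    winter footprint, and mean fractional snow cover inside each footprint
    is contrasted with two counterfactual residency strategies. A seeded
    synthetic generator produces multi-bird annual tracks, monthly snow
    rasters with an advancing and retreating snowline, and a latitudinally
    zoned land-cover raster, so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: geosphere, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), mgcv, jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
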