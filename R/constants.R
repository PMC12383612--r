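# Shared physical constants.

# Mean Earth radius (IUGG R1), km. Used for haversine distances, spherical
# cell areas and the per-degree metre scale in terrain derivation.
EARTH_RADIUS_KM <- 6371.0088

# Metres per degree of a great circle on that sphere (2*pi*R/360), rounded
# to the value conventionally used for 2.5-arc-minute work.
METERS_PER_DEGREE <- 111195
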