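Package: darktaxa
Title: Curation, Validation and Dark-Taxa Estimation for Bulk-Sample COI Metabarcoding
Version: 0.1.0
Authors@R: person("Metabarcoding", "Pipeline Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A post-clustering analysis pipeline for DNA metabarcoding of bulk
    insect samples (e.g. Malaise-trap monitoring networks). Implements
    OTU-table curation (technical-replicate consensus, negative-control read
    subtraction, stop-codon screening under the invertebrate mitochondrial
    code, species-level merging and species-name hygiene), multi-criteria
    species validation against expert lists, checklists and spatial occurrence
    records (buffered convex-hull range checks), sequencing- and
    sampling-effort rarefaction with Michaelis-Menten asymptotics and the
    iChao2 incidence-based richness estimator, estimation of plausible species
    and dark taxa from OTU-per-species ratios, and a laboratory cost/time
    accounting model. Ships a seeded synthetic-data generator so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
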