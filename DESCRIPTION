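Package: cpdsvm
Title: Federated Sparse Support Vector Machines via Cluster Primal-Dual Splitting
Version: 0.1.0
Authors@R:
    person("cpdsvm", "maintainers", email = "cpdsvm@example.org", role = c("aut", "cre"))
Description: Fits soft-margin L1-regularised (sparse) support vector machines
    over decentralised data held by a network of agents, without raw-data
    exchange. Provides the cluster primal-dual splitting (cPDS) solver over a
    Metropolis-weighted communication graph, a centralized dual oracle with
    duality-gap certificates, a FedAvg-style comparator, a Round-Robin
    transmission scheduler with communication-volume accounting, and a seeded
    generator for EHR-like synthetic cohorts used to benchmark accuracy
    against communication rounds, volume and cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
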