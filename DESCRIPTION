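Package: rtswitch
Title: Detection of Replication Timing Switching Domains from
    Early/Late Log2 Ratio Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-condition, replicated
    replication-timing (Repli-chip style) experiments. Simulates
    probe-level log2(early/late) profiles with known injected switching
    domains, normalizes and loess-smooths tracks along chromosomes,
    aggregates signal into fixed 200-Kb windows, tests each window for a
    replication-timing switch with an empirical-null Euclidean distance
    statistic and Storey q-value FDR control, segments per-probe
    differential profiles into switching domains with a permutation-tested
    recursive changepoint splitter, and provides comparative statistics
    (correlation matrices, interval-overlap permutation tests, alignment
    to reference panels) and enrichment statistics (binding-site density
    versus timing, Wilcoxon timing-shift tests, expression-versus-switch
    association).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
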