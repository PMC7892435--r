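Package: founderage
Title: Dating Founder Mutations from Linkage Disequilibrium Decay at
    Flanking Microsatellites
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the age of a founder disease allele, in generations
    and calendar years, from the decay of linkage disequilibrium across
    short tandem repeat (STR) markers flanking the disease locus. Implements
    the Bengtsson-Thomson LD index, the Risch moment estimator
    g = log(delta)/log(1 - theta), a mutation-corrected Markov
    transition-matrix iteration, a composite likelihood of generations to
    the most recent common ancestor from first-discordance positions, and a
    Bayesian posterior over age with a population-growth-informed prior.
    Includes readers and writers for phased STR haplotype panels (wide TSV
    and PED/MAP), demographic and prevalence arithmetic, a forward-in-time
    star-genealogy simulator of founder haplotype decay, and a parameter
    recovery harness. Ships the eight-marker SERPINC1 (antithrombin
    Budapest 3) panel as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
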