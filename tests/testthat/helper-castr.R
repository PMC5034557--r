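# Profile with every indicator measured and exactly (k_social, k_community)
# flags, small fixed seed unless stated.
flagged_profile <- function(k_social, k_community, seed = 42,
                            population = 50000) {
  generate_profile(seed, k_social, k_community, population = population)
}

# One-row definition lookup from the shipped registry.
indicator_defn <- function(id, registry = default_indicators()) {
  registry[registry$id == id, ]
}
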