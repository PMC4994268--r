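## Shared fixtures, computed once per test run. Conformer embedding and
## descriptor computation dominate the suite's runtime, so tests pull them
## from this cache instead of recomputing.

.testCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .testCache)) {
    assign(key, force(expr), envir = .testCache)
  }
  get(key, envir = .testCache)
}

## One minimized conformer per registry compound (seed 1).
registryConformers <- function() {
  cached("registry_conformers", {
    reg <- compoundRegistry()
    setNames(lapply(seq_len(nrow(reg)), function(i)
      embedConformer(reg[i, ], seed = 1L)), reg$id)
  })
}

## Computed descriptor table for the full registry (seed 1, defaults).
computedDescriptors <- function() {
  cached("computed_descriptors", {
    reg <- compoundRegistry()
    do.call(rbind, lapply(seq_len(nrow(reg)), function(i)
      computeDescriptors(reg[i, ], seed = 1L)))
  })
}

## The packaged reference descriptor table (8f's sign slip warns on load).
fixtureTable4 <- function() {
  cached("table4", suppressWarnings(
    loadDescriptorTable(fixturePath("descriptors"), expected_rows = 14L)))
}

fixtureBinding <- function() {
  cached("binding", loadBindingTable(fixturePath("binding")))
}
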