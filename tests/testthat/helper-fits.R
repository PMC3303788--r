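# Shared fitted models (estimation is the expensive step; fit once per
# test session).  Seeds are fixed so the whole suite is deterministic.

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(chain, dependent = FALSE) {
  key <- paste0(chain, if (dependent) "_dep")
  if (is.null(.fit_cache[[key]])) {
    seed <- switch(chain, activator = 11L, repressor = 12L,
                   three_state = 13L)
    .fit_cache[[key]] <- mcm(chain = chain, seed = seed + dependent,
                             dependent = dependent)
  }
  .fit_cache[[key]]
}
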