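# One full-size study simulation (5 groups x 8 animals, 6 therapy weeks)
# shared by the tests that exercise cohort-level behavior; memoized because
# it is the expensive fixture.
.protocol_cache <- new.env(parent = emptyenv())

study_protocol <- function() {
  if (is.null(.protocol_cache$p)) {
    .protocol_cache$p <- simulate_protocol(
      clv_cohort(n_per_group = 8), clv_timeline(), seed = 1729
    )
  }
  .protocol_cache$p
}
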