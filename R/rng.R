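# Seeded package functions must not clobber the caller's RNG stream:
# each one snapshots .Random.seed, seeds its own draws, and restores the
# snapshot on exit. Returns a restore closure for use with on.exit().

preserve_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}
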