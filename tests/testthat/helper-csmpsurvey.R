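# Agreement with a value as printed in the reference tables: round the
# recomputed value to the table's 3-significant-figure convention, then allow
# one unit in the last printed digit (the tables were produced from unrounded
# intermediates, so exact ties are not guaranteed).
agrees_last_digit <- function(x, printed, sig = 3) {
  ulp <- 10^(floor(log10(abs(printed))) - (sig - 1))
  abs(signif(x, sig) - printed) <= ulp * (1 + 1e-9)
}

# canonical ID map between the worn-date particle table and the sized/fraction
# tables, resolved once by activity matching (warns about the known conflicts)
canonical_worn_particles <- function() {
  suppressWarnings(
    match_particle_ids(reference_particles_worn(),
                       reference_particle_fractions())
  )
}
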