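# Worked-example fixtures: peptide SYSDMK with a single phosphorylation,
# candidate sites restricted to the serines (the two sites realized by the
# example isoforms), integer 1-Da ticks so all masses are the printed ones.

phospho_ser <- function() modification("Phospho", 21, "S", 79.96633)

example_pmg <- function() build_pmg("SYSDMK", list(phospho_ser()), scale = 1)

example_precursor <- function() 791 + 18.010565

example_masses <- c(87, 167, 250, 330, 417, 532, 663, 791)
example_intensities <- c(39, 75, 33, 76, 105, 110, 92, 99)

example_smg <- function(masses = example_masses,
                        intensities = example_intensities, delta = 0) {
  build_smg(tibble::tibble(mass = masses, intensity = intensities),
            precursor_mass = example_precursor(), scale = 1, delta = delta)
}

# the variant with the peak at 250 missing
example_smg_missing <- function() {
  drop <- example_masses != 250
  example_smg(example_masses[drop], example_intensities[drop])
}

example_btg <- function(smg = example_smg()) {
  build_backtracking_graph(example_pmg(), smg, delta = 0, max_missing = 2,
                           mod_counts = c(`21` = 1L))
}

# pick the alignment whose first matched peak has the given mass
alignment_starting_at <- function(alignments, mass) {
  hit <- vapply(alignments, function(a) a$nodes$mass[2] == mass, logical(1))
  stopifnot(sum(hit) == 1L)
  alignments[[which(hit)]]
}
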