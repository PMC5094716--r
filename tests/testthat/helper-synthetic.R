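# Shared fixtures: reduced-size receptor templates and generator configs.
# Tests run on scaled-down templates (fewer residues per helix) where the
# geometry, not the receptor size, is under test.

reduced_helix_ranges <- function(n = 4L) {
  lapply(cxcr4_helix_ranges(), function(r) c(r[1], r[1] + n - 1L))
}

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_runs = 2L, run_length = 100, frame_stride = 1,
                   box = c(15, 15, 9), association_rate = 2e-2,
                   dissociation_rate = 0,
                   helix_ranges = reduced_helix_ranges(),
                   cholesterol_fraction = 0, include_lipids = FALSE,
                   hotspot = NULL, seed = 1L)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# minimal hand-built topology: a few free beads of one type, no helices
# involved beyond the mandatory ranges
bead_topology <- function(n, type = "X", charge = 0, species = "protein",
                          C6 = 1, C12 = 1e-3) {
  beads <- data.frame(bead_id = seq_len(n), bead_name = "BB",
                      residue_number = seq_len(n), residue_name = "RES",
                      molecule_id = seq_len(n), species = species,
                      type_key = type, charge = charge,
                      stringsAsFactors = FALSE)
  topology(beads, nonbonded = data.frame(type_i = type, type_j = type,
                                         C6 = C6, C12 = C12))
}
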