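# Small registries and hand-built runs shared across tests.

tiny_materials <- function() {
  reference_materials(data.frame(
    id = c("A", "B", "QC"),
    material_class = c("cellulose", "cellulose", "sugar"),
    d2H = c(-130, -60, -85),
    d13C = c(-28, -22, -25.5),
    d18O = c(22, 32, 34),
    x_e = c(0.2, 0.2, 0.36),
    n_content_pct = 0,
    s_content_pct = 0,
    exchanges_h = TRUE
  ))
}

# A minimal hand-built run: standards A,B in duplicate at both ends, one
# sample in the middle, supplied raw deltas recycled across channels.
manual_run <- function(d2H, d13C = d2H, d18O = d2H,
                       ids = c("A", "A", "B", "B", "S1", "A", "A", "B", "B"),
                       roles = c(rep("standard", 4), "sample",
                                 rep("standard", 4)),
                       reactor = "glassy_carbon",
                       autosampler = "zero_blank",
                       water = "W1") {
  n <- length(ids)
  run_sequence(
    data.frame(position = seq_len(n), material_id = ids, role = roles,
               d2H_raw = rep_len(d2H, n), d13C_raw = rep_len(d13C, n),
               d18O_raw = rep_len(d18O, n), area_H2 = 1, area_CO = 1,
               mass_mg = 1),
    reactor = reactor, equilibration_water_id = water,
    autosampler = autosampler
  )
}

# Registry covering manual_run(): sample S1 is an uncertified cellulose.
manual_materials <- function() {
  reference_materials(data.frame(
    id = c("A", "B", "S1"),
    material_class = "cellulose",
    d2H = c(-130, -60, NA),
    d13C = c(-28, -22, NA),
    d18O = c(22, 32, NA),
    x_e = c(0.2, 0.2, NA),
    n_content_pct = 0, s_content_pct = 0, exchanges_h = TRUE
  ))
}
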