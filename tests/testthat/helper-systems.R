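# Shared fixtures: shipped parameter table and a loam reference texture are
# loaded once; random systems come from random_system() under fixed seeds.
shipped_params <- default_parameter_table()
loam <- default_soil_texture()

ebf_system <- function() transfer_system(shipped_params[["EBF"]], loam)

# tiny deterministic grid used by pipeline tests
small_grid <- function(seed = 101, shape = c(3, 5))
  generate_grid(shape = shape, seed = seed)

# hand-built two-cell grid with constant forcing, for hand-checkable swaps
constant_grid <- function(t1 = 5, t2 = 20, k1 = 0.3, k2 = 0.8,
                          porosity = 0.5, n_days = 10) {
  cells <- data.frame(cell = 1:2, row = c(1, 2), col = c(1, 1),
                      biome = c("GRA", "EBF"),
                      clay = 0.2, silt = 0.4, sand = 0.4,
                      porosity = porosity,
                      npp = c(300, 1300), stringsAsFactors = FALSE)
  structure(list(cells = cells,
                 t_soil = matrix(c(t1, t2), 2, n_days),
                 swc = matrix(c(k1, k2) * porosity, 2, n_days),
                 seed = 0L, shape = c(2L, 1L), n_days = n_days),
            class = "synthetic_grid")
}
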