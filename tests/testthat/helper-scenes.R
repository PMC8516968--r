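# Shared builders for simulated study scenes and small hand-made panels.

# a full simulated scene: geography, climate, populations, altitude, graph
make_scene <- function(n_rows = 5, n_cols = 8, n_districts = 4,
                       n_months = 48, seed = 1) {
  geo <- make_lattice(n_rows, n_cols, n_districts)
  list(geo = geo,
       climate = simulate_climate(geo, n_months, seed = seed),
       pop = simulate_populations(geo, seed = seed + 1),
       alt = simulate_altitude(geo, seed = seed + 2),
       graph = suppressMessages(queen_contiguity(geo)),
       n_months = n_months)
}

# deterministic toy count panel (no RNG): cases follow a fixed pattern
toy_panel <- function(n_area = 2, n_months = 3, base_pop = 100) {
  grid <- expand.grid(sex = c("male", "female"),
                      age_group = c("5to14", "under5"),
                      month_index = seq_len(n_months),
                      area = paste0("a", seq_len(n_area)),
                      stringsAsFactors = FALSE)
  grid$district <- "d1"
  grid$population <- base_pop
  grid$cases <- (seq_len(nrow(grid)) * 7L) %% 5L
  count_panel(grid[, c("area", "district", "month_index", "age_group",
                       "sex", "cases", "population")])
}

# constant climate covering the districts of a panel
flat_climate <- function(districts, n_months, rain = 100, rh = 70,
                         tmin = 5, tmax = 20) {
  climate_panel(expand.grid(district = districts,
                            month_index = seq_len(n_months),
                            rainfall_mm = rain, rh_percent = rh,
                            tmin_c = tmin, tmax_c = tmax,
                            stringsAsFactors = FALSE))
}

quiet_design <- function(...) suppressMessages(assemble_design(...))

# Moore-Penrose pseudo-inverse of a symmetric matrix (spectral form)
pseudo_inverse <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > 1e-9
  V <- e$vectors[, keep, drop = FALSE]
  V %*% diag(1 / e$values[keep], sum(keep)) %*% t(V)
}

quiet_fit <- function(...) {
  suppressWarnings(suppressMessages(fit_zip(...)))
}
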