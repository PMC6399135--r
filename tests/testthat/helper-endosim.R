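# Shared fixtures. Everything is generated in code; no stored data.

tiny_params <- function(...) {
  # small lattice + short window keep reference-path tests fast
  default_parameters(lattice_side = 10L, n_surface_init = 30L,
                     n_ee_init = 20L, S_im = 10L, t_start = -1, t_end = 1,
                     ...)
}

# scripted state: deterministic occupancies on an empty lattice
scripted_state <- function(p, surf_sites = integer(), ee_sites = integer()) {
  st <- endosim:::new_state(p)
  for (s in surf_sites) st$surf[s] <- st$surf[s] + 1L
  for (s in ee_sites) st$ee[s] <- st$ee[s] + 1L
  st
}

expect_conserved <- function(st, p, total) {
  expect_identical(unname(census(st, p)[["total"]]), as.integer(total))
}
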