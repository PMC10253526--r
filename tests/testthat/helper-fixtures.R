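## Shared fixtures: tiny abstract networks and grids built in code.

AVOGADRO <- 6.02214076e23
STANDARD_SPECIES <- unlist(radchemxt::species_categories, use.names = FALSE)

toy_species <- function(names, D = rep(1, length(names))) {
  data.frame(name = names, D = D, category = "other",
             charge = 0, stringsAsFactors = FALSE)
}

toy_reactions <- function(r1, r2, products, k) {
  df <- data.frame(id = paste0("T", seq_along(r1)), r1 = r1, r2 = r2,
                   k = k, stringsAsFactors = FALSE)
  df$products <- products
  df
}

## A + B -> C, k in 1/M/s
net_ab_c <- function(k = 1e10, D = c(A = 1, B = 1, C = 1)) {
  reaction_network(toy_species(c("A", "B", "C"), D[c("A", "B", "C")]),
                   toy_reactions("A", "B", list("C"), k))
}

## A + A -> B with the two-per-event convention
net_aa_b <- function(k = 1e10) {
  reaction_network(toy_species(c("A", "B")),
                   toy_reactions("A", "A", list("B"), k))
}

## A -> B, unimolecular, k in 1/s
net_a_b <- function(k = 1e9) {
  reaction_network(toy_species(c("A", "B")),
                   toy_reactions("A", NA_character_, list("B"), k))
}

## diffusion only: a species with no reactions
net_diffusion_only <- function(species = "A", D = 1) {
  reaction_network(toy_species(species, D),
                   toy_reactions(species[1], species[1],
                                 list(species[1]), 0)[0, ])
}

small_grid <- function(bw = 50, r_max = 400, h = 1000) {
  radial_grid(bw = bw, r_max = r_max, h = h)
}

flat_state <- function(grid, conc, time = 0, flattened = FALSE) {
  species <- names(conc)
  m <- matrix(rep(unlist(conc), each = grid$J), grid$J, length(conc))
  system_state(grid, species, m, time = time,
               flattened = setNames(rep(flattened, length(species)), species))
}

gaussian_state <- function(grid, species = "A", peak = 1e-6, sigma = 100,
                           time = 0) {
  v <- peak * exp(-grid$centers^2 / (2 * sigma^2))
  system_state(grid, species, matrix(v, ncol = 1), time = time)
}

## schedule with a single fixed dt
fixed_schedule <- function(t_in, t_end, dt) {
  data.frame(t_start = t_in, t_end = t_end, dt = dt)
}
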