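#' @useDynLib radchemxt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif rbinom sd rexp setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

## Physical constants and unit conversions. Internal unit system:
## length nm, time ns, concentration mol/L. 1 nm^3 = 1e-24 L, and a
## diffusion coefficient of 1e-9 m^2/s equals 1 nm^2/ns.
.AVOGADRO <- 6.02214076e23
.NM3_PER_L <- 1e24

## Elemental composition (H, O) and charge of every species the default
## network can reference, including continuum O2 and water. Used only by
## the element-balance validator.
.COMPOSITION <- list(
  "OH"   = c(H = 1, O = 1, q = 0),
  "H3O+" = c(H = 3, O = 1, q = 1),
  "H"    = c(H = 1, O = 0, q = 0),
  "eaq-" = c(H = 0, O = 0, q = -1),
  "H2"   = c(H = 2, O = 0, q = 0),
  "H2O2" = c(H = 2, O = 2, q = 0),
  "OH-"  = c(H = 1, O = 1, q = -1),
  "HO2"  = c(H = 1, O = 2, q = 0),
  "O2-"  = c(H = 0, O = 2, q = -1),
  "HO2-" = c(H = 1, O = 2, q = -1),
  "O2"   = c(H = 0, O = 2, q = 0),
  "H2O"  = c(H = 2, O = 1, q = 0)
)

#' Species categories of the standard radiolysis set
#'
#' Category (i) are the direct water-radiolysis radicals, (ii) the
#' intra-track recombination molecules and (iii) the products of
#' reactions with dissolved oxygen.
#'
#' @format Named list of character vectors with elements `i`, `ii`, `iii`.
#' @export
species_categories <- list(
  i   = c("OH", "H3O+", "H", "eaq-"),
  ii  = c("H2", "H2O2", "OH-"),
  iii = c("HO2", "O2-", "HO2-")
)

#' Dissolved oxygen concentration from partial pressure
#'
#' Applies Henry's law: `[O2] = pO2 * K_H` with the oxygen partial
#' pressure expressed as a fraction of 1 atm.
#'
#' @param po2 Oxygen partial pressure as a fraction of 1 atm (0.21 for
#'   air-saturated water).
#' @param henry_constant Henry solubility constant in M/atm. The default
#'   1.3e-3 M/atm corresponds to water at 25 C.
#' @return Molar O2 concentration.
#' @examples
#' o2_concentration_from_po2(0.21) # about 2.73e-4 M
#' @export
o2_concentration_from_po2 <- function(po2, henry_constant = 1.3e-3) {
  if (!is.numeric(po2) || length(po2) != 1L || is.na(po2) || po2 < 0 || po2 > 1)
    stop("`po2` must be a single value in [0, 1]")
  if (!is.numeric(henry_constant) || henry_constant <= 0)
    stop("`henry_constant` must be positive")
  po2 * henry_constant
}

#' Build a reaction network
#'
#' Low-level constructor used by [build_default_network()] and the config
#' loader. Rate constants are given in laboratory units (1/M/s for
#' bimolecular, 1/s for unimolecular) and converted to the internal
#' per-nanosecond system.
#'
#' @param species `data.frame` with columns `name`, `D` (nm^2/ns),
#'   `category` (one of `"i"`, `"ii"`, `"iii"`, `"other"`), `charge`.
#' @param reactions `data.frame` with columns `id`, `r1`, `r2` (`NA` for
#'   unimolecular), a list column `products` (character vectors, up to 3)
#'   and `k` in 1/M/s (or 1/s for unimolecular reactions).
#' @param continuum named numeric vector of continuum solute molarities
#'   (e.g. `c(O2 = 2.7e-4)`). Continuum solutes never evolve as fields.
#' @param henry_M_per_atm Henry constant kept for provenance/re-derivation.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions, continuum = c(O2 = 0),
                             henry_M_per_atm = 1.3e-3) {
  stopifnot(is.data.frame(species), is.data.frame(reactions))
  if (anyDuplicated(species$name))
    stop("species names must be unique within a network")
  known <- c(species$name, names(continuum))
  for (i in seq_len(nrow(reactions))) {
    refs <- c(reactions$r1[i], reactions$r2[i], reactions$products[[i]])
    refs <- refs[!is.na(refs)]
    bad <- setdiff(refs, known)
    if (length(bad))
      stop("reaction ", reactions$id[i], " references unknown species: ",
           paste(bad, collapse = ", "))
    rs <- c(reactions$r1[i], reactions$r2[i])
    if (sum(rs %in% names(continuum), na.rm = TRUE) > 1L)
      stop("reaction ", reactions$id[i], " has more than one continuum reactant")
  }
  structure(
    list(species = species, reactions = reactions,
         continuum = continuum, henry_M_per_atm = henry_M_per_atm),
    class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions\n", sep = "")
  cat("  continuum:",
      paste(sprintf("%s = %.3g M", names(x$continuum), x$continuum),
            collapse = ", "), "\n")
  invisible(x)
}

.read_network_file <- function(path) {
  raw <- jsonlite::read_json(path)
  sp <- do.call(rbind, lapply(raw$species, function(s)
    data.frame(name = s$name, D = s$D_nm2_per_ns,
               category = s$category, charge = s$charge,
               stringsAsFactors = FALSE)))
  rx <- data.frame(
    id = vapply(raw$reactions, function(r) r$id, ""),
    r1 = vapply(raw$reactions, function(r) r$reactants[[1]], ""),
    r2 = vapply(raw$reactions, function(r)
      if (length(r$reactants) > 1L) r$reactants[[2]] else NA_character_, ""),
    k = vapply(raw$reactions, function(r)
      if (!is.null(r$k_per_M_per_s)) r$k_per_M_per_s else r$k_per_s, 0),
    stringsAsFactors = FALSE)
  rx$products <- lapply(raw$reactions, function(r)
    as.character(unlist(r$products)))
  henry <- raw$continuum$O2$henry_M_per_atm
  list(species = sp, reactions = rx, henry = henry)
}

#' Build the default water-radiolysis reaction network
#'
#' Returns the ten-species network (OH, H3O+, H, eaq-, H2, H2O2, OH-,
#' HO2, O2-, HO2-) plus continuum dissolved O2, with standard
#' diffusion-controlled rate constants read from the bundled, editable
#' table `inst/extdata/default_network.json`. The dissolved oxygen
#' concentration is derived from `po2` via Henry's law.
#'
#' Supported overrides (a named list):
#' \describe{
#'   \item{`po2`}{oxygen partial pressure, fraction of 1 atm (default 0).}
#'   \item{`henry_M_per_atm`}{Henry constant (default 1.3e-3).}
#'   \item{`k`}{named list of rate-constant overrides in lab units; keys
#'     are reaction ids (`"R13"`) or reactant signatures (`"eaq-+O2"`).}
#'   \item{`D`}{named list of diffusion-coefficient overrides (nm^2/ns),
#'     keyed by species name.}
#' }
#'
#' @param overrides optional named list as described above.
#' @param file alternative network file in the same JSON dialect.
#' @return A [reaction_network()].
#' @examples
#' net <- build_default_network(list(po2 = 0.21))
#' @export
build_default_network <- function(overrides = NULL, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "default_network.json",
                        package = "radchemxt", mustWork = TRUE)
  tab <- .read_network_file(file)
  po2 <- 0
  henry <- tab$henry
  if (!is.null(overrides)) {
    if (!is.list(overrides))
      stop("`overrides` must be a named list")
    unknown <- setdiff(names(overrides), c("po2", "henry_M_per_atm", "k", "D"))
    if (length(unknown))
      stop("unknown override key(s): ", paste(unknown, collapse = ", "))
    if (!is.null(overrides$po2)) po2 <- overrides$po2
    if (!is.null(overrides$henry_M_per_atm)) henry <- overrides$henry_M_per_atm
    if (!is.null(overrides$k)) {
      sig <- ifelse(is.na(tab$reactions$r2), tab$reactions$r1,
                    paste0(tab$reactions$r1, "+", tab$reactions$r2))
      for (key in names(overrides$k)) {
        hit <- which(tab$reactions$id == key | sig == key)
        if (!length(hit))
          stop("rate override references unknown reaction: ", key)
        tab$reactions$k[hit] <- overrides$k[[key]]
      }
    }
    if (!is.null(overrides$D)) {
      for (key in names(overrides$D)) {
        hit <- which(tab$species$name == key)
        if (!length(hit))
          stop("diffusion override references unknown species: ", key)
        tab$species$D[hit] <- overrides$D[[key]]
      }
    }
  }
  o2 <- o2_concentration_from_po2(po2, henry)
  net <- reaction_network(tab$species, tab$reactions,
                          continuum = c(O2 = o2), henry_M_per_atm = henry)
  net$po2 <- po2
  net
}

#' Validate a reaction network
#'
#' Checks non-negative rate and diffusion constants, unique species
#' names, and elemental H/O plus charge balance of every reaction.
#' Water is implicit in the scheme: a reaction balances if the H and O
#' excesses are consistent with an integer number of implied H2O
#' molecules on either side (e.g. H3O+ + OH- -> 2 H2O).
#'
#' @param net a [reaction_network()].
#' @return Character vector of violations; empty if the network is valid.
#' @export
validate_network <- function(net) {
  out <- character()
  if (anyDuplicated(net$species$name))
    out <- c(out, "duplicate species names")
  bad_d <- net$species$name[net$species$D < 0]
  if (length(bad_d))
    out <- c(out, paste0("negative diffusion coefficient: ",
                         paste(bad_d, collapse = ", ")))
  evolving <- intersect(names(net$continuum), net$species$name)
  if (length(evolving))
    out <- c(out, paste0("continuum solute also defined as evolving species: ",
                         paste(evolving, collapse = ", ")))
  for (i in seq_len(nrow(net$reactions))) {
    rx <- net$reactions[i, ]
    if (rx$k < 0) {
      out <- c(out, paste0(rx$id, ": negative rate constant"))
    }
    members <- list(reactants = c(rx$r1, rx$r2), products = rx$products[[1]])
    comp <- lapply(members, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(H = 0, O = 0, q = 0))
      unknown <- setdiff(v, names(.COMPOSITION))
      if (length(unknown)) return(NULL)
      Reduce(`+`, .COMPOSITION[v])
    })
    ## user-defined species of unknown composition are exempt from the
    ## element check (the bookkeeping only covers the standard table)
    if (any(vapply(comp, is.null, TRUE))) next
    ex <- comp$reactants - comp$products
    m <- ex[["O"]]  # implied waters (reactant side if negative)
    balanced <- abs(ex[["H"]] - 2 * m) < 1e-9 && abs(m - round(m)) < 1e-9
    if (!balanced)
      out <- c(out, paste0(rx$id, ": H/O element balance fails"))
    if (abs(ex[["q"]]) > 1e-9)
      out <- c(out, paste0(rx$id, ": charge balance fails"))
  }
  out
}

## Compiled form of a network used by the bin-wise kinetics: column
## indices into an augmented concentration matrix [species | continuum | 1]
## and the (rate-scaled) stoichiometry matrix, so that
##   d(conc)/dt = (Caug[, i1] * Caug[, i2]) %*% KS
## with KS = k * stoich. Same-species reactions get -2 in stoich, which
## realises the d[A]/dt = -2 k [A]^2 convention.
compile_network <- function(net) {
  spn <- net$species$name
  aug <- c(spn, names(net$continuum), ".one")
  nR <- nrow(net$reactions)
  i1 <- match(net$reactions$r1, aug)
  i2 <- ifelse(is.na(net$reactions$r2), match(".one", aug),
               match(net$reactions$r2, aug))
  stoich <- matrix(0, nR, length(spn), dimnames = list(net$reactions$id, spn))
  for (r in seq_len(nR)) {
    for (s in c(net$reactions$r1[r], net$reactions$r2[r])) {
      if (!is.na(s) && s %in% spn) stoich[r, s] <- stoich[r, s] - 1
    }
    for (p in net$reactions$products[[r]]) {
      if (p %in% spn) stoich[r, p] <- stoich[r, p] + 1
    }
  }
  k <- net$reactions$k * 1e-9  # 1/M/s -> 1/M/ns (or 1/s -> 1/ns)
  list(species = spn, aug = aug, i1 = i1, i2 = i2, k = k,
       stoich = stoich, KS = k * stoich,
       continuum = net$continuum)
}
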