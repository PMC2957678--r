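#' Declare a species
#'
#' @param name Species identifier (unique within a network).  By convention an
#'   `_a` suffix marks the active and `_p` the phosphorylated form of a base
#'   species.
#' @param initial Initial molecule count, non-negative.
#' @param role One of `"protein"`, `"mRNA"`, `"complex"`, `"ligand"`,
#'   `"receptor"`.
#' @param variant_of Optional name of the base species this one is an
#'   active/phosphorylated variant of.
#' @return A `species_def` object.
#' @export
species_def <- function(name, initial = 0, role = "protein", variant_of = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(initial), length(initial) == 1L, initial >= 0)
  role <- match.arg(role, c("protein", "mRNA", "complex", "ligand", "receptor"))
  structure(list(name = name, initial = as.numeric(initial), role = role,
                 variant_of = variant_of),
            class = "species_def")
}

#' Declare a reaction
#'
#' Reactants and products are given as character vectors; stoichiometric
#' multiplicity is expressed by repetition (`c("A", "A")` for a homodimer
#' pair).  Pure synthesis has no reactants, pure degradation no products.
#'
#' @param label Reaction identifier.
#' @param reactants,products Character vectors of species names (possibly
#'   empty, possibly with repeats).
#' @param rate A [mass_action()] or [hill()] rate law.
#' @return A `pathmc_reaction` object.
#' @export
reaction <- function(label, reactants, products, rate) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(rate, "rate_law"))
  reactants <- as.character(reactants)
  products <- as.character(products)
  if (length(reactants) + length(products) == 0L)
    stop("reaction '", label, "': reactants and products are both empty")
  rtab <- table(reactants)
  if (rate$kind == "mass_action" && any(rtab > 2L))
    stop("reaction '", label, "': mass-action multiplicity > 2 per species")
  r <- as.integer(rtab); names(r) <- names(rtab)
  ptab <- table(products)
  p <- as.integer(ptab); names(p) <- names(ptab)
  structure(list(label = label, reactants = r, products = p, rate = rate),
            class = "pathmc_reaction")
}

#' @export
format.pathmc_reaction <- function(x, ...) {
  side <- function(m) {
    if (length(m) == 0L) return("0")
    paste(ifelse(m > 1L, paste0(m, " ", names(m)), names(m)), collapse = " + ")
  }
  sprintf("%s -> %s @ %s", side(x$reactants), side(x$products), format(x$rate))
}

#' @export
print.pathmc_reaction <- function(x, ...) {
  cat(x$label, ": ", format(x), "\n", sep = "")
  invisible(x)
}

#' Declare a conservation relation
#'
#' The sum of the member species' counts is invariant along every trajectory
#' (exactly under SSA, to solver tolerance under the ODE engine).  Typical use:
#' the active and inactive forms of a signalling protein, e.g.
#' `AKT + AKT_p = AKT_tot`.
#'
#' @param members Character vector of species names.
#' @param total The conserved total count.
#' @return A `conservation` object.
#' @export
conservation <- function(members, total) {
  stopifnot(is.character(members), length(members) >= 2L,
            is.numeric(total), total >= 0)
  structure(list(members = members, total = as.numeric(total)),
            class = "conservation")
}

#' Assemble and validate a reaction network
#'
#' Cross-references (reaction reactants/products, Hill regulators,
#' conservation members) are checked against the species list; every
#' conservation relation is checked statically, i.e. each reaction's net
#' stoichiometry over the members must sum to zero and the initial counts must
#' sum to the stated total.
#'
#' @param species List of [species_def()] objects.
#' @param reactions List of [reaction()] objects.
#' @param conservation List of [conservation()] objects.
#' @param parameters Optional named numeric vector recording the scalar
#'   parameters the network was built from (kept for provenance and sweeps).
#' @return A `reaction_network` object with components `species`, `reactions`,
#'   `conservation`, `parameters`, plus derived matrices: `stoich` (species x
#'   reactions net change) used by both simulation engines.
#' @export
reaction_network <- function(species, reactions, conservation = list(),
                             parameters = numeric()) {
  stopifnot(is.list(species), length(species) > 0L, is.list(reactions))
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate species names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (s in species) {
    if (!is.na(s$variant_of) && !(s$variant_of %in% nm))
      stop("species '", s$name, "': variant_of references unknown species '",
           s$variant_of, "'")
  }
  ns <- length(nm)
  nr <- length(reactions)
  if (nr == 0L) stop("network has no reactions")
  stoich <- matrix(0, nrow = ns, ncol = nr,
                   dimnames = list(nm, vapply(reactions, `[[`, character(1), "label")))
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    stopifnot(inherits(rx, "pathmc_reaction"))
    refs <- c(names(rx$reactants), names(rx$products),
              if (rx$rate$kind == "hill") rx$rate$regulator)
    bad <- setdiff(refs, nm)
    if (length(bad) > 0L)
      stop("reaction '", rx$label, "' references undeclared species: ",
           paste(bad, collapse = ", "))
    stoich[names(rx$reactants), j] <- stoich[names(rx$reactants), j] - rx$reactants
    stoich[names(rx$products), j] <- stoich[names(rx$products), j] + rx$products
  }
  init <- stats::setNames(vapply(species, `[[`, numeric(1), "initial"), nm)
  for (cs in conservation) {
    stopifnot(inherits(cs, "conservation"))
    bad <- setdiff(cs$members, nm)
    if (length(bad) > 0L)
      stop("conservation relation references undeclared species: ",
           paste(bad, collapse = ", "))
    net <- colSums(stoich[cs$members, , drop = FALSE])
    if (any(net != 0))
      stop("conservation over {", paste(cs$members, collapse = ", "),
           "} violated by reaction(s): ",
           paste(colnames(stoich)[net != 0], collapse = ", "))
    if (abs(sum(init[cs$members]) - cs$total) > 1e-9 * max(1, cs$total))
      stop("conservation over {", paste(cs$members, collapse = ", "),
           "}: initial counts sum to ", sum(init[cs$members]),
           ", stated total is ", cs$total)
  }
  if (length(parameters) > 0L && any(parameters < 0))
    stop("negative parameter: ",
         paste(names(parameters)[parameters < 0], collapse = ", "))
  structure(list(species = species, reactions = reactions,
                 conservation = conservation,
                 parameters = parameters,
                 species_names = nm, init = init, stoich = stoich),
            class = "reaction_network")
}

#' Number of independent dynamical variables
#'
#' Species count minus the number of (independent) conservation relations:
#' the dimension of the reduced ODE system.
#'
#' @param network A [reaction_network()].
#' @return Integer.
#' @export
n_free_variables <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  length(network$species) - length(network$conservation)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions,",
      length(x$conservation), "conservation relations\n")
  cat("Free dynamical variables:", n_free_variables(x), "\n")
  nz <- x$init[x$init > 0]
  if (length(nz) > 0L) {
    cat("Non-zero initial counts:\n")
    print(nz)
  }
  invisible(x)
}

#' @export
summary.reaction_network <- function(object, ...) {
  cat("Reaction network\n")
  cat("  species:", length(object$species), "\n")
  cat("  reactions:", length(object$reactions), "\n")
  cat("  conservation relations:", length(object$conservation), "\n")
  cat("  free variables:", n_free_variables(object), "\n\n")
  for (r in object$reactions) cat(" ", r$label, ": ", format(r), "\n", sep = "")
  invisible(object)
}

# all propensities at a state (named vector), used by the ODE RHS and tests
all_rates <- function(network, state, mode = "deterministic") {
  vapply(network$reactions, reaction_rate, numeric(1),
         state = state, mode = mode)
}
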