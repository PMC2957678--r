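#' Save / load a reaction network as a YAML config
#'
#' The config has four sections: `species` (name, initial count, role,
#' variant_of), `reactions` (a map from label to a rule string of the form
#' `"A + B -> C @ mass_action(k=...)"` or
#' `"0 -> X @ hill(vmax=..., K=..., n=..., regulator=TF, basal=...)"`, with
#' `0` denoting an empty side and `2 A` a stoichiometric coefficient),
#' `conservation` (members + total) and `parameters`.  `load_network`
#' re-validates everything, so a config referencing an undeclared species
#' fails with a validation error; `load_network(save_network(N))` is
#' structurally identical to `N`.
#'
#' @param network A [reaction_network()].
#' @param path File path.
#' @param header Optional comment lines written at the top of the file.
#' @return `load_network` returns a [reaction_network()]; `save_network`
#'   returns `path` invisibly.
#' @export
save_network <- function(network, path, header = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  num <- function(x) sprintf("%.17g", x)
  fmt_rate <- function(rl) {
    if (rl$kind == "mass_action") {
      sprintf("mass_action(k=%s)", num(rl$k))
    } else {
      sprintf("hill(vmax=%s, K=%s, n=%s, regulator=%s, basal=%s)",
              num(rl$vmax), num(rl$K), num(rl$n), rl$regulator, num(rl$basal))
    }
  }
  fmt_side <- function(m) {
    if (length(m) == 0L) return("0")
    paste(ifelse(m > 1L, paste(m, names(m)), names(m)), collapse = " + ")
  }
  rx <- lapply(network$reactions, function(r)
    sprintf("%s -> %s @ %s", fmt_side(r$reactants), fmt_side(r$products),
            fmt_rate(r$rate)))
  names(rx) <- vapply(network$reactions, `[[`, character(1), "label")
  doc <- list(
    species = lapply(network$species, function(s)
      list(name = s$name, initial = s$initial, role = s$role,
           variant_of = if (is.na(s$variant_of)) NULL else s$variant_of)),
    reactions = rx,
    conservation = lapply(network$conservation, function(cs)
      list(members = as.list(cs$members), total = cs$total)),
    parameters = as.list(network$parameters))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(yaml::as.yaml(doc, precision = 17), con)
  invisible(path)
}

parse_rule <- function(label, text) {
  err <- function(...) stop("reaction '", label, "': ", ..., call. = FALSE)
  parts <- strsplit(text, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2L) err("expected '<lhs> -> <rhs> @ <rate law>'")
  sides <- strsplit(parts[1], "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) err("expected exactly one '->'")
  side <- function(s) {
    s <- trimws(s)
    if (s == "0" || s == "") return(character())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    unlist(lapply(terms, function(tm) {
      m <- regmatches(tm, regexec("^([0-9]+)\\s+(\\S+)$", tm))[[1]]
      if (length(m) == 3L) rep(m[3], as.integer(m[2])) else tm
    }))
  }
  rt <- trimws(parts[2])
  m <- regmatches(rt, regexec("^(mass_action|hill)\\s*\\((.*)\\)$", rt))[[1]]
  if (length(m) != 3L) err("unparseable rate law: '", rt, "'")
  kv <- strsplit(trimws(strsplit(m[3], ",", fixed = TRUE)[[1]]), "=")
  args <- stats::setNames(lapply(kv, function(p) trimws(p[2])),
                          vapply(kv, function(p) trimws(p[1]), character(1)))
  rate <- if (m[2] == "mass_action") {
    if (is.null(args$k)) err("mass_action needs k")
    mass_action(as.numeric(args$k))
  } else {
    if (!all(c("vmax", "K", "n", "regulator") %in% names(args)))
      err("hill needs vmax, K, n, regulator")
    hill(as.numeric(args$vmax), as.numeric(args$K), as.numeric(args$n),
         args$regulator,
         basal = if (is.null(args$basal)) 0 else as.numeric(args$basal))
  }
  reaction(label, side(sides[1]), side(sides[2]), rate)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- yaml::read_yaml(path)
  for (sec in c("species", "reactions"))
    if (is.null(doc[[sec]])) stop("config is missing the '", sec, "' section")
  sp <- lapply(doc$species, function(s) {
    if (is.null(s$name)) stop("species entry without a name")
    species_def(s$name,
                initial = if (is.null(s$initial)) 0 else s$initial,
                role = if (is.null(s$role)) "protein" else s$role,
                variant_of = if (is.null(s$variant_of)) NA_character_
                             else s$variant_of)
  })
  rx <- mapply(parse_rule, names(doc$reactions), unlist(doc$reactions),
               SIMPLIFY = FALSE, USE.NAMES = FALSE)
  cons <- lapply(doc$conservation, function(cs)
    conservation(unlist(cs$members), cs$total))
  pars <- unlist(doc$parameters)
  if (is.null(pars)) pars <- numeric()
  reaction_network(sp, rx, cons, parameters = pars)
}
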