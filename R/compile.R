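# Internal: flatten a reaction_network into index vectors shared by the ODE
# right-hand side and the C++ SSA core.
#
# Mass-action reactions carry up to two reactant slots (r1, r2, 1-based
# species indices, 0 = unused); a homodimer pair occupies both slots with the
# same index and is flagged in `same2`.  Hill reactions carry
# (vmax, K, n, basal) and a regulator index.  The sparse state-change list and
# the propensity dependency graph (which propensities must be refreshed after
# a reaction fires) are stored in CSR-style offset/index vectors.
compile_network <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  nm <- network$species_names
  ns <- length(nm)
  nr <- length(network$reactions)
  type <- integer(nr); k <- numeric(nr)
  r1 <- integer(nr); r2 <- integer(nr); same2 <- integer(nr)
  vmax <- numeric(nr); K <- numeric(nr); nh <- numeric(nr)
  basal <- numeric(nr); reg <- integer(nr)
  ch_idx <- list(); ch_delta <- list()
  depends_on <- vector("list", nr)  # species indices each propensity reads
  for (j in seq_len(nr)) {
    rx <- network$reactions[[j]]
    rl <- rx$rate
    if (rl$kind == "mass_action") {
      type[j] <- 0L; k[j] <- rl$k
      rs <- rep(match(names(rx$reactants), nm), rx$reactants)
      if (length(rs) > 2L) stop("mass-action order > 2")
      if (length(rs) >= 1L) r1[j] <- rs[1]
      if (length(rs) == 2L) { r2[j] <- rs[2]; same2[j] <- as.integer(rs[1] == rs[2]) }
      depends_on[[j]] <- unique(rs)
    } else {
      type[j] <- 1L
      vmax[j] <- rl$vmax; K[j] <- rl$K; nh[j] <- rl$n; basal[j] <- rl$basal
      reg[j] <- match(rl$regulator, nm)
      depends_on[[j]] <- reg[j]
    }
    delta <- network$stoich[, j]
    nzi <- which(delta != 0)
    ch_idx[[j]] <- as.integer(nzi)
    ch_delta[[j]] <- as.numeric(delta[nzi])
  }
  # reactions whose propensity reads species s
  readers <- vector("list", ns)
  for (j in seq_len(nr)) for (s in depends_on[[j]])
    readers[[s]] <- c(readers[[s]], j)
  dep <- vector("list", nr)
  for (j in seq_len(nr)) {
    affected <- unique(unlist(readers[ch_idx[[j]]]))
    dep[[j]] <- sort(as.integer(affected))
  }
  csr <- function(lst) {
    lens <- lengths(lst)
    list(ptr = c(0L, cumsum(lens)), idx = as.integer(unlist(lst, use.names = FALSE)))
  }
  ch <- csr(ch_idx)
  dp <- csr(dep)
  list(ns = ns, nr = nr, names = nm,
       type = type, k = k, r1 = r1, r2 = r2, same2 = same2,
       vmax = vmax, K = K, nhill = nh, basal = basal, reg = reg,
       ch_ptr = ch$ptr, ch_idx = ch$idx,
       ch_delta = as.numeric(unlist(ch_delta, use.names = FALSE)),
       dep_ptr = dp$ptr, dep_idx = dp$idx)
}

# Internal: vectorised deterministic rate evaluation for the ODE RHS.
compiled_rates_det <- function(comp, y) {
  yy <- c(pmax(y, 0), 1)  # last slot: neutral factor for empty reactant slots
  i1 <- ifelse(comp$r1 > 0L, comp$r1, comp$ns + 1L)
  i2 <- ifelse(comp$r2 > 0L, comp$r2, comp$ns + 1L)
  rates <- comp$k * yy[i1] * yy[i2]
  rates[comp$same2 == 1L] <- rates[comp$same2 == 1L] / 2
  hj <- which(comp$type == 1L)
  if (length(hj) > 0L) {
    R <- yy[comp$reg[hj]]
    rates[hj] <- comp$basal[hj] +
      comp$vmax[hj] * R^comp$nhill[hj] / (comp$K[hj]^comp$nhill[hj] + R^comp$nhill[hj])
  }
  pmax(rates, 0)
}
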