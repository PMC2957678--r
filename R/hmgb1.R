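#' Default rate constants for the HMGB1 network
#'
#' Named numeric vector of all rate constants used by [hmgb1_network()], in
#' per-minute units (molecule counts, not concentrations).  The three
#' mutation/sensitivity knobs are:
#' \describe{
#'   \item{`d_ARF`}{MDM2_p degradation rate driven by ARF.  Small values model
#'     ARF loss (MDM2 unchecked, p53 destabilised).}
#'   \item{`d_P21`}{CyclinD/E degradation rate driven by P21.  Small values
#'     model P21/FBXW7 mutation (cyclins accumulate).}
#'   \item{`d_RAS`}{RAS deactivation rate.  Small values model constitutively
#'     active (oncogenic) K-RAS.}
#' }
#' The constants are this package's own calibration, chosen so that the
#' default network reproduces the qualitative behaviours documented in the
#' methods vignette (early p53 pulse, damped deterministic vs sustained
#' stochastic p53/MDM2_p oscillation, CyclinE peak near the G1-S transition at
#' ~600 min, and the dose-response directions of the HMGB1/AKT/mutation
#' sweeps).
#'
#' @param ... Named overrides, e.g. `hmgb1_params(d_RAS = 1e-6)`.
#' @return Named numeric vector.
#' @export
hmgb1_params <- function(...) {
  p <- c(
    ## receptor engagement (RAGE lumps all HMGB1 receptors)
    ka_RAGE = 2e-5, kd_RAGE = 0.1, d_HMGB1 = 1e-5,
    ## PI3K-PIP3-AKT axis
    ka_PI3K = 1.2e-4, ka_PI3K_RAS = 2e-6, kd_PI3K = 0.1,
    ka_PIP = 2e-6, kd_PIP = 0.05, k_PTEN = 3e-5,
    ka_AKT = 2e-6, kd_AKT = 0.02,
    ## RAS-RAF-MEK-ERK cascade
    ka_RAS = 2e-4, d_RAS = 1e-2,
    ka_RAF = 2e-7, kd_RAF = 0.01,
    ka_MEK = 2e-7, kd_MEK = 0.01,
    ka_ERK = 2e-6, kd_ERK = 0.01,
    ## p53 core
    k_syn_p53 = 15000, d_p53 = 0.1, d_p53_mdm2 = 5e-5,
    ## mdm2 transcript (low copy number: transcription bursts drive the
    ## stochastic p53 oscillation) and MDM2 protein
    vmax_mdm2 = 600, K_mdm2 = 2.6e4, n_mdm2 = 9, basal_mdm2 = 0.02,
    d_mdm2_rna = 0.2, k_transl_mdm2 = 45, d_MDM2 = 0.05,
    ka_MDM2 = 2e-5, kd_MDM2p = 0.05, d_MDM2p = 0.45, d_ARF = 3e-5,
    ## PTEN (p53 target, positive feedback on p53)
    vmax_PTEN = 60, K_PTEN = 2.6e4, n_PTEN = 4, d_PTEN = 0.02,
    ## Myc and CyclinD (ERK targets)
    vmax_Myc = 20, K_Myc = 500, n_Myc = 2, d_Myc = 0.01,
    vmax_CD = 72, K_CD = 500, n_CD = 4, basal_CD = 0.1, d_CD = 0.01,
    d_P21 = 5.5e-6, d_INK4A = 2e-5,
    ## Rb / E2F / RE complex
    k_syn_Rb = 2, d_Rb = 0.01, k_assoc_RE = 1e-5, k_dissoc_RE = 1e-5,
    k_rel_CD = 1.6e-7, k_rel_Myc = 1.6e-7, k_rel_CE = 1.6e-7,
    k_rbp_CD = 1e-8, k_rbp_CE = 1e-8, k_rbp_Myc = 1e-8,
    vmax_E2F = 20, K_E2F = 1000, n_E2F = 2, d_E2F = 0.04,
    ## CyclinE (E2F target)
    vmax_CE = 47, K_CE = 700, n_CE = 4, d_CE = 0.01,
    ## ARF (E2F target), P21 (p53 target), INK4A
    k_syn_ARF = 0.01, d_ARF_deg = 0.01,
    k_syn_P21 = 0.001, d_P21_deg = 0.002,
    k_syn_INK4A = 1, d_INK4A_deg = 0.01
  )
  dots <- list(...)
  if (length(dots) > 0L) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("overrides must be named")
    bad <- setdiff(names(dots), names(p))
    if (length(bad) > 0L)
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- as.numeric(unlist(dots))
  }
  if (any(p < 0)) stop("parameters must be non-negative")
  p
}

#' Build the HMGB1 signal-transduction network
#'
#' Constructs the 31-species, 59-reaction model of HMGB1 signalling coupling
#' three pathways: the RAS-ERK cascade (RAS -> RAF -> MEK -> ERK -> CyclinD,
#' plus Myc), the p53-MDM2 module with its negative feedback loop
#' (PI3K -> PIP3 -> AKT -> MDM2 -| p53 -> mdm2 transcript -> MDM2) and the
#' PTEN positive loop (p53 -> PTEN -| PIP3), and the Rb-E2F module
#' (CyclinD -| Rb -| E2F -> CyclinE -| Rb) with the explicit Rb-E2F complex
#' RE.  Crosstalk edges: RAS activates PI3K; E2F induces ARF which degrades
#' MDM2_p; p53 induces P21 which degrades CyclinD/E; INK4A degrades CyclinD.
#' HMGB1 activates the single lumped receptor RAGE.
#'
#' Hill rate laws are used exactly for the six transcription-driven syntheses
#' (PTEN, mdm2 transcript, CyclinD, Myc, E2F, CyclinE); every other reaction
#' is mass action.  Eight conservation relations hold: the active+inactive
#' totals of RAGE, PI3K, PIP, AKT, RAS, RAF, MEK and ERK, so the network has
#' 31 - 8 = 23 free dynamical variables.
#'
#' Default initial counts: RAGE 1e3, PI3K 1e5, PIP2 1e5, AKT 1e5, MDM2 1e4,
#' MDM2_p 2e4, p53 2e4, RAS/RAF/MEK/ERK 1e4, RE 1e5, all other species 0,
#' HMGB1 as given.
#'
#' @param hmgb1_init Initial number of HMGB1 molecules (default 1e3, the
#'   baseline stimulus).
#' @param params Named numeric vector from [hmgb1_params()]; every constant
#'   must be present.
#' @param init Optional named numeric vector of initial-count overrides,
#'   e.g. `c(AKT = 3e5)` (conservation totals are adjusted accordingly).
#' @return A validated [reaction_network()].
#' @examples
#' net <- hmgb1_network()
#' length(net$species)    # 31
#' length(net$reactions)  # 59
#' @export
hmgb1_network <- function(hmgb1_init = 1e3, params = hmgb1_params(),
                          init = numeric()) {
  required <- names(hmgb1_params())
  miss <- setdiff(required, names(params))
  if (length(miss) > 0L)
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  p <- as.list(params[required])

  i0 <- c(HMGB1 = hmgb1_init,
          RAGE = 1e3, RAGE_a = 0,
          PI3K = 1e5, PI3K_a = 0,
          PIP2 = 1e5, PIP3 = 0,
          AKT = 1e5, AKT_p = 0,
          RAS = 1e4, RAS_a = 0,
          RAF = 1e4, RAF_a = 0,
          MEK = 1e4, MEK_p = 0,
          ERK = 1e4, ERK_p = 0,
          p53 = 2e4, mdm2 = 0, MDM2 = 1e4, MDM2_p = 2e4,
          PTEN = 0, Myc = 0, CyclinD = 0, CyclinE = 0,
          Rb = 0, E2F = 0, RE = 1e5,
          ARF = 0, P21 = 0, INK4A = 0)
  if (length(init) > 0L) {
    bad <- setdiff(names(init), names(i0))
    if (length(bad) > 0L)
      stop("unknown species in init: ", paste(bad, collapse = ", "))
    i0[names(init)] <- init
  }

  role <- c(HMGB1 = "ligand", RAGE = "receptor", RAGE_a = "receptor",
            mdm2 = "mRNA", RE = "complex")
  base <- c(RAGE_a = "RAGE", PI3K_a = "PI3K", PIP3 = "PIP2", AKT_p = "AKT",
            RAS_a = "RAS", RAF_a = "RAF", MEK_p = "MEK", ERK_p = "ERK",
            MDM2_p = "MDM2")
  sp <- lapply(names(i0), function(nm)
    species_def(nm, i0[[nm]],
                role = if (nm %in% names(role)) role[[nm]] else "protein",
                variant_of = if (nm %in% names(base)) base[[nm]] else NA_character_))

  ma <- mass_action
  rx <- list(
    ## receptor engagement
    reaction("RAGE_act",    c("HMGB1", "RAGE"), c("HMGB1", "RAGE_a"), ma(p$ka_RAGE)),
    reaction("RAGE_deact",  "RAGE_a", "RAGE", ma(p$kd_RAGE)),
    reaction("HMGB1_clear", "HMGB1", character(), ma(p$d_HMGB1)),
    ## PI3K-PIP3-AKT
    reaction("PI3K_act_RAGE", c("RAGE_a", "PI3K"), c("RAGE_a", "PI3K_a"), ma(p$ka_PI3K)),
    reaction("PI3K_act_RAS",  c("RAS_a", "PI3K"), c("RAS_a", "PI3K_a"), ma(p$ka_PI3K_RAS)),
    reaction("PI3K_deact",  "PI3K_a", "PI3K", ma(p$kd_PI3K)),
    reaction("PIP2_to_PIP3", c("PI3K_a", "PIP2"), c("PI3K_a", "PIP3"), ma(p$ka_PIP)),
    reaction("PIP3_to_PIP2", "PIP3", "PIP2", ma(p$kd_PIP)),
    reaction("PIP3_hydrolysis_PTEN", c("PTEN", "PIP3"), c("PTEN", "PIP2"), ma(p$k_PTEN)),
    reaction("AKT_phos",    c("PIP3", "AKT"), c("PIP3", "AKT_p"), ma(p$ka_AKT)),
    reaction("AKT_dephos",  "AKT_p", "AKT", ma(p$kd_AKT)),
    ## RAS-RAF-MEK-ERK
    reaction("RAS_act",     c("RAGE_a", "RAS"), c("RAGE_a", "RAS_a"), ma(p$ka_RAS)),
    reaction("RAS_deact",   "RAS_a", "RAS", ma(p$d_RAS)),
    reaction("RAF_act",     c("RAS_a", "RAF"), c("RAS_a", "RAF_a"), ma(p$ka_RAF)),
    reaction("RAF_deact",   "RAF_a", "RAF", ma(p$kd_RAF)),
    reaction("MEK_phos",    c("RAF_a", "MEK"), c("RAF_a", "MEK_p"), ma(p$ka_MEK)),
    reaction("MEK_dephos",  "MEK_p", "MEK", ma(p$kd_MEK)),
    reaction("ERK_phos",    c("MEK_p", "ERK"), c("MEK_p", "ERK_p"), ma(p$ka_ERK)),
    reaction("ERK_dephos",  "ERK_p", "ERK", ma(p$kd_ERK)),
    ## p53 core
    reaction("p53_syn",     character(), "p53", ma(p$k_syn_p53)),
    reaction("p53_deg",     "p53", character(), ma(p$d_p53)),
    reaction("p53_deg_MDM2p", c("MDM2_p", "p53"), "MDM2_p", ma(p$d_p53_mdm2)),
    ## mdm2 transcript -> MDM2 -> MDM2_p
    reaction("mdm2_transcription", character(), "mdm2",
             hill(p$vmax_mdm2, p$K_mdm2, p$n_mdm2, "p53", p$basal_mdm2)),
    reaction("mdm2_decay",  "mdm2", character(), ma(p$d_mdm2_rna)),
    reaction("MDM2_translation", "mdm2", c("mdm2", "MDM2"), ma(p$k_transl_mdm2)),
    reaction("MDM2_deg",    "MDM2", character(), ma(p$d_MDM2)),
    reaction("MDM2_phos",   c("AKT_p", "MDM2"), c("AKT_p", "MDM2_p"), ma(p$ka_MDM2)),
    reaction("MDM2p_dephos", "MDM2_p", "MDM2", ma(p$kd_MDM2p)),
    reaction("MDM2p_deg",   "MDM2_p", character(), ma(p$d_MDM2p)),
    reaction("MDM2p_deg_ARF", c("ARF", "MDM2_p"), "ARF", ma(p$d_ARF)),
    ## PTEN
    reaction("PTEN_syn",    character(), "PTEN",
             hill(p$vmax_PTEN, p$K_PTEN, p$n_PTEN, "p53")),
    reaction("PTEN_deg",    "PTEN", character(), ma(p$d_PTEN)),
    ## Myc
    reaction("Myc_syn",     character(), "Myc",
             hill(p$vmax_Myc, p$K_Myc, p$n_Myc, "ERK_p")),
    reaction("Myc_deg",     "Myc", character(), ma(p$d_Myc)),
    ## CyclinD
    reaction("CD_syn",      character(), "CyclinD",
             hill(p$vmax_CD, p$K_CD, p$n_CD, "ERK_p", p$basal_CD)),
    reaction("CD_deg",      "CyclinD", character(), ma(p$d_CD)),
    reaction("CD_deg_P21",  c("P21", "CyclinD"), "P21", ma(p$d_P21)),
    reaction("CD_deg_INK4A", c("INK4A", "CyclinD"), "INK4A", ma(p$d_INK4A)),
    ## Rb / E2F / RE
    reaction("Rb_syn",      character(), "Rb", ma(p$k_syn_Rb)),
    reaction("Rb_deg",      "Rb", character(), ma(p$d_Rb)),
    reaction("RE_assoc",    c("Rb", "E2F"), "RE", ma(p$k_assoc_RE)),
    reaction("RE_dissoc",   "RE", c("Rb", "E2F"), ma(p$k_dissoc_RE)),
    reaction("E2F_release_CD", c("CyclinD", "RE"), c("CyclinD", "E2F"), ma(p$k_rel_CD)),
    reaction("E2F_release_Myc", c("Myc", "RE"), c("Myc", "E2F"), ma(p$k_rel_Myc)),
    reaction("E2F_release_CE", c("CyclinE", "RE"), c("CyclinE", "E2F"), ma(p$k_rel_CE)),
    reaction("Rb_phos_CD",  c("CyclinD", "Rb"), "CyclinD", ma(p$k_rbp_CD)),
    reaction("Rb_phos_CE",  c("CyclinE", "Rb"), "CyclinE", ma(p$k_rbp_CE)),
    reaction("Rb_phos_Myc", c("Myc", "Rb"), "Myc", ma(p$k_rbp_Myc)),
    reaction("E2F_syn",     character(), "E2F",
             hill(p$vmax_E2F, p$K_E2F, p$n_E2F, "Myc")),
    reaction("E2F_deg",     "E2F", character(), ma(p$d_E2F)),
    ## CyclinE
    reaction("CE_syn",      character(), "CyclinE",
             hill(p$vmax_CE, p$K_CE, p$n_CE, "E2F")),
    reaction("CE_deg",      "CyclinE", character(), ma(p$d_CE)),
    reaction("CE_deg_P21",  c("P21", "CyclinE"), "P21", ma(p$d_P21)),
    ## ARF, P21, INK4A
    reaction("ARF_syn",     "E2F", c("E2F", "ARF"), ma(p$k_syn_ARF)),
    reaction("ARF_deg",     "ARF", character(), ma(p$d_ARF_deg)),
    reaction("P21_syn",     "p53", c("p53", "P21"), ma(p$k_syn_P21)),
    reaction("P21_deg",     "P21", character(), ma(p$d_P21_deg)),
    reaction("INK4A_syn",   character(), "INK4A", ma(p$k_syn_INK4A)),
    reaction("INK4A_deg",   "INK4A", character(), ma(p$d_INK4A_deg))
  )

  cons <- list(
    conservation(c("RAGE", "RAGE_a"), i0[["RAGE"]] + i0[["RAGE_a"]]),
    conservation(c("PI3K", "PI3K_a"), i0[["PI3K"]] + i0[["PI3K_a"]]),
    conservation(c("PIP2", "PIP3"), i0[["PIP2"]] + i0[["PIP3"]]),
    conservation(c("AKT", "AKT_p"), i0[["AKT"]] + i0[["AKT_p"]]),
    conservation(c("RAS", "RAS_a"), i0[["RAS"]] + i0[["RAS_a"]]),
    conservation(c("RAF", "RAF_a"), i0[["RAF"]] + i0[["RAF_a"]]),
    conservation(c("MEK", "MEK_p"), i0[["MEK"]] + i0[["MEK_p"]]),
    conservation(c("ERK", "ERK_p"), i0[["ERK"]] + i0[["ERK_p"]])
  )

  reaction_network(sp, rx, cons, parameters = params[required])
}
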