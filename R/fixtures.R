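# Programmatic builders for the cell-signaling networks used as the test
# corpus.  Where the source prints matrices (cell cycle, hybrid histidine
# kinase, shared-kinase reduced, allosteric reduced) the builders pin the
# printed species and reaction orders exactly; the remaining motifs are
# reconstructed from the standard literature mechanisms and validated by
# their species/reaction/extreme-ray counts and signed-support sizes.

.fixture_names <- c(
  "running_example", "cell_cycle", "hybrid_histidine_kinase",
  "phospho_cycle", "phospho_diff_phosphatases",
  "weakly_irrev_dephos", "fully_weakly_irrev", "erk",
  "shared_kinase", "shared_kinase_reduced", "mapk_two_layer",
  "covalent_regulation", "allosteric_regulation", "allosteric_reduced"
)

#' Build a named example network
#'
#' Available fixtures: `running_example` (the three-reaction autocatalytic
#' toy network), `cell_cycle` (G2/M transition module), `hybrid_histidine_kinase`,
#' `phospho_cycle` (m-site sequential distributive phosphorylation cycle,
#' Michaelis-Menten kinase and one phosphatase; `m` sites), `phospho_diff_phosphatases`
#' (one phosphatase per dephosphorylation step), `weakly_irrev_dephos`
#' (2-site cycle, weakly irreversible dephosphorylation), `fully_weakly_irrev`
#' (2-site cycle, weak irreversibility in both directions), `erk` (ERK
#' dual-site regulation with processive and distributive paths),
#' `shared_kinase` / `shared_kinase_reduced` (two-layer cascade, the kinase
#' shared between layers), `mapk_two_layer`, `covalent_regulation` and
#' `allosteric_regulation` / `allosteric_reduced` (reciprocal kinase/phosphatase
#' regulation via a shared modifying enzyme / a shared allosteric ligand).
#'
#' @param name fixture identifier.
#' @param m number of phosphorylation sites for the `phospho_*` families.
#' @return A [reaction_network].
#' @export
example_network <- function(name, m = 2) {
  name <- match.arg(name, .fixture_names)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  text <- switch(name,
    running_example = "
      species: X1 X2
      X1 -> X2
      X2 -> X1
      2 X1 + X2 -> 3 X1",
    # Species order C, C+, M, M+, W, W+ and reaction order chosen to
    # reproduce the printed stoichiometric matrix of the G2/M module:
    # the phosphatase C activates MPF (M+ -> M), active MPF activates C and
    # deactivates the kinase W, W phosphorylates MPF, C and W+ relax.
    cell_cycle = "
      species: C C+ M M+ W W+
      C + M+ -> C + M
      C+ + M -> C + M
      M + W -> M+ + W
      M + W -> M + W+
      C -> C+
      W+ -> W",
    hybrid_histidine_kinase = "
      species: HK00 HKp0 HK0p HKpp Hpt Hptp
      HK00 -> HKp0
      HKp0 -> HK0p
      HK0p -> HKpp
      HK0p + Hpt -> HK00 + Hptp
      HKpp + Hpt -> HKp0 + Hptp
      Hptp -> Hpt",
    phospho_cycle = .phospho_cycle_text(m, diff_phosphatases = FALSE),
    phospho_diff_phosphatases = .phospho_cycle_text(m, diff_phosphatases = TRUE),
    weakly_irrev_dephos = "
      S + E <-> ES
      ES -> Sp + E
      Sp + E <-> ESp
      ESp -> Spp + E
      Spp + F <-> FSpp
      FSpp -> FSp_c
      FSp_c <-> Sp + F
      Sp + F <-> FSp_b
      FSp_b -> FS
      FS <-> S + F",
    fully_weakly_irrev = "
      S + E <-> ES
      ES -> ESp_c
      ESp_c <-> Sp + E
      Sp + E <-> ESp_b
      ESp_b -> ESpp
      ESpp <-> Spp + E
      Spp + F <-> FSpp
      FSpp -> FSp_c
      FSp_c <-> Sp + F
      Sp + F <-> FSp_b
      FSp_b -> FS
      FS <-> S + F",
    erk = "
      S00 + E <-> S00E
      S00E -> S01E
      S01E <-> S01 + E
      S01E -> S11 + E
      S11 + F <-> S11F
      S11F -> S10F
      S10F <-> S10 + F
      S10F -> S00 + F
      S10 + E <-> S10E
      S10E -> S11 + E
      S01 + F <-> S01F
      S01F -> S00 + F",
    # full cascade: reduced network plus the five reverse unbinding
    # reactions; reaction order (catalysis, binding, unbinding) per triple so
    # the unbinding reactions are every third one
    shared_kinase = "
      SE -> Sp + E
      S + E -> SE
      SE -> S + E
      SpF1 -> S + F1
      Sp + F1 -> SpF1
      SpF1 -> Sp + F1
      PSp -> Pp + Sp
      P + Sp -> PSp
      PSp -> P + Sp
      PE -> Pp + E
      P + E -> PE
      PE -> P + E
      PpF2 -> P + F2
      Pp + F2 -> PpF2
      PpF2 -> Pp + F2",
    shared_kinase_reduced = "
      SE -> Sp + E
      S + E -> SE
      SpF1 -> S + F1
      Sp + F1 -> SpF1
      PSp -> Pp + Sp
      P + Sp -> PSp
      PE -> Pp + E
      P + E -> PE
      PpF2 -> P + F2
      Pp + F2 -> PpF2",
    mapk_two_layer = "
      KKK + E1 <-> KKK_E1
      KKK_E1 -> KKKs + E1
      KKKs + E2 <-> KKKs_E2
      KKKs_E2 -> KKK + E2
      KK + KKKs <-> KK_KKKs
      KK_KKKs -> KKp + KKKs
      KKp + KKKs <-> KKp_KKKs
      KKp_KKKs -> KKpp + KKKs
      KKpp + P2 <-> KKpp_P2
      KKpp_P2 -> KKp + P2
      KKp + P2 <-> KKp_P2
      KKp_P2 -> KK + P2",
    # reciprocal kinase/phosphatase regulation by covalent modification: the
    # substrate cycle runs on the activated kinase Kp (itself switched on by
    # E and off by G through Michaelis-Menten steps); the phosphatase P is
    # covalently inactivated by the active kinase and during catalysis (the
    # dephosphorylation step leaves the mark on P), and reactivated through
    # contact with the phosphorylated substrate
    covalent_regulation = "
      S + Kp <-> SKp
      SKp -> Sp + Kp
      Sp + P <-> SpP
      SpP -> S + Pp
      K + E <-> KE
      KE -> Kp + E
      Kp + G <-> KpG
      KpG -> K + G
      P + Kp -> Pp + Kp
      Pp + Sp -> P + Sp",
    # species and reaction order reproduce the printed stoichiometric matrix
    allosteric_regulation = "
      species: S Sp K P KL PL SKL SpP L
      S + KL -> SKL
      SKL -> S + KL
      SKL -> Sp + KL
      Sp + P -> SpP
      SpP -> Sp + P
      SpP -> S + P
      K + L -> KL
      KL -> K + L
      P + L -> PL
      PL -> P + L",
    allosteric_reduced = "
      species: S Sp K P KL PL SKL SpP L
      S + KL -> SKL
      SKL -> Sp + KL
      Sp + P -> SpP
      SpP -> S + P
      K + L -> KL
      KL -> K + L
      P + L -> PL
      PL -> P + L"
  )
  parse_network(text)
}

.phospho_site_name <- function(i) paste0("S", strrep("p", i))

.phospho_cycle_text <- function(m, diff_phosphatases) {
  lines <- character(0)
  for (i in seq_len(m)) {
    s0 <- if (i == 1) "S" else .phospho_site_name(i - 1)
    s1 <- .phospho_site_name(i)
    ek <- paste0("E", s0) # kinase-substrate complex: ES, ESp, ...
    f <- if (diff_phosphatases) paste0("F", i) else "F"
    fk <- paste0(f, s1)
    lines <- c(lines,
      paste0(s0, " + E <-> ", ek),
      paste0(ek, " -> ", s1, " + E"),
      paste0(s1, " + ", f, " <-> ", fk),
      paste0(fk, " -> ", s0, " + ", f))
  }
  paste(lines, collapse = "\n")
}
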