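## Declarative encodings of the four Alzheimer's disease pathway nets:
## calcium influx/efflux channels, the Calpain-CAST regulatory system, APP
## processing, and their crosstalk. Transition rates are the published
## parameter tables; net topology is reconstructed from the model
## descriptions (each arc's provenance is recorded in the bundle notes as
## "stated" or "inferred"), and initial markings are package calibrations
## (none are published). The bundles carry mass-action hazard semantics:
## marking-dependent hazards are what biochemical SPN tools simulate, and
## they are required for the documented lag-phase and intervention
## behaviours to emerge from the published rates (see the methods vignette).

pl <- function(id, tokens = 0L, label = id, note = "stated") {
  data.frame(id = id, tokens = as.integer(tokens), label = label,
             note = note, stringsAsFactors = FALSE)
}
tr <- function(id, rate, label = id, note = "stated") {
  data.frame(id = id, rate = rate, label = label, note = note,
             stringsAsFactors = FALSE)
}
ar <- function(source, target, kind = "standard", weight = 1L,
               note = "inferred") {
  data.frame(source = source, target = target, kind = kind,
             weight = as.integer(weight), note = note,
             stringsAsFactors = FALSE)
}

## ---- calcium influx / efflux subnet (transitions t1..t31 + Energy) ----
## t1-t10 GPCR branch storing excess Ca in the ER, t11 store release,
## t12-t22 NMDAR and VGCC influx, t23-t29 ATP-dependent efflux pumps,
## t30-t31 calcium-dependent PKC activation, Energy = ATP production.
calcium_part <- function() {
  places <- rbind(
    pl("Ca_Out", 80, "extracellular Ca2+ pool", "calibrated"),
    pl("Ca_In", 2, "cytosolic Ca2+", "calibrated"),
    pl("Ca_ER", 5, "ER Ca2+ store", "calibrated"),
    pl("glu", 1, "glutamate"),
    pl("NMDR_0", 1, "NMDAR, closed"),
    pl("NMDR_glu_0", 0, "NMDAR-glutamate complex, closed"),
    pl("NMDR_glu_1", 0, "NMDAR-glutamate complex, open"),
    pl("VGCC_c1", 0, "VGCC channel 1, open"),
    pl("VGCC_c2", 0, "VGCC channel 2, open"),
    pl("GPCR", 1, "G-protein coupled receptor"),
    pl("ligand", 3, "GPCR ligand"),
    pl("GPCR_Lig", 0, "GPCR-ligand complex"),
    pl("GProtein_i", 1, "G-protein, inactive"),
    pl("GProtein_act", 0, "G-protein, active"),
    pl("PLC_i", 1, "phospholipase C, inactive", "inferred"),
    pl("PLC_act", 0, "phospholipase C, active"),
    pl("PIP2", 2, "PIP2"),
    pl("DAG", 0, "diacylglycerol"),
    pl("IP3", 0, "IP3"),
    pl("IP3R", 1, "IP3 receptor on ER"),
    pl("ATP", 40, "ATP pool", "calibrated"),
    pl("PMCA_1", 1, "PMCA pump, ready"),
    pl("PMCA_Ca", 0, "PMCA pump, Ca-loaded", "inferred"),
    pl("NCX", 1, "Na/Ca exchanger"),
    pl("Na_In", 2, "intracellular Na+", "calibrated"),
    pl("Na_out", 4, "extracellular Na+", "calibrated"),
    pl("Na_K_1", 1, "Na/K ATPase, ready"),
    pl("NaK_load", 0, "Na/K ATPase, Na-loaded", "inferred"),
    pl("K_In", 4, "intracellular K+", "calibrated"),
    pl("K_Out", 8, "extracellular K+", "calibrated"),
    pl("iPKC", 6, "PKC, inactive", "calibrated"),
    pl("PKC", 0, "PKC, active"))
  transitions <- rbind(
    tr("t1", 1, "GPCR-ligand binding"),
    tr("t2", 1, "GPCR-ligand dissociation", "inferred"),
    tr("t3", 1, "G-protein activation"),
    tr("t4", 1, "G-protein deactivation", "inferred"),
    tr("t5", 1, "PLC activation"),
    tr("t6", 1, "PLC deactivation", "inferred"),
    tr("t7", 1, "PIP2 synthesis", "inferred"),
    tr("t8", 1, "PLC cleaves PIP2 into DAG + IP3"),
    tr("t9", 1, "IP3-gated Ca storage into the ER"),
    tr("t10", 0.65, "store uptake of cytosolic Ca into the ER"),
    tr("t11", 1, "Ca release from the ER store"),
    tr("t12", 1, "NMDAR binds glutamate"),
    tr("t13", 1, "NMDAR complex opens"),
    tr("t14", 1, "Ca admission through open NMDAR"),
    tr("t15", 1, "NMDAR closes, releases glutamate", "inferred"),
    tr("t16", 1, "NMDAR activity opens VGCC 1"),
    tr("t17", 1, "Ca admission closes VGCC 1"),
    tr("t18", 1, "VGCC 1 spontaneous closing", "inferred"),
    tr("t19", 1, "Na load + NCX depolarization opens VGCC 2"),
    tr("t20", 1, "Ca admission closes VGCC 2"),
    tr("t21", 1, "VGCC 2 spontaneous closing", "inferred"),
    tr("t22", 1, "NMDAR unbinds without opening", "inferred"),
    tr("t23", 1, "PMCA loads one cytosolic Ca"),
    tr("t24", 1, "PMCA extrudes Ca, consuming ATP"),
    tr("t25", 1, "PMCA slip: load released back", "inferred"),
    tr("t26", 1, "NCX: 1 Ca out per 3 Na in"),
    tr("t27", 1, "Na/K ATPase loads 3 Na"),
    tr("t28", 1, "Na/K ATPase: 3 Na out, 2 K in, ATP consumed"),
    tr("t29", 1, "K leak channel", "inferred"),
    tr("t30", 1, "PKC activation by DAG and Ca"),
    tr("t31", 1, "PKC deactivation", "inferred"),
    tr("Energy", 1, "ATP production"))
  arcs <- rbind(
    ar("GPCR", "t1"), ar("ligand", "t1"), ar("t1", "GPCR_Lig"),
    ar("GPCR_Lig", "t2"), ar("t2", "GPCR"), ar("t2", "ligand"),
    ar("GProtein_i", "t3"), ar("GPCR_Lig", "t3", "read"),
    ar("t3", "GProtein_act"),
    ar("GProtein_act", "t4"), ar("t4", "GProtein_i"),
    ar("PLC_i", "t5"), ar("GProtein_act", "t5", "read"), ar("t5", "PLC_act"),
    ar("PLC_act", "t6"), ar("t6", "PLC_i"),
    ar("t7", "PIP2"),
    ar("PIP2", "t8"), ar("PLC_act", "t8", "read"),
    ar("t8", "DAG"), ar("t8", "IP3"),
    ar("Ca_In", "t9"), ar("IP3", "t9"), ar("IP3R", "t9", "read"),
    ar("t9", "Ca_ER"),
    ar("Ca_In", "t10"), ar("t10", "Ca_ER"),
    ar("Ca_ER", "t11"), ar("t11", "Ca_In"),
    ar("NMDR_0", "t12"), ar("glu", "t12"), ar("t12", "NMDR_glu_0"),
    ar("NMDR_glu_0", "t13"), ar("t13", "NMDR_glu_1"),
    ar("Ca_Out", "t14"), ar("NMDR_glu_1", "t14"),
    ar("t14", "Ca_In"), ar("t14", "NMDR_glu_0"),
    ar("NMDR_glu_1", "t15"), ar("t15", "NMDR_0"), ar("t15", "glu"),
    ar("NMDR_glu_0", "t16", "read"), ar("t16", "VGCC_c1"),
    ar("Ca_Out", "t17"), ar("VGCC_c1", "t17"), ar("t17", "Ca_In"),
    ar("VGCC_c1", "t18"),
    ar("NCX", "t19", "read"), ar("Na_In", "t19", "read", 10L),
    ar("t19", "VGCC_c2"),
    ar("Ca_Out", "t20"), ar("VGCC_c2", "t20"), ar("t20", "Ca_In"),
    ar("VGCC_c2", "t21"),
    ar("NMDR_glu_0", "t22"), ar("t22", "NMDR_0"), ar("t22", "glu"),
    ar("PMCA_1", "t23"), ar("Ca_In", "t23"), ar("t23", "PMCA_Ca"),
    ar("PMCA_Ca", "t24"), ar("ATP", "t24"),
    ar("t24", "PMCA_1"), ar("t24", "Ca_Out"),
    ar("PMCA_Ca", "t25"), ar("t25", "PMCA_1"), ar("t25", "Ca_In"),
    ar("NCX", "t26", "read"), ar("Ca_In", "t26"),
    ar("Na_out", "t26", "standard", 3L),
    ar("t26", "Ca_Out"), ar("t26", "Na_In", "standard", 3L),
    ar("Na_K_1", "t27"), ar("Na_In", "t27", "standard", 3L),
    ar("t27", "NaK_load"),
    ar("NaK_load", "t28"), ar("ATP", "t28"),
    ar("K_Out", "t28", "standard", 2L),
    ar("t28", "Na_K_1"), ar("t28", "Na_out", "standard", 3L),
    ar("t28", "K_In", "standard", 2L),
    ar("K_In", "t29"), ar("t29", "K_Out"),
    ar("iPKC", "t30"), ar("DAG", "t30"), ar("Ca_In", "t30"),
    ar("t30", "PKC"),
    ar("PKC", "t31"), ar("t31", "iPKC"), ar("t31", "Ca_In"),
    ar("Energy", "ATP"))
  list(places = places, transitions = transitions, arcs = arcs)
}

## ---- Calpain-CAST subnet (transitions c1..c14) ----
## Calpain (pCalp) is held at the membrane by CAST (mCT) in the mC complex;
## rising cytosolic Ca breaks mC, freeing active Calpain (CLP) and cytosolic
## CAST (cCT), which re-complex as cC; Calpain slowly digests complexed CAST
## into inactive fragments (dCT). PKC phosphorylates CAST into iCT;
## phosphatases (pp) reactivate it (CT), which redistributes to membrane and
## cytosol. Calpain also cleaves PKC into pkm and P35 into p25.
calpain_part <- function(c4 = 0.5, c5 = 0.02, c6 = 0.5, c12 = 1) {
  places <- rbind(
    pl("pCalp", 4, "pro-Calpain at the membrane", "calibrated"),
    pl("mCT", 2, "membrane CAST", "calibrated"),
    pl("mC", 8, "membrane Calpain-CAST complex", "calibrated"),
    pl("CLP", 0, "active Calpain"),
    pl("cCT", 0, "cytosolic CAST"),
    pl("cC", 0, "cytosolic Calpain-CAST complex"),
    pl("dCT", 0, "degraded CAST fragments"),
    pl("CT", 4, "active CAST pool", "calibrated"),
    pl("iCT", 0, "phosphorylated (inactive) CAST"),
    pl("pp", 2, "phosphatases", "calibrated"),
    pl("pp_used", 0, "phosphatases, recycling", "inferred"),
    pl("P35", 0, "P35"),
    pl("p25", 0, "p25 cleavage fragment"),
    pl("pkm", 0, "PKM (cleaved PKC)"))
  transitions <- rbind(
    tr("c1", 0.5, "membrane complex formation at low Ca"),
    tr("c2", 0.1, "Ca-triggered complex break, Calpain activation"),
    tr("c3", 1, "CAST translocation to the membrane"),
    tr("c4", c4, "cytosolic Calpain-CAST complex formation"),
    tr("c5", c5, "slow CAST degradation inside the complex"),
    tr("c6", c6, "P35 synthesis", "inferred"),
    tr("c7", 0.3, "Calpain cleaves PKC into PKM"),
    tr("c8", 0.5, "CAST translocation to the cytosol"),
    tr("c9", 1, "PKC phosphorylates membrane CAST"),
    tr("c10", 1, "PKC phosphorylates cytosolic CAST"),
    tr("c11", 1, "phosphatase reactivates CAST"),
    tr("c12", c12, "p25 turnover", "inferred"),
    tr("c13", 1, "Calpain cleaves P35 into p25"),
    tr("c14", 0.5, "phosphatase recycling", "inferred"))
  arcs <- rbind(
    ar("pCalp", "c1"), ar("mCT", "c1"), ar("c1", "mC"),
    ar("Ca_In", "c1", "inhibitor", 4L),
    ar("mC", "c2"), ar("Ca_In", "c2", "read"),
    ar("c2", "CLP"), ar("c2", "cCT"),
    ar("CT", "c3"), ar("c3", "mCT"),
    ar("cCT", "c4"), ar("CLP", "c4"), ar("c4", "cC"),
    ar("cC", "c5"), ar("c5", "CLP"), ar("c5", "dCT"),
    ar("c6", "P35"),
    ar("PKC", "c7"), ar("CLP", "c7", "read"), ar("c7", "pkm"),
    ar("CT", "c8"), ar("c8", "cCT"),
    ar("mCT", "c9"), ar("PKC", "c9", "read"), ar("c9", "iCT"),
    ar("cCT", "c10"), ar("PKC", "c10", "read"), ar("c10", "iCT"),
    ar("iCT", "c11"), ar("pp", "c11"), ar("c11", "CT"), ar("c11", "pp_used"),
    ar("p25", "c12"),
    ar("P35", "c13"), ar("CLP", "c13", "read"), ar("c13", "p25"),
    ar("pp_used", "c14"), ar("c14", "pp"))
  list(places = places, transitions = transitions, arcs = arcs)
}

## ---- APP processing subnet ----
## Non-amyloidogenic route (a, a1, g_a): APP is cleaved by alpha-secretase
## into sAPPa + CTF83, then by gamma-secretase into p3 + AICD.
## Amyloidogenic route (b, b1, g_b): cleavage by BACE yields sAPPb + CTF99,
## then gamma-secretase releases amyloid-beta + AICD. Amyloid-beta
## aggregates into oligomers (p1, n_oligo monomers each) and oligomers
## deposit as plaques (p2, n_plaq oligomers each).
app_part <- function(n_oligo = 4L, n_plaq = 4L, abeta0 = 6L) {
  places <- rbind(
    pl("aAPP", 0, "APP routed to alpha-secretase cleavage"),
    pl("bAPP", 0, "APP routed to BACE cleavage"),
    pl("ALPHA", 1, "alpha-secretase"),
    pl("BACE", 1, "beta-secretase (BACE)"),
    pl("GAMA", 1, "gamma-secretase"),
    pl("sAPPa", 0, "soluble APP-alpha"),
    pl("sAPPb", 0, "soluble APP-beta"),
    pl("CTF83", 0, "C-terminal fragment 83"),
    pl("CTF99", 0, "C-terminal fragment 99"),
    pl("p3", 0, "p3 fragment"),
    pl("AICD", 0, "APP intracellular domain"),
    pl("Amyloidbeta", abeta0, "amyloid-beta monomers", "calibrated"),
    pl("Oligomer", 0, "amyloid-beta oligomers"),
    pl("Plaq", 0, "senile plaques"))
  transitions <- rbind(
    tr("a", 0.5, "APP supply to the non-amyloidogenic route"),
    tr("a1", 0.5, "alpha-secretase cleavage of APP"),
    tr("b", 0.3, "APP supply to the amyloidogenic route"),
    tr("b1", 0.3, "BACE cleavage of APP"),
    tr("g1", 0.5, "gamma-secretase synthesis", "inferred"),
    tr("g2", 0.5, "gamma-secretase turnover", "inferred"),
    tr("g_a", 0.5, "gamma-secretase cleaves CTF83"),
    tr("g_b", 0.3, "gamma-secretase cleaves CTF99"),
    tr("p1", 0.005, "oligomerization of amyloid-beta"),
    tr("p2", 0.02, "plaque deposition from oligomers"))
  arcs <- rbind(
    ar("a", "aAPP"),
    ar("aAPP", "a1"), ar("ALPHA", "a1", "read"),
    ar("a1", "sAPPa"), ar("a1", "CTF83"),
    ar("b", "bAPP"),
    ar("bAPP", "b1"), ar("BACE", "b1", "read"),
    ar("b1", "sAPPb"), ar("b1", "CTF99"),
    ar("g1", "GAMA"), ar("GAMA", "g2"),
    ar("CTF83", "g_a"), ar("GAMA", "g_a", "read"),
    ar("g_a", "p3"), ar("g_a", "AICD"),
    ar("CTF99", "g_b"), ar("GAMA", "g_b", "read"),
    ar("g_b", "Amyloidbeta"), ar("g_b", "AICD"),
    ar("Amyloidbeta", "p1", "standard", n_oligo), ar("p1", "Oligomer"),
    ar("Oligomer", "p2", "standard", n_plaq), ar("p2", "Plaq"))
  list(places = places, transitions = transitions, arcs = arcs)
}

merge_parts <- function(...) {
  parts <- list(...)
  list(places = do.call(rbind, lapply(parts, `[[`, "places")),
       transitions = do.call(rbind, lapply(parts, `[[`, "transitions")),
       arcs = do.call(rbind, lapply(parts, `[[`, "arcs")))
}

part_to_bundle <- function(name, part, params = list()) {
  net <- spn(part$places[c("id", "label")],
             part$transitions[c("id", "label")],
             part$arcs[c("source", "target", "kind", "weight")],
             name = name)
  marking <- stats::setNames(part$places$tokens, part$places$id)
  rates <- stats::setNames(part$transitions$rate, part$transitions$id)
  notes <- rbind(
    data.frame(element = part$places$id, type = "place",
               provenance = part$places$note, stringsAsFactors = FALSE),
    data.frame(element = part$transitions$id, type = "transition",
               provenance = part$transitions$note, stringsAsFactors = FALSE),
    data.frame(element = paste(part$arcs$source, "->", part$arcs$target,
                               paste0("(", part$arcs$kind, ")")),
               type = "arc", provenance = part$arcs$note,
               stringsAsFactors = FALSE))
  new_bundle(name, net, marking, rates, semantics = "mass_action",
             params = params, notes = notes)
}

#' Names of the shipped disease models
#' @return character vector of model names accepted by \code{\link{ad_model}}.
#' @export
ad_models <- function() {
  c("calcium_channel", "calpain_cast", "app_processing", "crosstalk")
}

#' Build a shipped Alzheimer's disease pathway model
#'
#' Returns one of four SPN bundles: \code{calcium_channel} (calcium influx /
#' efflux channels, transitions t1..t31 plus Energy), \code{calpain_cast}
#' (the calcium subnet plus Calpain-Calpastatin regulation, c1..c14),
#' \code{app_processing} (amyloid precursor protein cleavage and plaque
#' aggregation) and \code{crosstalk} (the union plus the pathological
#' couplings k1..k6, the Calpain-driven doubling of BACE-mediated cleavage,
#' amyloid-beta inhibition of ATP production, and oligomer membrane pores
#' feeding calcium influx). Published transition rates are used verbatim,
#' except that the Calpain-CAST model adopts c4 = 0.5 (complex formation)
#' and c5 = 0.02 (slow degradation), the assignment consistent with the
#' narrative, the crosstalk table and the intervention experiment; set
#' \code{raw_table_rates = TRUE} for the unswapped alternative.
#'
#' @param name model name, see \code{\link{ad_models}}.
#' @param n_oligo amyloid-beta monomers consumed per oligomer.
#' @param n_plaq oligomers consumed per plaque.
#' @param energy_threshold amyloid-beta token count at which ATP production
#'   is inhibited (crosstalk only; inhibitor arc weight, calibrated).
#' @param pore_threshold oligomer count at which membrane pores open a
#'   direct calcium influx route (crosstalk only; read arc weight,
#'   calibrated).
#' @param raw_table_rates use the published Calpain-CAST table values
#'   c4 = 0.02, c5 = 0.5 instead of the corrected assignment
#'   (\code{calpain_cast} only).
#' @return an \code{spn_model} bundle (net, calibrated default marking,
#'   rates, mass-action semantics, per-element provenance notes).
#' @examples
#' m <- ad_model("app_processing")
#' m$rates[c("p1", "p2")]
#' @export
ad_model <- function(name = ad_models(), n_oligo = 4L, n_plaq = 4L,
                     energy_threshold = 6L, pore_threshold = 5L,
                     raw_table_rates = FALSE) {
  name <- match.arg(name)
  params <- list(n_oligo = n_oligo, n_plaq = n_plaq,
                 energy_threshold = energy_threshold,
                 pore_threshold = pore_threshold)
  if (name == "calcium_channel")
    return(part_to_bundle(name, calcium_part()))
  if (name == "calpain_cast") {
    cp <- if (raw_table_rates) calpain_part(c4 = 0.02, c5 = 0.5)
          else calpain_part()
    return(part_to_bundle(name, merge_parts(calcium_part(), cp)))
  }
  if (name == "app_processing")
    return(part_to_bundle(name, app_part(n_oligo, n_plaq),
                          params = params[c("n_oligo", "n_plaq")]))
  ## crosstalk uses its own published values for c6 (1) and c12 (0.5)
  part <- merge_parts(calcium_part(), calpain_part(c6 = 1, c12 = 0.5),
                      app_part(n_oligo, n_plaq),
                      crosstalk_part(n_oligo, n_plaq,
                                     energy_threshold, pore_threshold))
  part_to_bundle("crosstalk", part, params = params)
}

## ---- pathological couplings of the crosstalk network ----
## b2: active Calpain doubles BACE-mediated APP processing (a second,
##     CLP-gated amyloidogenic cleavage at the baseline b rate).
## k1: PKC enhances alpha-secretase. k2: p25 hyperactivates cdk5.
## k3: oligomer membrane pores admit extracellular Ca.
## k4-k6: cdk5-dependent amplification of amyloid-beta production,
##        oligomerization and plaque deposition.
## Amyloidbeta inhibits the Energy transition (ATP starvation).
crosstalk_part <- function(n_oligo, n_plaq, energy_threshold,
                           pore_threshold) {
  places <- rbind(
    pl("cdk5_i", 1, "cdk5, basal"),
    pl("cdk5", 0, "cdk5, hyperactivated"))
  transitions <- rbind(
    tr("b2", 0.3, "Calpain-enhanced BACE cleavage of APP"),
    tr("k1", 0.5, "PKC enhances alpha-secretase"),
    tr("k2", 0.6, "p25 hyperactivates cdk5"),
    tr("k3", 1, "oligomer pores admit extracellular Ca"),
    tr("k4", 0.6, "cdk5-enhanced amyloid-beta release"),
    tr("k5", 0.01, "cdk5-enhanced oligomerization"),
    tr("k6", 0.04, "cdk5-enhanced plaque deposition"))
  arcs <- rbind(
    ar("CLP", "b2", "read"), ar("BACE", "b2", "read"),
    ar("b2", "sAPPb"), ar("b2", "CTF99"),
    ar("PKC", "k1", "read"), ar("k1", "ALPHA"),
    ar("p25", "k2"), ar("cdk5_i", "k2"), ar("k2", "cdk5"),
    ar("Ca_Out", "k3"), ar("Oligomer", "k3", "read", pore_threshold),
    ar("k3", "Ca_In"),
    ar("CTF99", "k4"), ar("GAMA", "k4", "read"), ar("cdk5", "k4", "read"),
    ar("k4", "Amyloidbeta"), ar("k4", "AICD"),
    ar("Amyloidbeta", "k5", "standard", n_oligo),
    ar("cdk5", "k5", "read"), ar("k5", "Oligomer"),
    ar("Oligomer", "k6", "standard", n_plaq),
    ar("cdk5", "k6", "read"), ar("k6", "Plaq"),
    ar("Amyloidbeta", "Energy", "inhibitor", energy_threshold))
  list(places = places, transitions = transitions, arcs = arcs)
}

#' Published therapeutic intervention parameter sets
#'
#' The intervention experiment perturbs the rates of the two complex
#' degradation transitions: c2 (membrane Calpain-CAST complex break) and c5
#' (cytosolic complex degradation). Each may be lowered (0.05 / 0.005) or
#' set to zero, which permanently disables the transition.
#'
#' @return named list of override vectors for
#'   \code{\link{apply_intervention}}.
#' @export
ad_interventions <- function() {
  list(mild = c(c2 = 0.05, c5 = 0.005),
       c2_block = c(c2 = 0),
       c5_block = c(c5 = 0),
       full_block = c(c2 = 0, c5 = 0))
}

#' Apply a rate intervention to a model bundle
#'
#' Returns a new bundle with the given transition rates replaced; a rate of
#' 0 disables the transition permanently. The original bundle is unchanged.
#'
#' @param bundle an \code{spn_model}.
#' @param overrides named numeric vector, e.g. \code{c(c2 = 0, c5 = 0.005)}.
#' @param label optional label appended to the bundle name.
#' @return the modified \code{spn_model}.
#' @examples
#' base <- ad_model("crosstalk")
#' noclp <- apply_intervention(base, c(c2 = 0))
#' noclp$rates["c2"]
#' @export
apply_intervention <- function(bundle, overrides, label = NULL) {
  stopifnot(inherits(bundle, "spn_model"))
  if (length(overrides) == 0L) return(bundle)
  unknown <- setdiff(names(overrides), names(bundle$rates))
  if (length(unknown))
    stop("unknown transitions in overrides: ",
         paste(unknown, collapse = ", "))
  if (any(overrides < 0) || any(!is.finite(overrides)))
    stop("override rates must be finite and >= 0")
  bundle$rates[names(overrides)] <- overrides
  bundle$name <- paste0(bundle$name, "+",
                        if (is.null(label))
                          paste(names(overrides), overrides, sep = "=",
                                collapse = ",")
                        else label)
  bundle
}

#' Catalogue of shipped models with element counts
#'
#' @return data frame with one row per model: name, number of places,
#'   transitions, arcs and rate entries.
#' @export
list_models <- function() {
  do.call(rbind, lapply(ad_models(), function(nm) {
    b <- ad_model(nm)
    data.frame(name = nm, places = nrow(b$net$places),
               transitions = nrow(b$net$transitions),
               arcs = nrow(b$net$arcs), rates = length(b$rates),
               stringsAsFactors = FALSE)
  }))
}
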