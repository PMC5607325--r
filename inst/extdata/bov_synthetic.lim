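# Bransfield Strait site model (SYNTHETIC stocks/isotopes).
# Topology, environment and physiological ranges follow the study
# design; biomass and d13C values are invented placeholders because
# the measured site data are not published. Replace them via a
# stocks CSV for real analyses.
## COMPARTMENTS
Det, Detritus, internal, detritus, NA, -25, 1, -
DOC, Dissolved organic carbon, internal, dissolved, NA, -24.5, 1, -
Bac, Heterotrophic bacteria, internal, bacteria, 50, -24, 1.5, heterotrophy
MacES, Macrofauna with endosymbionts, internal, macrofauna, 6, -35, 2, symbiont_fixation
MacDF, Macrofaunal deposit feeders, internal, macrofauna, 60, -23.5, 1.5, deposit
MacSF, Macrofaunal suspension feeders, internal, macrofauna, 4, -24, 1, suspension
MacPS, Macrofaunal predators/scavengers, internal, macrofauna, 25, -22.800000000000001, 2, predation
MegDF, Megafaunal deposit feeders, internal, megafauna, 80, -24, 1.5, deposit
MegSF, Megafaunal suspension feeders, internal, megafauna, 10, -24, 1, suspension
Det_s, Buried detritus, external, detritus, NA, NA, NA, -
Predation, Megafaunal predation, external, external, NA, NA, NA, -
DIC, Dissolved inorganic carbon, external, dissolved, NA, NA, NA, -
DOC_w, Water-column DOC, external, dissolved, NA, NA, NA, -
Det_w, Particulate detritus flux from the water column, external, detritus, NA, -25, 0.5, -
## FLOWS
Det_w -> Det
Det_w -> MacSF
Det_w -> MegSF
Det -> DOC
Det -> Det_s
Det -> MacDF
Det -> MegDF
DOC -> Bac
DOC -> DOC_w
Bac -> DIC
Bac -> Det
Bac -> MacDF
Bac -> MacPS
MacDF -> DIC
MacDF -> Det
MacDF -> MacPS
MacSF -> DIC
MacSF -> Det
MacSF -> MacPS
MacPS -> DIC
MacPS -> Det
MacPS -> Predation
MegDF -> DIC
MegDF -> Det
MegDF -> Predation
MegSF -> DIC
MegSF -> Det
MegSF -> Predation
DIC -> MacES
MacES -> DIC
MacES -> MacPS
## PARAMETERS
site_id = BOV
depth = 1150
temperature = -1
scoc_range = [0.81000000000000005, 2.8599999999999999]
poc_range = [0.69999999999999996, 27.170000000000002]
substrate.CH4 = 7
q10 = 2
bge_range = [0.050000000000000003, 0.45000000000000001]
viral_lysis_range = [0.29999999999999999, 0.80000000000000004]
chemo_efficiency_range = [0.10000000000000001, 0.5]
burial_efficiency_range = [0.01, 0.029999999999999999]
doc_efflux_range = [0, 0.10000000000000001]
macrofauna.growth_coeff_range = [0.01, 0.050000000000000003]
macrofauna.nge_range = [0.29999999999999999, 0.69999999999999996]
macrofauna.ae_range = [0.20000000000000001, 0.75]
macrofauna.faecal_range = [0.25, 0.80000000000000004]
macrofauna.maintenance_coeff = 0.01
macrofauna.respiration_multiplier_range = [0.5, 1.5]
macrofauna.biomass_specific_respiration = 0.01
megafauna.growth_coeff_range = [0.0027000000000000001, 0.014]
megafauna.nge_range = [0.5, 0.69999999999999996]
megafauna.ae_range = [0.20000000000000001, 0.75]
megafauna.faecal_range = [0.25, 0.80000000000000004]
megafauna.maintenance_coeff = 0.001
megafauna.respiration_multiplier_range = [0.5, 1.5]
megafauna.biomass_specific_respiration = 0.01
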