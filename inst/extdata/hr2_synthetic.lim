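# Bransfield Strait site model (SYNTHETIC stocks/isotopes).
# Topology, environment and physiological ranges follow the study
# design; biomass and d13C values are invented placeholders because
# the measured site data are not published. Replace them via a
# stocks CSV for real analyses.
## COMPARTMENTS
Det, Detritus, internal, detritus, NA, -25, 1, -
DOC, Dissolved organic carbon, internal, dissolved, NA, -24.5, 1, -
Bac, Heterotrophic bacteria, internal, bacteria, 90, -24, 1.5, heterotrophy
ChBac, Chemosynthetic bacteria, internal, bacteria, 35, -35, 2, chemoautotrophy
MacDF, Macrofaunal deposit feeders, internal, macrofauna, 8, -25, 2.5, deposit
MacSF, Macrofaunal suspension feeders, internal, macrofauna, 10, -24, 1, suspension
MacPS, Macrofaunal predators/scavengers, internal, macrofauna, 3, -23.5, 2.5, predation
MegDF, Megafaunal deposit feeders, internal, megafauna, 2, -25, 2.5, deposit
MegSF, Megafaunal suspension feeders, internal, megafauna, 3, -24, 1, suspension
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
MacDF -> Predation
MacSF -> DIC
MacSF -> Det
MacSF -> MacPS
MacSF -> Predation
MacPS -> DIC
MacPS -> Det
MacPS -> Predation
MegDF -> DIC
MegDF -> Det
MegDF -> Predation
MegSF -> DIC
MegSF -> Det
MegSF -> Predation
DIC -> ChBac
ChBac -> DIC
ChBac -> Det
ChBac -> MacDF
ChBac -> MacPS
ChBac -> MegDF
Det -> MacPS
## PARAMETERS
site_id = HR2
depth = 1054
temperature = 48
advection = 34
scoc_range = [1.6200000000000001, 2.8599999999999999]
poc_range = [0.69999999999999996, 27.170000000000002]
substrate.H2S = 160
substrate.CH4 = 26
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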