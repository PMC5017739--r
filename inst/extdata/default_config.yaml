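# Default configuration: reference physiology, ligand kinetics, radiobiology,
# dose constraints and solver settings for Lu-177 PSMA PBPK planning.
#
# All values are echoed into run reports for provenance. Reference organ
# values are for a 73 kg adult; organ masses/flows scale with body weight,
# measured volumes (kidneys, parotids, tumors) override the reference.
# Perfusion is serum flow per tissue mass (ml/g/min); vascular_fraction is the
# serum (plasma-equivalent) share of tissue volume; interstitial_fraction is
# the peptide-accessible interstitial share.

reference:
  body_weight_kg: 73
  height_m: 1.75          # used to derive weight from BSA (Du Bois) when absent
  plasma_volume_ml: 2900  # total serum; central pool = total - organ vascular

physiology:
  kidneys:        {mass_g: 299,   perfusion: 2.5,   vascular_fraction: 0.055, interstitial_fraction: 0.15, ps_per_g: 1.0,   psma: true}
  salivary_glands: {mass_g: 50,   perfusion: 0.16,  vascular_fraction: 0.05,  interstitial_fraction: 0.18, ps_per_g: 0.5,   psma: true}
  tumor_1:        {mass_g: 1,     perfusion: 0.5,   vascular_fraction: 0.07,  interstitial_fraction: 0.30, ps_per_g: 1.5,   psma: true}
  tumor_2:        {mass_g: 1,     perfusion: 0.5,   vascular_fraction: 0.07,  interstitial_fraction: 0.30, ps_per_g: 1.5,   psma: true}
  liver:          {mass_g: 1800,  perfusion: 0.15,  vascular_fraction: 0.085, interstitial_fraction: 0.16, ps_per_g: 0.20,   psma: true}
  spleen:         {mass_g: 180,   perfusion: 0.8,   vascular_fraction: 0.17,  interstitial_fraction: 0.15, ps_per_g: 0.5,   psma: true}
  gi_tract:       {mass_g: 1100,  perfusion: 0.25,  vascular_fraction: 0.03,  interstitial_fraction: 0.12, ps_per_g: 0.2,   psma: true}
  prostate:       {mass_g: 25,    perfusion: 0.18,  vascular_fraction: 0.03,  interstitial_fraction: 0.25, ps_per_g: 0.3,   psma: true}
  muscle:         {mass_g: 29000, perfusion: 0.02,  vascular_fraction: 0.010, interstitial_fraction: 0.10, ps_per_g: 0.010,  psma: false}
  fat:            {mass_g: 13500, perfusion: 0.02,  vascular_fraction: 0.008, interstitial_fraction: 0.12, ps_per_g: 0.010,  psma: false}
  lungs:          {mass_g: 1000,  perfusion: 0.10,  vascular_fraction: 0.10,  interstitial_fraction: 0.18, ps_per_g: 0.030,  psma: false}
  bone:           {mass_g: 5500,  perfusion: 0.02,  vascular_fraction: 0.008, interstitial_fraction: 0.08, ps_per_g: 0.005,  psma: false}
  red_marrow:     {mass_g: 1170,  perfusion: 0.10,  vascular_fraction: 0.03,  interstitial_fraction: 0.15, ps_per_g: 0.10,   psma: false}
  heart:          {mass_g: 330,   perfusion: 0.60,  vascular_fraction: 0.10,  interstitial_fraction: 0.15, ps_per_g: 0.05,   psma: false}
  brain:          {mass_g: 1400,  perfusion: 0.30,  vascular_fraction: 0.02,  interstitial_fraction: 0.03, ps_per_g: 0.0001, psma: false}
  skin:           {mass_g: 2600,  perfusion: 0.04,  vascular_fraction: 0.012, interstitial_fraction: 0.30, ps_per_g: 0.020,  psma: false}
  rest:           {mass_g: 5000,  perfusion: 0.05,  vascular_fraction: 0.03,  interstitial_fraction: 0.15, ps_per_g: 0.020,  psma: false}

receptors:
  # fitted densities default to the cohort medians (nmol per l tissue)
  kidneys: 24
  salivary_glands: 42
  tumor_1: 110
  tumor_2: 110
  reference_kidney_density: 24
  # non-fitted PSMA-positive tissues: fixed multiples of the reference kidney
  # density (literature values are not printed in the source; assumption,
  # see methods vignette)
  relative:
    liver: 0.08
    spleen: 0.12
    gi_tract: 0.08
    prostate: 0.5

ligand:
  k_on: 0.046                 # l nmol^-1 min^-1
  k_off: 0.046                # min^-1; 0.046 = Model 1, 0.46 = Model 2
  lambda_int: 0.001           # min^-1, all receptor-positive tissues
  lambda_release:             # min^-1; kidneys/salivary/tumors are fitted
    kidneys: 2.9e-4
    salivary_glands: 3.7e-4
    tumor_1: 2.0e-4
    tumor_2: 2.0e-4
    other: 3.0e-4             # fixed for liver/spleen/GI/prostate
  molar_mass_factor: 1.66     # ug per nmol
  half_life_min: 9573         # Lu-177, 6.647 d
  molar_activity_gbq_nmol: 0.7268  # carrier-free Lu-177
  unspecific_kidney_fraction: 0.02 # share of filtered peptide retained
  # peptide renal filtration clearance = factor * TER; the MAG3 TER tracks
  # effective renal plasma flow and bounds glomerular filtration of the
  # peptide from above, hence factor < 1
  renal_clearance_ter_factor: 0.3
  catabolite_clearance_ter_factor: 0.3

background:
  fraction: 0.002             # shared muscle-signal fraction in organ ROIs
  shared: true

radiobiology:
  alpha_beta:   {kidneys: 2.5, tumor: 3.9, salivary_glands: 4.5, red_marrow: 15}
  repair_halftime_min: {kidneys: 168, tumor: 90, salivary_glands: 90, red_marrow: 90}

svalues:
  kidney_self_ref: 4.8e-3     # Gy/(GBq min) at 299 g, scales as 1/mass
  kidney_ref_mass_g: 299
  rm_rm_ref: 1.22e-3          # Gy/(GBq min) at reference weight
  rm_rem_ref: 1.4e-6          # Gy/(GBq min), remainder -> red marrow
  ref_weight_kg: 73
  sphere_table: svalues_sphere_lu177_synthetic.csv

constraints:
  kidney_bed_max: 10          # Gy_2.5 per cycle
  salivary_dose_max: 7.5      # Gy per cycle
  marrow_bed_max: 0.25        # Gy_15 per cycle
  n_cycles: 4

administration:
  infusion_duration_min: 10

solver:
  rtol: 1.0e-8
  atol: 1.0e-12
  t_end_min: 30000
  grid_points: 400            # log-spaced; early segment densified
  max_steps: 2000000

fitting:
  n_starts: 5
  max_outer: 3
  max_lm_iter: 15
  fd_step: 0.02               # forward-difference step on log parameters
  rtol: 1.0e-4                # fit-grade solver tolerance (noise ~10%)
  atol: 1.0e-8
  aic_variance_per_region: true
  bounds:
    density: [1, 5000]        # nmol/l
    release: [1.0e-5, 1.0e-2] # min^-1
    f_sal: [0.01, 2]          # ml/g/min
    background: [1.0e-5, 0.2]

envelopes:
  # virtual-patient sampling envelopes (cohort min/max)
  r_kidneys: [14, 46]
  r_salivary: [38, 108]
  r_tumor: [19, 2412]         # log-uniform
  lrel_kidneys: [2.3e-4, 3.7e-4]
  lrel_salivary: [3.3e-4, 4.8e-4]
  lrel_tumor: [0.88e-4, 2.4e-4]
  f_sal: [0.074, 0.53]
  tumor_volume_ml: [0.5, 34]  # log-uniform
  parotid_volume_ml: [17, 54]
  kidney_volume_ml: [268, 394]
  ter_ml_min: [136, 252]
  bsa_m2: [1.8, 2.1]
  amount_nmol: [74, 302]
  activity_gbq: [5.4, 6.0]

noise:
  # fractional measurement SD per region (defaults; observed range 3-27%)
  tumor_1: 0.10
  tumor_2: 0.10
  kidneys: 0.10
  salivary_glands: 0.10
  total_body: 0.05

schedule_min: [30, 120, 1440, 2880, 4320]  # 0.5 h, 2 h, 1 d, 2 d, 3 d
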