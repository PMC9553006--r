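# Genotype presets for the closure-kinetics generator.
#
# Rates (um/min) are the published cohort means for each genotype's early
# (hole > 190 um) and, for wild type, late (hole < 190 um) closure phase.
# Septate-junction mutants generally fail to enter the fast phase
# (enter_fast_phase: false => the late rate equals the early rate) and may
# arrest; tearing penetrance per genotype is the observed live-imaging
# frequency. Values the source data do not constrain are marked "free" and
# were fixed once:
#   * tear_length_mean/sd: Nrx-IV tears shortly after the hole drops below
#     190 um (mean 180, sd 10); cora/Mcr tear later in closure, so a
#     smaller-length mean (120, sd 30) was adopted (free).
#   * p_anterior_tear: tears occur "more often" anteriorly; 0.7 (free).
#   * p_arrest: per-genotype arrest probabilities are unpublished; 0.3 for
#     all three mutant presets (free).
#   * noise_sigma: manual canthus-placement measurement error, 2 um (free).
#   * arrest_length_mean/sd: 120/30 um, truncated below L_inflection (free).
wild_type:
  genotype_label: wild_type
  r_early: 0.64
  r_late: 1.88
  enter_fast_phase: true
  p_tear: 0.0
  p_arrest: 0.0
cora4:
  genotype_label: cora4
  r_early: 0.52
  r_late: 0.52
  enter_fast_phase: false
  p_tear: 0.875
  p_arrest: 0.3
  tear_length_mean: 120
  tear_length_sd: 30
Mcr1:
  genotype_label: Mcr1
  r_early: 0.50
  r_late: 0.50
  enter_fast_phase: false
  p_tear: 0.5
  p_arrest: 0.3
  tear_length_mean: 120
  tear_length_sd: 30
NrxIV4304:
  genotype_label: NrxIV4304
  r_early: 0.57
  r_late: 0.57
  enter_fast_phase: false
  p_tear: 1.0
  p_arrest: 0.3
  tear_length_mean: 180
  tear_length_sd: 10
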