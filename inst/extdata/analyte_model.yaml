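# Default concentration model for the synthetic cohort generator.
#
# Per analyte: target arithmetic mean and SD (ng/ml) of the cohort-level
# steady-state distribution, relative genotype-category multipliers in the
# fixed order PM/PM, IM/PM, IM/IM, EM/PM, EM/IM, EM/EM, EM/UM (1 everywhere
# for CYP2D6-independent compounds), a detection limit (draws below it are
# not detected) and the calibration linearity range [lolr_lo, lolr_hi].
#
# Anchors: overall mean/SD per analyte from the cohort summary table;
# (Z)-endoxifen multipliers from the printed genotype-group means 1.8 / 2.3
# / 4.9 / 7.3 ng/ml (PM/PM, IM/PM, EM/PM, EM/EM; the unreported EM/IM,
# IM/IM and EM/UM levels are interpolated); (Z)-4-OH-Tam from its printed
# 1.5 vs 2.7 ng/ml extremes (geometric interpolation); NDM-Tam,
# 4'-OH-NDM-Tam (higher with impairment) and the 4-OH-NDM glucuronide
# (lower with impairment) use geometric per-step factors reproducing the
# reported direction of association. Detection limits are set at the
# log-normal quantile matching the reported not-detected rates.
analytes:
  - id: tamoxifen
    mean: 173.53
    sd: 67.68
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0
    lolr_lo: 40
    lolr_hi: 450
  - id: ndm_tam
    mean: 235.53
    sd: 97.04
    multipliers: [1.611, 1.464, 1.331, 1.21, 1.1, 1.0, 0.909]
    detect_limit: 0
    lolr_lo: 33
    lolr_hi: 900
  - id: z_endoxifen
    mean: 5.55
    sd: 3.26
    multipliers: [0.247, 0.315, 0.45, 0.671, 0.70, 1.0, 1.10]
    detect_limit: 0
    lolr_lo: 0.5
    lolr_hi: 20
  - id: z_4oh_tam
    mean: 2.46
    sd: 1.20
    multipliers: [0.556, 0.625, 0.703, 0.790, 0.889, 1.0, 1.125]
    detect_limit: 0
    lolr_lo: 0.1
    lolr_hi: 6.5
  - id: e_endoxifen
    mean: 0.02
    sd: 0.07
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0.04
    lolr_lo: 0.5
    lolr_hi: 2.0
  - id: oh_tam_4p
    mean: 3.13
    sd: 1.32
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0
    lolr_lo: 0.35
    lolr_hi: 9.0
  - id: oh_ndm_tam_4p
    mean: 3.84
    sd: 1.93
    multipliers: [1.762, 1.574, 1.405, 1.254, 1.12, 1.0, 0.893]
    detect_limit: 0
    lolr_lo: 0.19
    lolr_hi: 16.0
  - id: tam_n_oxide
    mean: 13.47
    sd: 7.43
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0
    lolr_lo: 1.4
    lolr_hi: 60.0
  - id: e_4oh_tam_o_gluc
    mean: 0.23
    sd: 0.17
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0
    lolr_lo: 0.03
    lolr_hi: 1.3
  - id: ez_4oh_ndm_tam_gluc
    mean: 1.12
    sd: 1.02
    multipliers: [0.444, 0.522, 0.614, 0.722, 0.85, 1.0, 1.176]
    detect_limit: 0
    lolr_lo: 0.10
    lolr_hi: 12.0
  - id: ez_tam_n_gluc
    mean: 0.32
    sd: 0.32
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0
    lolr_lo: 0.03
    lolr_hi: 2.6
  - id: e_aoh_tam
    mean: 0.36
    sd: 0.17
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0.10
    lolr_lo: 0.56
    lolr_hi: 1.1
  - id: z_aoh_tam
    mean: 0.04
    sd: 0.03
    multipliers: [1, 1, 1, 1, 1, 1, 1]
    detect_limit: 0.028
    lolr_lo: 0.138
    lolr_hi: 0.25
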