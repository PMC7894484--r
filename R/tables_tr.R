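# Published characterization tables for the thermophilic-rhodopsin (TR)
# construct panel, transcribed as data functions.  These are inputs to the
# pipeline (candidate ranking, summary-statistics tests, stabilization
# classification) and the source of the synthetic-generator presets.

#' Position-scan mutation candidates
#'
#' The twenty single-mutation candidates retained from the free-energy
#' position scan over the 28 solvent-exposed extramembrane residues, with
#' the predicted total folding free-energy change (kcal/mol; negative =
#' stabilizing) and the N-/C-terminal side of each site.
#'
#' @return Data frame with columns `site`, `wild_type`, `substitution`,
#'   `ddg_position_scan`, `side`.
#' @export
tr_position_scan <- function() {
  x <- read.csv(text = "site,wild_type,substitution,ddg_position_scan,side
8,S,D,-2.30,N
76,Q,R,-0.48,N
79,V,K,-0.41,N
81,V,R,-0.26,N
114,T,D,-3.08,C
114,T,E,-2.77,C
115,A,P,-1.26,C
116,A,D,-2.12,C
116,A,E,-1.53,C
142,N,R,-0.70,N
143,T,K,-1.01,N
177,A,K,-1.24,C
180,G,P,-1.87,C
210,W,R,-0.50,N
214,G,D,-3.43,N
214,G,E,-1.43,N
215,A,P,-1.48,N
216,A,E,-1.28,N
249,L,R,-0.15,C
250,E,M,-1.30,C", stringsAsFactors = FALSE)
  x
}

#' Final mutation candidates with refined free energies
#'
#' The ten selected single-mutation candidates with the refined
#' (build-model) folding free-energy change, the putative stabilizing
#' effect and its free-energy contribution.
#'
#' @return Data frame with columns `construct`, `site`, `wild_type`,
#'   `substitution`, `side`, `ddg_build_model`, `effect_tag`,
#'   `effect_contribution`.
#' @export
tr_candidates <- function() {
  x <- read.csv(text = "construct,site,wild_type,substitution,side,ddg_build_model,effect_tag,effect_contribution
S8D,8,S,D,N,-2.32,helix_dipole,-2.40
V79K,79,V,K,N,-0.45,electrostatic,-0.21
T114D,114,T,D,C,-3.91,helix_dipole,-2.61
A115P,115,A,P,C,-1.32,entropic,-1.08
A116E,116,A,E,C,-2.20,helix_dipole,-1.01
T143K,143,T,K,N,-1.02,hydrogen_bond,-1.76
A177K,177,A,K,C,-1.08,helix_dipole,-0.60
W210R,210,W,R,N,-0.66,helix_dipole,-0.33
G214D,214,G,D,N,-3.42,helix_dipole,-2.48
A215P,215,A,P,N,-1.54,entropic,-1.12", stringsAsFactors = FALSE)
  x
}

#' Experimental stability characterization of the construct panel
#'
#' Per-construct residual pigment after 4 minutes at 90 degrees C (mean and
#' s.e.m., percent), relative purification yield, decoloration rate
#' constant (min^-1) and apparent DSC melting temperature (degrees C), each
#' from three independent experiments; `NA` where a quantity was not
#' measured (mutants already classified as destabilized were not taken
#' through kinetics and DSC).
#'
#' @return Data frame with columns `construct`, `residual_pigment_mean`,
#'   `residual_pigment_sem`, `relative_yield`, `k_mean`, `k_sem`,
#'   `tm_mean`, `tm_sem`, `n_replicates`.
#' @export
tr_stability <- function() {
  x <- read.csv(text = "construct,residual_pigment_mean,residual_pigment_sem,relative_yield,k_mean,k_sem,tm_mean,tm_sem
WT,44.5,3.2,1.0,0.21,0.01,91.78,0.34
S8D,21.7,2.9,0.81,NA,NA,NA,NA
V79K,61.4,4.0,0.69,0.11,0.01,94.52,0.07
T114D,67.6,3.2,1.3,0.069,0.001,95.93,0.04
A115P,66.5,4.8,0.50,0.11,0.01,94.37,0.06
A116E,69.5,6.3,0.96,0.11,0.01,94.04,0.08
T143K,49.1,4.9,NA,NA,NA,NA,NA
A177K,35.9,2.7,0.66,NA,NA,NA,NA
W210R,12.6,1.0,0.74,NA,NA,NA,NA
G214D,35.8,5.0,0.95,NA,NA,NA,NA
A215P,36.0,4.5,1.2,NA,NA,NA,NA", stringsAsFactors = FALSE)
  x$n_replicates <- 3L
  x
}

#' Native-state ensemble RMSD statistics of the construct panel
#'
#' Mean and s.e.m. (across independent runs) of the average C-alpha RMSD of
#' late-window snapshots against the crystal structure, per construct, with
#' the two-tailed p-value of the comparison against the wild type.
#'
#' @return Data frame with columns `construct`, `rmsd_mean`, `rmsd_sem`,
#'   `n_runs`, `p_vs_wt`.
#' @export
tr_native_rmsd <- function() {
  read.csv(text = "construct,rmsd_mean,rmsd_sem,n_runs,p_vs_wt
WT,1.06,0.06,3,NA
S8D,1.03,0.03,3,0.61
V79K,1.29,0.08,3,0.087
T114D,1.47,0.06,3,0.0072
A115P,1.05,0.08,3,0.93
A116E,1.15,0.15,3,0.62
T143K,1.26,0.14,4,0.29
A177K,1.25,0.11,3,0.21
W210R,1.21,0.08,3,0.22
G214D,1.07,0.06,3,0.90
A215P,1.11,0.09,3,0.70", stringsAsFactors = FALSE)
}

#' Random-coil fluctuation statistics of the construct panel
#'
#' Mean and s.e.m. (n = 19) of the RMSDs between the medoid representative
#' and the other members of each construct's 20-member random-coil
#' ensemble, with the two-tailed p-value against the wild type.
#'
#' @return Data frame with columns `construct`, `rmsd_mean`, `rmsd_sem`,
#'   `n`, `p_vs_wt`.
#' @export
tr_coil_rmsd <- function() {
  read.csv(text = "construct,rmsd_mean,rmsd_sem,n,p_vs_wt
WT,22.4,0.5,19,NA
S8D,24.9,0.4,19,0.00050
V79K,23.1,0.7,19,0.42
T114D,22.7,0.5,19,0.69
A115P,22.7,0.6,19,0.69
A116E,23.3,0.6,19,0.26
T143K,22.3,0.6,19,0.87
A177K,22.7,0.6,19,0.76
W210R,22.9,0.4,19,0.45
G214D,23.3,0.6,19,0.27
A215P,22.7,0.4,19,0.70", stringsAsFactors = FALSE)
}

#' Synthetic-generator presets per construct
#'
#' Parameters that make the generators emulate the measured panel: the
#' decoloration rate constant `k` (min^-1), the melting temperature `tm`
#' (degrees C) and the residual pigment (percent) are the printed values
#' from [tr_stability()]; `native_sigma` (Angstrom, per-coordinate
#' isotropic noise) is the printed native-state ensemble RMSD divided by
#' sqrt(3), the first-order mapping between an isotropic displacement scale
#' and the expected superposition RMSD; `coil_scale` (Angstrom-equivalent
#' per-step angular perturbation) is a common base value for all
#' constructs, scaled up for S8D by the printed random-coil RMSD ratio, so
#' only the one construct with a reported coil-fluctuation difference
#' differs.
#'
#' @return Named list of per-construct parameter lists with elements
#'   `native_sigma`, `coil_scale`, `k`, `tm`, `residual_pigment`.
#' @export
construct_presets <- function() {
  stab <- tr_stability()
  native <- tr_native_rmsd()
  coil <- tr_coil_rmsd()
  base_coil <- 0.6
  out <- lapply(stab$construct, function(cl) {
    i <- match(cl, stab$construct)
    coil_ratio <- if (cl == "S8D") {
      coil$rmsd_mean[coil$construct == "S8D"] /
        coil$rmsd_mean[coil$construct == "WT"]
    } else 1
    list(native_sigma = native$rmsd_mean[native$construct == cl] / sqrt(3),
         coil_scale = base_coil * coil_ratio,
         k = stab$k_mean[i],
         tm = stab$tm_mean[i],
         residual_pigment = stab$residual_pigment_mean[i])
  })
  stats::setNames(out, stab$construct)
}
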