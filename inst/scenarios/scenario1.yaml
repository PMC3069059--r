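scenario_id: 1
n_covariates: 10
covariate_roles:
- confounder
- confounder
- confounder
- confounder
- exposure_only
- exposure_only
- exposure_only
- outcome_only
- outcome_only
- outcome_only
correlation_pairs:
  i:
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  j:
  - 5.0
  - 6.0
  - 8.0
  - 9.0
  rho:
  - 0.2
  - 0.9
  - 0.2
  - 0.9
dichotomize:
- 1
- 3
- 5
- 6
- 8
- 9
dichotomize_cut: 0.0
exposure_intercept: 0.0
exposure_main_coefs:
- 0.8
- -0.25
- 0.6
- -0.4
- -0.8
- -0.5
- 0.7
- 0.0
- 0.0
- 0.0
exposure_interaction_terms:
  i: []
  j: []
  coef: []
exposure_quadratic_terms:
  i: []
  coef: []
outcome_intercept: -3.85
outcome_coefs:
- 0.3
- -0.36
- -0.73
- -0.2
- 0.0
- 0.0
- 0.0
- 0.71
- -0.19
- 0.26
treatment_effect: -0.4
outcome_noise_sd: 0.0
outcome_on_latent: yes
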