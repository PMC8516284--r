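# Shared fixtures, built once per test run.
# A large cohort for Monte-Carlo recovery checks and a study-sized one for
# pipeline smoke tests; seeds fixed for reproducibility.

big_cohort <- simulate_cohort(cohort_params(n = 5000), seed = 42)
big_panel <- derive_panel(big_cohort)

study_cohort <- simulate_cohort(cohort_params(n = 146), seed = 7)
study_panel <- derive_panel(study_cohort)
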