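# SYNTHETIC placeholder for a conventional (non-gender-specific) SAF risk
# scheme.  The published conventional boundary coefficients are not
# available in print; these values are invented stand-ins with a plausible
# magnitude for a northern-European reference cohort and carry NO clinical
# meaning.  They exist so that scheme-comparison machinery can be exercised
# and so that users can substitute real coefficients via configuration.
name: conventional (synthetic placeholder)
multipliers:
- 1.0
- 2.0
sr_threshold: 10.0
strata:
  men:
    mean_intercept: 0.83
    mean_slope: 0.019
    sd_intercept: 0.18
    sd_slope: 0.0025
    age_min: 18.0
    age_max: 99.0
  women_low_sr:
    mean_intercept: 0.83
    mean_slope: 0.019
    sd_intercept: 0.18
    sd_slope: 0.0025
    age_min: 18.0
    age_max: 99.0
  women_high_sr:
    mean_intercept: 0.83
    mean_slope: 0.019
    sd_intercept: 0.18
    sd_slope: 0.0025
    age_min: 18.0
    age_max: 99.0
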