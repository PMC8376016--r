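# SYNTHETIC starter disability-weight registry. Codes and values are
# illustrative injury health-state weights in the style of the GBD 2013
# appendix (mean with 95% uncertainty bounds; treated/untreated variants for
# long-term-capable states, 'single' variant for short-term states). They are
# NOT a copy of any published table; supply the published appendix as a CSV
# with these columns for real analyses.
code,description,variant,mean,ui_lower,ui_upper
st_minor,"short-term minor injury (open wound, contusion)",single,0.006,0.002,0.012
st_moderate,"short-term moderate injury (uncomplicated fracture)",single,0.067,0.044,0.097
st_severe,"short-term severe injury (multiple trauma, internal injury)",single,0.132,0.088,0.190
lt_musculoskeletal,"long-term musculoskeletal impairment",treated,0.062,0.041,0.089
lt_musculoskeletal,"long-term musculoskeletal impairment",untreated,0.123,0.082,0.176
lt_amputation,"long-term limb amputation",treated,0.088,0.059,0.125
lt_amputation,"long-term limb amputation",untreated,0.164,0.110,0.231
lt_spinal,"long-term spinal cord lesion",treated,0.296,0.198,0.414
lt_spinal,"long-term spinal cord lesion",untreated,0.589,0.404,0.753
lt_tbi,"long-term traumatic brain injury",treated,0.203,0.134,0.289
lt_tbi,"long-term traumatic brain injury",untreated,0.350,0.235,0.475
lt_burn_disfigurement,"long-term burn with disfigurement",treated,0.188,0.124,0.267
lt_burn_disfigurement,"long-term burn with disfigurement",untreated,0.280,0.187,0.391
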