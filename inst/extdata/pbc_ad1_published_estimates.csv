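parameter,case,control
fixef_intercept,1.139,-0.569
fixef_visit_time,-4.813e-4,2.906e-4
fixef_time_before_event,2.283e-4,
fixef_visit_time_x_tbe,-1.083e-7,
ranef_sd_intercept,0.593,0.550
ranef_sd_visit_time,3.448e-4,2.615e-4
ranef_cor,-0.378,0.209
resid_sd,0.293,0.220
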