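{
  "flat":       {"load_amp": 1.00, "swing_amp_dps": 100, "stride_period_mean_s": 1.10, "stride_period_sd_s": 0.05, "load_duty": 0.55, "swing_cv": 0.12},
  "upstairs":   {"load_amp": 1.20, "swing_amp_dps": 50,  "stride_period_mean_s": 1.30, "stride_period_sd_s": 0.06, "load_duty": 0.60, "swing_cv": 0.25},
  "downstairs": {"load_amp": 1.10, "swing_amp_dps": 60,  "stride_period_mean_s": 1.25, "stride_period_sd_s": 0.06, "load_duty": 0.60, "swing_cv": 0.22},
  "uphill":     {"load_amp": 1.05, "swing_amp_dps": 90,  "stride_period_mean_s": 1.20, "stride_period_sd_s": 0.05, "load_duty": 0.57, "swing_cv": 0.15},
  "downhill":   {"load_amp": 0.95, "swing_amp_dps": 85,  "stride_period_mean_s": 1.15, "stride_period_sd_s": 0.05, "load_duty": 0.55, "swing_cv": 0.15}
}
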