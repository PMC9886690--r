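{
  "comment": "17-metric ISAW registry with group-conditional summary parameters (analysis scale: natural log for the four starred sway metrics). Group sizes: 123 non-fallers, 91 fallers.",
  "n_nonfaller": 123,
  "n_faller": 91,
  "metrics": [
    {"name": "centroidal_frequency", "domain": "S",   "log_scale": true,  "units": "Hz",     "mean_nonfaller": -0.068, "sd_nonfaller": 0.259, "mean_faller": -0.125, "sd_faller": 0.239},
    {"name": "jerkiness",            "domain": "S",   "log_scale": true,  "units": "m^2/s^5","mean_nonfaller": 0.361,  "sd_nonfaller": 1.032, "mean_faller": 0.367,  "sd_faller": 0.979},
    {"name": "sway_velocity",        "domain": "S",   "log_scale": true,  "units": "m/s",    "mean_nonfaller": -2.085, "sd_nonfaller": 0.595, "mean_faller": -1.888, "sd_faller": 0.566},
    {"name": "coronal_rms",          "domain": "S",   "log_scale": true,  "units": "m/s^2",  "mean_nonfaller": -3.649, "sd_nonfaller": 0.602, "mean_faller": -3.540, "sd_faller": 0.510},
    {"name": "apa_lateral_peak",     "domain": "A",   "log_scale": false, "units": "m/s^2",  "mean_nonfaller": 0.381,  "sd_nonfaller": 0.164, "mean_faller": 0.422,  "sd_faller": 0.180},
    {"name": "stride_time",          "domain": "G:T", "log_scale": false, "units": "s",      "mean_nonfaller": 1.119,  "sd_nonfaller": 0.092, "mean_faller": 1.138,  "sd_faller": 0.095},
    {"name": "double_support_time",  "domain": "G:T", "log_scale": false, "units": "%",      "mean_nonfaller": 22.21,  "sd_nonfaller": 3.519, "mean_faller": 23.09,  "sd_faller": 3.736},
    {"name": "gait_speed",           "domain": "G:S", "log_scale": false, "units": "m/s",    "mean_nonfaller": 1.064,  "sd_nonfaller": 0.176, "mean_faller": 1.000,  "sd_faller": 0.187},
    {"name": "stride_length",        "domain": "G:S", "log_scale": false, "units": "m",      "mean_nonfaller": 1.175,  "sd_nonfaller": 0.152, "mean_faller": 1.125,  "sd_faller": 0.187},
    {"name": "stride_time_cov",      "domain": "G:V", "log_scale": false, "units": "ratio",  "mean_nonfaller": 0.031,  "sd_nonfaller": 0.013, "mean_faller": 0.035,  "sd_faller": 0.015},
    {"name": "stride_length_cov",    "domain": "G:V", "log_scale": false, "units": "ratio",  "mean_nonfaller": 0.084,  "sd_nonfaller": 0.062, "mean_faller": 0.091,  "sd_faller": 0.055},
    {"name": "lateral_step_dev_sd",  "domain": "G:V", "log_scale": false, "units": "cm",     "mean_nonfaller": 4.079,  "sd_nonfaller": 1.194, "mean_faller": 4.333,  "sd_faller": 1.461},
    {"name": "coronal_rom",          "domain": "G:U", "log_scale": false, "units": "deg",    "mean_nonfaller": 5.436,  "sd_nonfaller": 2.128, "mean_faller": 5.330,  "sd_faller": 2.115},
    {"name": "sagittal_rom",         "domain": "G:U", "log_scale": false, "units": "deg",    "mean_nonfaller": 4.307,  "sd_nonfaller": 1.258, "mean_faller": 4.200,  "sd_faller": 1.183},
    {"name": "arm_rom",              "domain": "G:U", "log_scale": false, "units": "deg",    "mean_nonfaller": 40.66,  "sd_nonfaller": 14.62, "mean_faller": 38.35,  "sd_faller": 13.76},
    {"name": "turn_duration",        "domain": "T",   "log_scale": false, "units": "s",      "mean_nonfaller": 2.354,  "sd_nonfaller": 0.491, "mean_faller": 2.389,  "sd_faller": 0.471},
    {"name": "turn_velocity",        "domain": "T",   "log_scale": false, "units": "deg/s",  "mean_nonfaller": 169.4,  "sd_nonfaller": 46.00, "mean_faller": 154.80, "sd_faller": 38.90}
  ]
}
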