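condition,thermal_camera_c,thermistor_c,abs_deviation_c
hand_warm,33.88,34.04,0.45
hand_cold,25.25,25.67,1.63
mouse_1,34.60,33.96,0.64
mouse_2,33.64,33.37,0.28
mouse_3,33.74,34.09,0.35
mouse_4,33.38,32.81,0.58
mouse_5,34.97,36.23,1.26
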