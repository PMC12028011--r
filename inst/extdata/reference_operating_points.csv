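cohort,model,auc,sensitivity,specificity,ppv,npv
retrospective,radiologists,0.82,0.83,0.71,81.95,72.48
retrospective,3-Channel,0.82,0.85,0.62,78.01,72.27
retrospective,3-Channel+clinical,0.85,0.89,0.62,78.79,78.04
retrospective,ME-Fusion,0.85,0.81,0.74,83.17,71.06
retrospective,ME-Fusion+clinical,0.87,0.86,0.69,81.48,75.65
retrospective,MECA-Fusion,0.86,0.86,0.70,81.97,75.92
retrospective,MECA-Fusion+clinical,0.90,0.91,0.72,83.75,83.46
prospective,radiologists,0.76,0.87,0.65,73.15,82.02
prospective,3-Channel,0.71,0.71,0.53,62.34,62.51
prospective,3-Channel+clinical,0.80,0.78,0.67,72.15,73.54
prospective,ME-Fusion,0.80,0.75,0.71,73.92,72.15
prospective,ME-Fusion+clinical,0.84,0.78,0.77,78.80,76.15
prospective,MECA-Fusion,0.83,0.80,0.73,76.46,76.91
prospective,MECA-Fusion+clinical,0.87,0.86,0.75,79.04,83.02
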