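# Radiation-induced lesion formation rates in isolated DNA substrates.
# slope: lesions per 1e6 DNA bases on a common per-dose scale, from linear
#   fits of yield-dose series (three independent experiments).
# slope_sd: SD of the slope across the replicate experiments.
# percent_printed: integer display percentage of the parent-base total.
# censored: TRUE marks a value at the quantification limit (upper bound);
#   its SD is carried as 0.
# Products of a parent base absent from a substrate have no row.
substrate_id,analyte_id,slope,slope_sd,percent_printed,censored
ODN1:1,U-Gly,1.35,0.09,11,FALSE
ODN1:1,U-Hyd,1.88,0.13,15,FALSE
ODN1:1,C-Imid,5.38,0.38,43,FALSE
ODN1:1,5ohC,2.38,0.17,19,FALSE
ODN1:1,5ohU,1.48,0.10,12,FALSE
ODN1:1,T-Gly,1.69,0.12,17,FALSE
ODN1:1,T-Hyd,0.45,0.03,5,FALSE
ODN1:1,5hmU,0.51,0.04,5,FALSE
ODN1:1,5fU,7.21,0.50,73,FALSE
ODN1:1,8oxoG,40.8,2.9,100,FALSE
ODN2:2,5mC-Gly,1.49,0.10,12,FALSE
ODN2:2,5mC-Hyd,3.28,0.23,26,FALSE
ODN2:2,5mC-Imid,1.88,0.13,15,FALSE
ODN2:2,5hmC,0.55,0.04,4,FALSE
ODN2:2,5fC,5.45,0.38,43,FALSE
ODN2:2,U-Gly,1.44,0.10,17,FALSE
ODN2:2,U-Hyd,1.17,0.08,14,FALSE
ODN2:2,C-Imid,2.15,0.15,25,FALSE
ODN2:2,5ohC,2.28,0.16,27,FALSE
ODN2:2,5ohU,1.53,0.11,18,FALSE
ODN2:2,T-Gly,1.43,0.10,18,FALSE
ODN2:2,T-Hyd,0.16,0.01,2,FALSE
ODN2:2,5hmU,0.87,0.06,11,FALSE
ODN2:2,5fU,5.38,0.38,69,FALSE
ODN2:2,8oxoG,18.6,1.3,100,FALSE
ODN3:4,U-Gly,0.76,0.10,19,FALSE
ODN3:4,U-Hyd,1.32,0.39,34,FALSE
ODN3:4,C-Imid,0.48,0.04,12,FALSE
ODN3:4,5ohC,0.54,0.09,14,FALSE
ODN3:4,5ohU,0.80,0.07,21,FALSE
ODN3:4,T-Gly,2.60,0.20,32,FALSE
ODN3:4,T-Hyd,0.56,0.07,7,FALSE
ODN3:4,5hmU,0.42,0.05,5,FALSE
ODN3:4,5fU,4.65,0.60,56,FALSE
ODN3:4,8oxoG,14.4,1.2,100,FALSE
ODN3:6,5mC-Gly,0.23,0.04,8,FALSE
ODN3:6,5mC-Hyd,0.77,0.05,27,FALSE
ODN3:6,5mC-Imid,0.17,0.02,6,FALSE
ODN3:6,5hmC,0.08,0.01,3,FALSE
ODN3:6,5fC,1.56,0.44,56,FALSE
ODN3:6,U-Gly,0.52,0.10,22,FALSE
ODN3:6,U-Hyd,0.72,0.09,30,FALSE
ODN3:6,C-Imid,0.28,0.07,11,FALSE
ODN3:6,5ohC,0.31,0.07,13,FALSE
ODN3:6,5ohU,0.57,0.05,24,FALSE
ODN3:6,T-Gly,2.68,0.38,32,FALSE
ODN3:6,T-Hyd,0.45,0.11,5,FALSE
ODN3:6,5hmU,0.33,0.02,4,FALSE
ODN3:6,5fU,4.95,0.35,59,FALSE
ODN3:6,8oxoG,11.8,2.8,100,FALSE
ODN5:6,5mC-Gly,0.43,0.04,6,FALSE
ODN5:6,5mC-Hyd,1.70,0.12,23,FALSE
ODN5:6,5mC-Imid,0.38,0.10,5,FALSE
ODN5:6,5hmC,0.24,0.05,3,FALSE
ODN5:6,5fC,4.67,0.47,63,FALSE
ODN5:6,T-Gly,3.31,0.23,29,FALSE
ODN5:6,T-Hyd,0.60,0.04,5,FALSE
ODN5:6,5hmU,0.55,0.14,5,FALSE
ODN5:6,5fU,6.79,0.48,60,FALSE
ODN5:6,8oxoG,16.2,1.1,100,FALSE
CT-DNA,5mC-Gly,0.27,0.02,26,FALSE
CT-DNA,5mC-Hyd,0.27,0.03,26,FALSE
CT-DNA,5mC-Imid,0.02,0.00,0,TRUE
CT-DNA,5hmC,0.03,0.01,3,FALSE
CT-DNA,5fC,0.45,0.03,44,FALSE
CT-DNA,U-Gly,0.83,0.06,14,FALSE
CT-DNA,U-Hyd,1.08,0.08,18,FALSE
CT-DNA,C-Imid,1.23,0.15,21,FALSE
CT-DNA,5ohC,1.47,0.10,25,FALSE
CT-DNA,5ohU,1.27,0.09,22,FALSE
CT-DNA,T-Gly,1.89,0.13,16,FALSE
CT-DNA,T-Hyd,0.53,0.04,4,FALSE
CT-DNA,5hmU,0.95,0.07,8,FALSE
CT-DNA,5fU,8.70,0.61,72,FALSE
CT-DNA,8oxoG,11.8,0.8,100,FALSE
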