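# Radiation-induced lesion formation rates in cellular DNA (cultured rat
# glioma cells, 0-4 kGy).
# slope: lesions per 1e6 non-modified DNA bases per kGy of ionizing
#   radiation, from linear fits over five independent experiments.
# slope_sd: SD of the slope across the replicate experiments.
# baseline: lesion level measured in non-irradiated cells (lesions per 1e6
#   bases); analytes not detected in non-irradiated cells (< 0.1) carry 0.
# 5mC-Gly, 5mC-Imid, 5ohC and 5ohU were below detection in cells and have
# no row.
analyte_id,slope,slope_sd,baseline
5mC-Hyd,0.37,0.01,0
5hmC,1.20,0.14,7.5
5fC,0.47,0.05,0.5
U-Gly,1.48,0.14,0
U-Hyd,5.71,0.48,0
C-Imid,2.12,0.06,0
T-Gly,7.75,0.10,3.7
T-Hyd,0.85,0.14,0
5hmU,13.26,1.64,5.6
5fU,19.47,1.15,24.5
8oxoG,8.72,0.72,2.5
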