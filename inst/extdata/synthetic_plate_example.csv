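# ldm-plate-csv v1
# culture_volume_ml: 1
# t_tilde_hr: 2.3999999999999999
# meta origin: synthetic
# meta seed: 20260925
"well_id","role","turbid","target","timepoint","colony_count","dilution_factor","plated_volume_ml"
"A1","donor-control",FALSE,,,,,
"A2","recipient-control",FALSE,,,,,
"A3","transconjugant-control",TRUE,,,,,
"A4","mixed-control",FALSE,,,,,
"A5","mixed-control",FALSE,,,,,
"A6","density-coculture",,,,,,
"A7","density-coculture",,,,,,
"A8","density-coculture",,,,,,
"A9","blank",,,,,,
"A10","blank",,,,,,
"A11","blank",,,,,,
"A12","blank",,,,,,
"B1","coculture",TRUE,,,,,
"B2","coculture",TRUE,,,,,
"B3","coculture",FALSE,,,,,
"B4","coculture",FALSE,,,,,
"B5","coculture",FALSE,,,,,
"B6","coculture",TRUE,,,,,
"B7","coculture",FALSE,,,,,
"B8","coculture",TRUE,,,,,
"B9","coculture",TRUE,,,,,
"B10","coculture",FALSE,,,,,
"B11","coculture",TRUE,,,,,
"B12","coculture",FALSE,,,,,
"C1","coculture",FALSE,,,,,
"C2","coculture",TRUE,,,,,
"C3","coculture",FALSE,,,,,
"C4","coculture",TRUE,,,,,
"C5","coculture",FALSE,,,,,
"C6","coculture",TRUE,,,,,
"C7","coculture",TRUE,,,,,
"C8","coculture",FALSE,,,,,
"C9","coculture",TRUE,,,,,
"C10","coculture",TRUE,,,,,
"C11","coculture",FALSE,,,,,
"C12","coculture",FALSE,,,,,
"D1","coculture",TRUE,,,,,
"D2","coculture",FALSE,,,,,
"D3","coculture",FALSE,,,,,
"D4","coculture",TRUE,,,,,
"D5","coculture",FALSE,,,,,
"D6","coculture",TRUE,,,,,
"D7","coculture",TRUE,,,,,
"D8","coculture",FALSE,,,,,
"D9","coculture",FALSE,,,,,
"D10","coculture",TRUE,,,,,
"D11","coculture",FALSE,,,,,
"D12","coculture",FALSE,,,,,
"E1","coculture",FALSE,,,,,
"E2","coculture",TRUE,,,,,
"E3","coculture",TRUE,,,,,
"E4","coculture",FALSE,,,,,
"E5","coculture",TRUE,,,,,
"E6","coculture",TRUE,,,,,
"E7","coculture",FALSE,,,,,
"E8","coculture",FALSE,,,,,
"E9","coculture",TRUE,,,,,
"E10","coculture",FALSE,,,,,
"E11","coculture",FALSE,,,,,
"E12","coculture",FALSE,,,,,
"F1","coculture",TRUE,,,,,
"F2","coculture",FALSE,,,,,
"F3","coculture",FALSE,,,,,
"F4","coculture",TRUE,,,,,
"F5","coculture",FALSE,,,,,
"F6","coculture",FALSE,,,,,
"F7","coculture",TRUE,,,,,
"F8","coculture",TRUE,,,,,
"F9","coculture",FALSE,,,,,
"F10","coculture",TRUE,,,,,
"F11","coculture",TRUE,,,,,
"F12","coculture",TRUE,,,,,
"G1","coculture",FALSE,,,,,
"G2","coculture",TRUE,,,,,
"G3","coculture",FALSE,,,,,
"G4","coculture",FALSE,,,,,
"G5","coculture",TRUE,,,,,
"G6","coculture",TRUE,,,,,
"G7","coculture",FALSE,,,,,
"G8","coculture",FALSE,,,,,
"G9","coculture",TRUE,,,,,
"G10","coculture",FALSE,,,,,
"G11","coculture",FALSE,,,,,
"G12","coculture",FALSE,,,,,
"H1","coculture",FALSE,,,,,
"H2","coculture",FALSE,,,,,
"H3","coculture",FALSE,,,,,
"H4","coculture",TRUE,,,,,
"H5","coculture",FALSE,,,,,
"H6","coculture",FALSE,,,,,
"H7","coculture",TRUE,,,,,
"H8","coculture",TRUE,,,,,
"H9","coculture",TRUE,,,,,
"H10","coculture",TRUE,,,,,
"H11","coculture",FALSE,,,,,
"H12","coculture",TRUE,,,,,
"A6","density-coculture",,"donor-selective","initial",9,1,0.1
"A6","density-coculture",,"donor-selective","final",116,1,0.1
"A6","density-coculture",,"recipient-selective","initial",6,1,0.1
"A6","density-coculture",,"recipient-selective","final",103,1,0.1
"A7","density-coculture",,"donor-selective","initial",13,1,0.1
"A7","density-coculture",,"donor-selective","final",110,1,0.1
"A7","density-coculture",,"recipient-selective","initial",8,1,0.1
"A7","density-coculture",,"recipient-selective","final",114,1,0.1
"A8","density-coculture",,"donor-selective","initial",8,1,0.1
"A8","density-coculture",,"donor-selective","final",126,1,0.1
"A8","density-coculture",,"recipient-selective","initial",15,1,0.1
"A8","density-coculture",,"recipient-selective","final",96,1,0.1
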